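"""Independent constraint-based-modeling oracle for the test suite.

Reads a COBRA-schema JSON model, runs FBA, pFBA and FVA with an
established implementation, and prints a JSON summary for comparison
against the package's own LP machinery.
"""
import json
import sys

import cobra
from cobra.flux_analysis import flux_variability_analysis, pfba

model_path, fraction = sys.argv[1], float(sys.argv[2])
model = cobra.io.load_json_model(model_path)
model.solver.configuration.tolerances.feasibility = 1e-9

fba_obj = model.slim_optimize()
pfba_sol = pfba(model)
total_abs = float(pfba_sol.fluxes.abs().sum())

fva = flux_variability_analysis(model, fraction_of_optimum=fraction)
out = {
    "fba_objective": float(fba_obj),
    "pfba_total_abs_flux": total_abs,
    "fva": {rid: [float(fva.loc[rid, "minimum"]), float(fva.loc[rid, "maximum"])]
            for rid in fva.index},
}
print(json.dumps(out))
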