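#!/usr/bin/env Rscript
# Production indices from fed-batch fermentation profiles.
#
# Generates a synthetic dual-carbon fed-batch profile with known ground
# truth (the wet-lab runs are not reproducible in silico), recomputes
# titer, glucose-equivalent yield and the three productivities from the
# time series alone, and checks the round trip. Writes
# results/fermentation_profile.csv and results/fermentation_indices.csv.

suppressPackageStartupMessages(library(succinoflux))
dir.create("results", showWarnings = FALSE)

sim <- generate_fermentation_profile(titer = 100, overall_productivity = 4,
                                     max_productivity = 8,
                                     yield_mol_per_mol = 1.3,
                                     glycerol_fraction = 0.3, seed = 1)
ind <- compute_indices(sim$profile)

write.csv(sim$profile, "results/fermentation_profile.csv", row.names = FALSE)
write.csv(as.data.frame(unclass(ind)), "results/fermentation_indices.csv",
          row.names = FALSE)

cat("recovered production indices (generator truth in brackets):\n")
tr <- sim$truth
for (f in names(unclass(ind)))
  cat(sprintf("  %-22s %10.4f  [%.4f]\n", f, ind[[f]], tr[[f]]))
cat("\nhigh-inoculum conversions: OD600 21.1 ->",
    sprintf("%.2f gDCW/L;", dcw_from_od(21.1)),
    "19.3 ->", sprintf("%.2f gDCW/L\n", dcw_from_od(19.3)))
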