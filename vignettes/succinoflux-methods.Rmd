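---
title: "Methods: constraint-based and kinetic analysis of succinate overproduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: constraint-based and kinetic analysis of succinate overproduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(succinoflux)
```

# Scope

`succinoflux` reimplements, as a tested pipeline, the computational core of
a malate-dehydrogenase (MDH) selection study for succinic acid (SA)
overproduction in *Mannheimia succiniciproducens*: substrate-inhibition
enzyme kinetics, FVSEOF amplification-target identification on a
stoichiometric model, flux-sum analysis of cofactor turnover under single
vs dual carbon sources, and fermentation production indices. The original
genome-scale model (686 reactions) and the raw assay and fermentation data
are not publicly deposited, so a synthetic-data module supplies
structurally faithful stand-ins with known ground truth. Everything the
tests assert is therefore a property of the method or a published number,
never a claim about the unpublished data.

# The linear-programming layer

All flux analyses reduce to linear programs over the steady-state polytope
$\{v : S v = 0,\ lb \le v \le ub\}$. The package ships its own dense
two-phase simplex (`lp_solve`, internal) with Bland's anti-cycling rule,
pivot tolerance $10^{-9}$, and finite-bound preprocessing. Two properties
motivated building it into the package rather than delegating:

* **Determinism.** Identical inputs give the identical optimal basis, so
  alternate-optima tie-breaking is reproducible across machines. This
  matters for flux variability scans whose outputs feed regressions.
* **Verifiability.** The test suite cross-checks FBA, parsimonious FBA and
  FVA results on the toy network against an independent, established
  constraint-based implementation (COBRApy, via a JSON export) to within
  $10^{-5}$, and fuzz-tests the simplex itself for feasibility,
  optimality and status agreement.

Default flux bounds are $\pm 1000$ mmol gDCW$^{-1}$ h$^{-1}$ for
reversible and $[0, 1000]$ for irreversible reactions; uptake is a
negative exchange flux (export-positive convention).

## FBA, pFBA, FVA

`solve_fba()` maximizes the biomass objective. `solve_pfba()` fixes the
objective at its maximum and minimizes total absolute flux via flux
splitting ($v = v^+ - v^-$). `run_fva()` computes per-reaction flux
extremes under an objective floor (`growth_fraction`, default 0.95 of the
maximum), optionally under a total-flux cap and with thermodynamic-cycle
removal:

* **Flux cap.** The cap is stated in the source methodology as limiting
  the FVA total absolute flux to "no larger than 10% of" the parsimonious
  total. Taken literally this is infeasible — the parsimonious solution
  already minimizes that total — so the package implements the only
  self-consistent reading: $\sum_j |v_j| \le (1 + 0.10) \times$
  parsimonious total, i.e. at most 10% *above* it. The cap is rebuilt
  per FVA call (and per enforcement level in a scan) from a fresh
  parsimonious solution under the same constraints.
* **Loop handling.** `remove_thermodynamic_cycles()` post-processes a
  distribution in the CycleFreeFlux style: holding every exchange flux
  and the objective fixed, it minimizes total internal flux with each
  internal reaction restricted to its observed direction and magnitude.
  Pure loops collapse to zero; loop-free inputs are fixed points; the
  input itself is a feasibility witness, so the step cannot fail. In
  loopless FVA the scanned reaction's cycle-free flux is reported, which
  deliberately shrinks loop-only envelopes (a MILP loopless variant
  would do the same at far higher cost; post-processing was chosen as
  deterministic and fast, and the choice is configurable at the FVA
  call).

# The toy succinate network

`build_toy_model()` returns a ~30-reaction single-cell model of the
reductive-TCA production route: lumped glycolysis, lumped glycerol
assimilation, the PEP-carboxykinase (PCKA) / malate dehydrogenase (MDH) /
fumarase (FUMC) / fumarate reductase (FRD) backbone with a closed
menaquinone pool, the pyruvate-node byproduct routes (lactate, formate via
pyruvate-formate lyase, acetate via phosphotransacetylase/acetate kinase,
pyruvate overflow), a decarboxylating malic enzyme, formate dehydrogenase
feeding the quinone pool, ATP maintenance (default 1 mmol gDCW$^{-1}$
h$^{-1}$) and a biomass pseudo-reaction drawing pyruvate (1), oxaloacetate
(0.5), ATP (10) and NADH (0.5) per unit biomass. The production genotype
is obtained by deleting `LDHA`, `PTA` and `ACKA`
(`palk_knockouts()`), exactly as the homo-succinate strain was built.

Design choices that depart from a naive one-reaction-per-enzyme sketch,
all motivated by making the toy reproduce the *structure* of a
genome-scale scan rather than its size:

* **Parallel isoroutes.** Glycolysis, glycerol assimilation and
  NADH:menaquinone oxidoreductase are each present twice with identical
  lumped stoichiometry (EMP/ED-style glycolysis, kinase/dehydrogenase
  glycerol routes, ndh-1/ndh-2-style dehydrogenases). Genome-scale
  networks are full of such redundancy, and it is what keeps merely
  *load-bearing* reactions from looking like amplification targets: a
  unique reaction whose flux is stoichiometrically coupled to production
  would be "selected" by any minimum-flux criterion, telling us nothing.
* **NADH in biomass.** Anabolic reducing-power demand decouples succinate
  flux from glucose uptake; without it the production genotype is rigidly
  carbon-coupled and the succinate exchange has a degenerate (empty)
  enforceable range.
* **Energy and redox bookkeeping.** Water, phosphate and protons are
  omitted; cofactor pairs (NAD/NADH, ADP/ATP, MQ/MQH2) are strictly
  closed, and the validator rejects any exchange or drain touching them.
  Biomass units are arbitrary; maximal "growth rates" around 2-4 h$^{-1}$
  should not be read as physiological.
* **Boundary species.** Exchanged metabolites are tagged extracellular;
  the isolated reversible 2-cycle (`CYC1`/`CYC2`) carries no net
  stoichiometry and exists purely to exercise loop handling (its removal
  provably changes no objective).

The toy model round-trips through a TSV format (one reaction equation per
row) and a minimal SBML Level 3 + fbc subset is read for interoperability.

# FVSEOF

`fvseof()` enforces succinate export at `n_steps = 10` evenly spaced
levels between the FVA minimum ("base": what the network already commits
to at 95% growth) and base + 0.9 x (vmax - base), recomputes FVA at each
level (the growth floor is re-derived from the maximal growth attainable
*at that level*), regresses each reaction's minimum flux on the enforced
level by ordinary least squares, and selects reactions with positive
V$_{min}$ slope, a non-decreasing series, and positive V$_{min}$ at the
top level. The top level is placed *inside* the attainable range by
interpolation — equivalent to the conventional "fraction of the maximum"
when the base is zero, but still feasible on growth-coupled networks
where the base exceeds 90% of the maximum.

The number of levels, the slope threshold ($10^{-6}$), and whether the
flux cap applies inside the scan are not prescribed by the source
methodology; the defaults (10 levels, cap on) are documented package
choices, and the selected target set on the toy network is empirically
invariant to cap on/off, to the glycerol allowance, and to $\pm 20\%$
perturbation of the biomass coefficients.

Candidacy covers intracellular *enzymatic conversions* only: exchanges,
the enforced exchange itself, the biomass pseudo-reaction, and pure
transport steps (reactions that only translocate species unchanged
between compartments) are excluded. The last two exclusions matter on a
small network: the growth floor itself and the pyruvate-overflow exporter
both track enforced production arithmetically, but neither is an enzyme
one would amplify. The scan is run with both carbon channels open
(glucose 10 + glycerol 10 mmol gDCW$^{-1}$ h$^{-1}$); a toy network needs
the substrate-route degeneracy that a genome-scale model has natively, or
single catabolic steps become spuriously forced. Under these conditions
the scan selects exactly PCKA, MDH, FUMC and FRD — the four
reductive-branch enzymes.

# Flux-sum analysis

For a flux distribution $v$, the flux-sum of metabolite $i$ is
$\Phi_i = \tfrac12 \sum_j |S_{ij} v_j|$ — the turnover rate of its pool,
with production and consumption halves equal at steady state. The
conventional $\tfrac12$ factor is the default; the unhalved in-plus-out
sum is available with `halved = FALSE` because prose definitions of
"summation of all fluxes in or out" are ambiguous between the two.
Profiles are computed from the parsimonious point distribution (the
bounded-range alternative from FVA envelopes was considered and left
out of scope as the source analyses report point distributions), restricted
to cytosolic metabolites. `compare_media_flux_sums()` contrasts glucose
(10) against the equal-carbon dual feed (glucose 5 + glycerol 10);
`nadh_yield_per_glucose_equivalent()` probes the assimilation
stoichiometry directly — close all uptakes, admit one glucose-equivalent
(1 glucose or 2 glycerol), drain PEP freely, count NADH through a
NADH $\to$ NAD$^+$ drain, and maximize the count. On the toy network the
yields are 2.0 (glucose) and 4.0 (glycerol) NADH per glucose-equivalent:
the factor-two reducing-equivalent advantage of glycerol that motivates
dual-carbon feeding.

# Enzyme kinetics

The rate law is the uncompetitive substrate-inhibition (Haldane) form
$$ v = \frac{k_{cat} S}{K_m + S + S^2/K_i}, $$
which reduces to Michaelis-Menten as $K_i \to \infty$ and peaks at
$S^* = \sqrt{K_m K_i}$. The "modified Briggs-Haldane" variant cited for
the original fits is not printed in an accessible form; this standard
form was verified self-consistent with the published parameter table
(printed $k_{cat}/K_m$ equals $k_{cat} \div K_m$ at printed precision,
worst deviation 0.052 at one decimal).

`fit_substrate_inhibition()` minimizes squared *relative* residuals
$((v - \hat v)/\hat v)^2$ — the correct weighting for assay noise with a
constant coefficient of variation — over log-parameters (positivity by
construction), from a deterministic 3 x 3 multi-start grid ($K_m$ from
substrate-grid quartiles, $K_i$ from {max S, 10 max S, $10^8$}), polished
by Levenberg-Marquardt. Standard errors come from the asymptotic
covariance $\sigma^2 (J^\top J)^{-1}$ on the log scale, delta-transformed.
A Michaelis-Menten reference fit decides the no-inhibition flag: if the
inhibition term does not improve the weighted SSE, or $K_i$ runs beyond
$10^4 \times$ max S, the fit reports $K_i = \infty$ (mirroring the "not
determinable, extremely high" entries in the published table). With 5%
CV noise and 3 replicates on a 12-point grid, a 200-replicate simulation
recovers each parameter with |bias| < 5% and $\ge 90\%$ coverage of
$\pm 2$ SE intervals (asserted in the suite).

pH handling: parameter sets are tabulated per pH unit; physiological
evaluation (`physiological_velocity()`, default pH 6.86 and 26.11 uM
oxaloacetate — the measured intracellular state of the production strain)
interpolates parameters linearly in log space between bracketing pH
values and refuses to extrapolate. Log-linear interpolation is a modeling
choice, not a claim from the source. The assay-signal conversion uses
Beer-Lambert with the NADH extinction coefficient 6.22 mM$^{-1}$
cm$^{-1}$ at 340 nm.

# Fermentation indices

`compute_indices()` reduces a fed-batch time series to: titer (final
product concentration), yield in mol SA per mol glucose equivalent
(glycerol counts half a glucose, matching its carbon content; consumed
substrate = initial + cumulative feed - residual under a constant
working-volume approximation), overall productivity (titer / elapsed
time), maximum productivity (largest one-interval increment rate — the
original window convention is unstated, one sampling interval is the
package's convention), and specific productivity (titer divided by
trapezoidal time-averaged biomass x duration; the original averaging
convention is likewise unstated). OD600 converts to dry cell weight with
the strain's published factor 0.451 gDCW L$^{-1}$ per OD unit.

The profile generator embeds exact ground truth: a logistic biomass
curve, a piecewise-linear product curve whose ramp runs at the target
maximum productivity with kinks snapped to sampling points (so the
sampled data carry the exact interval slopes), and substrate consumption
back-computed from the target yield. Noiseless round trips recover every
index to $10^{-6}$ relative; multiplicative measurement noise is seeded
and reproducible.

What the generator does *not* emulate: volume changes from feeding and
base addition, product inhibition and lag phases, byproduct dynamics,
and measurement-correlated errors. Passing round-trip tests therefore
validates the index arithmetic, not any fermentation biology.

# Problem sizes and runtime

All analyses are desk-scale by design: the toy network has ~30 reactions,
an FVSEOF scan solves ~500 LPs in about a second, the full test suite
(including the 200-replicate fit-calibration simulation and the COBRApy
cross-check) runs in well under a minute, and the acceptance script in
seconds.

# Known limitations

* The toy network is a structural stand-in. Its biomass equation,
  maintenance demand and uptake rates are package choices, not the
  organism's measured values; target identification on it demonstrates
  the algorithm, not a genome-scale prediction.
* The simplex is dense and single-threaded; it is sized for
  hundreds-of-reactions models, not thousands.
* The kinetic module fits single-substrate laws at fixed cosubstrate;
  bi-substrate mechanisms and the reverse (malate-oxidizing) direction
  are out of scope.
* Wet-lab outcomes (titers around 100-134 g/L etc.) are inputs for the
  index arithmetic, not reproducible quantities; nothing in the package
  claims to predict them.
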