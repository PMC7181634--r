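#' Build the toy succinate-production network
#'
#' Constructs a small single-cell stoichiometric model of the reductive-TCA
#' succinate route of a capnophilic rumen bacterium: lumped glycolysis (two
#' parallel isoroutes, EMP/ED-style, so no single glucose-to-PEP step is
#' stoichiometrically forced), lumped glycerol assimilation (likewise two
#' parallel routes, kinase- and dehydrogenase-style), the
#' PEP-carboxykinase / malate-dehydrogenase / fumarase / fumarate-reductase
#' backbone, two NADH:menaquinone oxidoreductase isoenzymes (as in bacterial
#' ndh-1/ndh-2), formate dehydrogenase feeding the quinone pool, the
#' pyruvate-node byproduct pathways (lactate, formate, acetate, pyruvate
#' overflow), a decarboxylating malic enzyme, ATP maintenance, and a biomass
#' pseudo-reaction drawing pyruvate, oxaloacetate, ATP and NADH (anabolic
#' reducing power). Boundary metabolites are tagged extracellular
#' (\code{_e}); cofactor pools (NAD/NADH, ADP/ATP, MQ/MQH2) are closed.
#'
#' The wild-type network is returned; apply
#' \code{knockout_reactions(m, c("LDHA", "PTA", "ACKA"))} (see
#' \code{\link{palk_knockouts}}) for the homo-succinate production genotype.
#'
#' @param include_cycle_pair include an isolated reversible 2-cycle
#'   (\code{CYC1}/\code{CYC2}: X <-> Y twice) that carries no net
#'   stoichiometry, for loop-handling tests.
#' @param atpm_lower_bound non-growth maintenance ATP demand, mmol/gDCW/h.
#' @param biomass_coeffs named numeric: pyruvate (\code{pyr}), oxaloacetate
#'   (\code{oaa}), ATP (\code{atp}) and NADH (\code{nadh}) drawn per unit
#'   biomass.
#' @param glc_uptake,gol_uptake,co2_uptake default allowed uptake
#'   magnitudes, mmol/gDCW/h (glycerol closed by default).
#' @return a validated \code{sm_model} with objective \code{BIOMASS}.
#' @export
build_toy_model <- function(include_cycle_pair = TRUE,
                            atpm_lower_bound = 1,
                            biomass_coeffs = c(pyr = 1, oaa = 0.5,
                                               atp = 10, nadh = 0.5),
                            glc_uptake = 10, gol_uptake = 0,
                            co2_uptake = 1000) {
  bc <- biomass_coeffs
  stopifnot(all(c("pyr", "oaa", "atp", "nadh") %in% names(bc)), all(bc > 0))
  rows <- list(
    c("GLY1", "1 GLC_e + 2 NAD_c + 2 ADP_c -> 2 PEP_c + 2 NADH_c + 2 ATP_c",
      0, 1000, "glycolysis"),
    c("GLY2", "1 GLC_e + 2 NAD_c + 2 ADP_c -> 2 PEP_c + 2 NADH_c + 2 ATP_c",
      0, 1000, "glycolysis"),
    c("GOLU1", "1 GOL_e + 2 NAD_c -> 1 PEP_c + 2 NADH_c",
      0, 1000, "glycerol assimilation"),
    c("GOLU2", "1 GOL_e + 2 NAD_c -> 1 PEP_c + 2 NADH_c",
      0, 1000, "glycerol assimilation"),
    c("PCKA", "1 PEP_c + 1 CO2_e + 1 ADP_c -> 1 OAA_c + 1 ATP_c",
      0, 1000, "anaplerosis"),
    c("MDH", "1 OAA_c + 1 NADH_c <=> 1 MAL_c + 1 NAD_c",
      -1000, 1000, "reductive TCA"),
    c("FUMC", "1 MAL_c <=> 1 FUM_c", -1000, 1000, "reductive TCA"),
    c("FRD", "1 FUM_c + 1 MQH2_c -> 1 SUC_e + 1 MQ_c", 0, 1000, "reductive TCA"),
    c("NDH1", "1 NADH_c + 1 MQ_c -> 1 NAD_c + 1 MQH2_c",
      0, 1000, "respiration"),
    c("NDH2", "1 NADH_c + 1 MQ_c -> 1 NAD_c + 1 MQH2_c",
      0, 1000, "respiration"),
    c("FDH", "1 FOR_e + 1 MQ_c -> 1 CO2_e + 1 MQH2_c", 0, 1000, "respiration"),
    c("PYK", "1 PEP_c + 1 ADP_c -> 1 PYR_c + 1 ATP_c", 0, 1000, "glycolysis"),
    c("LDHA", "1 PYR_c + 1 NADH_c -> 1 LAC_e + 1 NAD_c",
      0, 1000, "byproduct"),
    c("PFL", "1 PYR_c -> 1 ACO_c + 1 FOR_e", 0, 1000, "byproduct"),
    c("PTA", "1 ACO_c -> 1 ACP_c", 0, 1000, "byproduct"),
    c("ACKA", "1 ACP_c + 1 ADP_c -> 1 ACT_e + 1 ATP_c", 0, 1000, "byproduct"),
    c("PYRX", "1 PYR_c -> 1 PYR_e", 0, 1000, "byproduct"),
    c("ME", "1 MAL_c + 1 NAD_c -> 1 PYR_c + 1 CO2_e + 1 NADH_c",
      0, 1000, "anaplerosis"),
    c("ATPM", "1 ATP_c -> 1 ADP_c", atpm_lower_bound, 1000, "maintenance"),
    c("BIOMASS",
      sprintf("%g PYR_c + %g OAA_c + %g ATP_c + %g NADH_c -> 1 BIOM_e + %g ADP_c + %g NAD_c",
              bc[["pyr"]], bc[["oaa"]], bc[["atp"]], bc[["nadh"]],
              bc[["atp"]], bc[["nadh"]]),
      0, 1000, "biomass"),
    c("EX_glc", "1 GLC_e ->", -glc_uptake, 1000, "exchange"),
    c("EX_gol", "1 GOL_e ->", -gol_uptake, 1000, "exchange"),
    c("EX_co2", "1 CO2_e ->", -co2_uptake, 1000, "exchange"),
    c("EX_suc", "1 SUC_e ->", 0, 1000, "exchange"),
    c("EX_lac", "1 LAC_e ->", 0, 1000, "exchange"),
    c("EX_for", "1 FOR_e ->", 0, 1000, "exchange"),
    c("EX_act", "1 ACT_e ->", 0, 1000, "exchange"),
    c("EX_pyr", "1 PYR_e ->", 0, 1000, "exchange"),
    c("EX_biom", "1 BIOM_e ->", 0, 1000, "exchange"))
  if (include_cycle_pair) {
    rows <- c(rows, list(
      c("CYC1", "1 X_c <=> 1 Y_c", -1000, 1000, "loop test"),
      c("CYC2", "1 X_c <=> 1 Y_c", -1000, 1000, "loop test")))
  }
  ids <- vapply(rows, `[`, character(1), 1)
  stoich <- stats::setNames(
    lapply(rows, function(r) parse_equation(r[2])$stoich), ids)
  met_ids <- sort(unique(unlist(lapply(stoich, names))))
  sm_model(
    tibble::tibble(id = met_ids, name = met_ids,
                   compartment = sub("^.*_", "", met_ids)),
    tibble::tibble(id = ids,
                   lb = as.numeric(vapply(rows, `[`, character(1), 3)),
                   ub = as.numeric(vapply(rows, `[`, character(1), 4)),
                   subsystem = vapply(rows, `[`, character(1), 5)),
    stoich, "BIOMASS")
}

#' Reaction deletions mimicking the homo-succinate production genotype
#'
#' The production strain carries deletions of lactate dehydrogenase,
#' phosphotransacetylase and acetate kinase, removing the lactate and
#' acetate byproduct routes.
#'
#' @return character vector of reaction ids to knock out.
#' @export
palk_knockouts <- function() c("LDHA", "PTA", "ACKA")

#' Simulate an enzyme-assay dataset from substrate-inhibition truth
#'
#' Evaluates the uncompetitive substrate-inhibition rate law
#' v = kcat*S/(km + S + S^2/ki) on a substrate grid and applies
#' multiplicative Gaussian noise (coefficient of variation
#' \code{noise_cv}) to each replicate. Seeded and reproducible.
#'
#' @param params named list/vector with \code{kcat} (1/s), \code{km} (uM),
#'   \code{ki} (uM; may be \code{Inf} for pure Michaelis-Menten).
#' @param s_grid substrate concentrations, uM. The default spans well below
#'   and above the velocity optimum sqrt(km*ki) of every tabulated enzyme.
#' @param noise_cv multiplicative noise CV (0 = noiseless).
#' @param replicates replicates per concentration.
#' @param seed RNG seed.
#' @param enzyme,ph labels carried into the output.
#' @return tibble of assay points: \code{enzyme}, \code{ph},
#'   \code{replicate}, \code{conc_uM}, \code{velocity_per_s}.
#' @export
generate_assay_dataset <- function(params,
                                   s_grid = c(2, 5, 10, 20, 40, 60, 100,
                                              150, 250, 400, 650, 1000),
                                   noise_cv = 0, replicates = 1L, seed = 1L,
                                   enzyme = "enzyme", ph = NA_real_) {
  stopifnot(all(s_grid >= 0), noise_cv >= 0, replicates >= 1)
  sopt <- sqrt(params[["km"]] * params[["ki"]])
  if (is.finite(sopt) && (min(s_grid) > sopt || max(s_grid) < sopt))
    warning("substrate grid does not span the velocity optimum sqrt(km*ki)")
  set.seed(seed)
  pts <- expand.grid(replicate = seq_len(replicates), conc_uM = s_grid)
  v <- substrate_inhibition_velocity(params, pts$conc_uM)
  if (noise_cv > 0) v <- v * (1 + stats::rnorm(length(v), 0, noise_cv))
  tibble::tibble(enzyme = enzyme, ph = ph, replicate = pts$replicate,
                 conc_uM = pts$conc_uM, velocity_per_s = pmax(v, 0))
}

#' Simulate a fed-batch fermentation profile with known production indices
#'
#' Builds a time series with a logistic biomass curve, piecewise-linear
#' product accumulation reaching the target titer with a prescribed maximum
#' productivity, and substrate consumption consistent with the target
#' glucose-equivalent yield (split between glucose and glycerol by
#' \code{glycerol_fraction} of glucose-equivalents). Substrate is supplied
#' as an initial charge plus a cumulative feed so that residual
#' concentrations stay positive. The embedded ground truth is returned
#' alongside the profile.
#'
#' @param titer final product concentration, g/L.
#' @param overall_productivity titer / duration, g/L/h (sets the duration).
#' @param max_productivity peak interval productivity, g/L/h; must be >=
#'   overall productivity.
#' @param yield_mol_per_mol mol product per mol glucose equivalent.
#' @param glycerol_fraction fraction of consumed glucose-equivalents
#'   supplied as glycerol (0 = glucose only).
#' @param dcw_max,dcw0 logistic biomass ceiling and inoculum, gDCW/L.
#' @param sampling_interval_h sampling interval, h.
#' @param noise_cv multiplicative measurement noise CV (0 = noiseless).
#' @param seed RNG seed.
#' @return list with \code{profile} (tibble: time_h, od600, dcw_g_l,
#'   glucose_g_l, glycerol_g_l, succinate_g_l, fed_glucose_g_l,
#'   fed_glycerol_g_l) and \code{truth} (the implied
#'   \code{production_indices}).
#' @export
generate_fermentation_profile <- function(titer = 100,
                                          overall_productivity = 4,
                                          max_productivity = 8,
                                          yield_mol_per_mol = 1.3,
                                          glycerol_fraction = 0.3,
                                          dcw_max = 10, dcw0 = 0.5,
                                          sampling_interval_h = 1,
                                          noise_cv = 0, seed = 1L) {
  if (max_productivity < overall_productivity)
    stop("max_productivity must be >= overall_productivity (internally ",
         "consistent targets required)")
  stopifnot(titer > 0, overall_productivity > 0, yield_mol_per_mol > 0,
            glycerol_fraction >= 0, glycerol_fraction <= 1)
  mm <- molar_masses()
  duration <- titer / overall_productivity
  tt <- seq(0, duration, by = sampling_interval_h)
  if (tt[length(tt)] < duration) tt <- c(tt, duration)

  ## piecewise-linear product curve: a ramp at max_productivity through the
  ## middle of the run, slower shoulders chosen to hit the target titer.
  ## Kinks are snapped to sampling points so the sampled curve carries the
  ## exact interval slopes (the embedded truth is recoverable exactly).
  if (max_productivity > overall_productivity) {
    n_int <- length(tt) - 1L
    ramp_int <- max(1L, min(n_int - 2L,
                            floor(0.5 * titer / max_productivity /
                                  sampling_interval_h)))
    i1 <- max(2L, (n_int - ramp_int) %/% 2L)
    t1 <- tt[i1]; t2 <- tt[i1 + ramp_int]
    ramp_gain <- max_productivity * (t2 - t1)
    shoulder_rate <- (titer - ramp_gain) / (duration - (t2 - t1))
    if (shoulder_rate < 0 || shoulder_rate > max_productivity)
      stop("targets inconsistent: no piecewise-linear curve attains both ",
           "the titer and the maximum productivity")
    sa <- ifelse(tt <= t1, shoulder_rate * tt,
          ifelse(tt <= t2, shoulder_rate * t1 + max_productivity * (tt - t1),
                 shoulder_rate * t1 + ramp_gain + shoulder_rate * (tt - t2)))
    sa[length(sa)] <- titer
  } else {
    sa <- overall_productivity * tt  # constant-rate: max == overall
  }

  ## substrate consumption tracking product formation at the target yield
  geq_consumed <- (sa / mm[["succinate"]]) / yield_mol_per_mol  # mol/L
  glc_consumed_g <- geq_consumed * (1 - glycerol_fraction) * mm[["glucose"]]
  gly_consumed_g <- geq_consumed * glycerol_fraction * 2 * mm[["glycerol"]]

  glc0 <- 18.02; gly0 <- if (glycerol_fraction > 0) 4.60 else 0
  resid_glc <- glc0 * (0.4 + 0.6 * (1 - tt / duration))   # drifts 18 -> 7.2
  resid_gly <- gly0 * (0.4 + 0.6 * (1 - tt / duration))
  fed_glc <- pmax(0, glc_consumed_g + resid_glc - glc0)
  fed_gly <- pmax(0, gly_consumed_g + resid_gly - gly0)
  fed_glc <- cummax(fed_glc); fed_gly <- cummax(fed_gly)

  ## logistic biomass anchored at dcw(0) = dcw0
  k <- 10 / duration
  dcw <- dcw_max / (1 + (dcw_max / dcw0 - 1) * exp(-k * tt))

  prof <- tibble::tibble(
    time_h = tt, od600 = dcw / 0.451, dcw_g_l = dcw,
    glucose_g_l = resid_glc, glycerol_g_l = resid_gly,
    succinate_g_l = sa,
    fed_glucose_g_l = fed_glc, fed_glycerol_g_l = fed_gly)
  if (noise_cv > 0) {
    set.seed(seed)
    noisy <- function(x) pmax(0, x * (1 + stats::rnorm(length(x), 0, noise_cv)))
    prof$od600 <- noisy(prof$od600)
    prof$dcw_g_l <- prof$od600 * 0.451
    prof$glucose_g_l <- noisy(prof$glucose_g_l)
    prof$glycerol_g_l <- noisy(prof$glycerol_g_l)
    prof$succinate_g_l[-1] <- noisy(prof$succinate_g_l[-1])
  }

  ## time-averaged biomass by trapezoidal integration (matches
  ## compute_indices' specific-productivity convention)
  dcw_mean <- sum((dcw[-1] + dcw[-length(dcw)]) / 2 * diff(tt)) / duration
  truth <- production_indices(
    titer = titer,
    yield_mol_per_mol = yield_mol_per_mol,
    overall_productivity = overall_productivity,
    max_productivity = max_productivity,
    specific_productivity = titer / (dcw_mean * duration),
    max_dcw = max(dcw))
  list(profile = prof, truth = truth)
}
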