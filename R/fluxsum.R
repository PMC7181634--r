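#' Flux-sum (metabolite turnover) profile of a flux distribution
#'
#' The flux-sum of metabolite i is half the sum of absolute
#' stoichiometry-weighted fluxes incident to it,
#' Phi_i = 1/2 sum_j |S_ij v_j| (mmol/gDCW/h). At steady state the
#' production half equals the consumption half, so Phi_i is the turnover
#' rate of the metabolite pool. Set \code{halved = FALSE} to report the
#' unhalved in-plus-out sum (2 Phi).
#'
#' @param model a valid \code{sm_model}.
#' @param dist a steady-state \code{flux_distribution}.
#' @param compartment compartment tag to restrict to (default "c",
#'   cytosol).
#' @param halved apply the conventional 1/2 factor (default TRUE).
#' @return tibble: metabolite, flux_sum; attribute \code{compartment}.
#' @export
compute_flux_sum <- function(model, dist, compartment = "c", halved = TRUE) {
  if (!compartment %in% model$mets$compartment)
    stop("unknown compartment tag: ", compartment)
  if (is.null(dist$fluxes)) stop("distribution has no flux vector")
  S <- s_matrix(model)
  v <- dist$fluxes[colnames(S)]
  phi <- rowSums(abs(S * rep(v, each = nrow(S))))
  if (halved) phi <- phi / 2
  keep <- model$mets$compartment == compartment
  out <- tibble::tibble(metabolite = model$mets$id[keep],
                        flux_sum = unname(phi[match(model$mets$id[keep],
                                                    rownames(S))]))
  attr(out, "compartment") <- compartment
  out
}

#' Compare cofactor turnover between two media
#'
#' Runs parsimonious FBA (maximizing biomass) under each medium, computes
#' the cytosolic flux-sum of the requested metabolites and reports the
#' ratio medium B over medium A. The production-strain comparison of
#' interest is single-carbon A = glucose 10 versus dual-carbon B =
#' glucose 5 + glycerol 10 mmol/gDCW/h (equal carbon input).
#'
#' @param model a valid \code{sm_model}.
#' @param mediumA,mediumB named uptake vectors for \code{\link{set_medium}}.
#' @param metabolite_ids cytosolic metabolite ids to report.
#' @return tibble: metabolite, phi_A, phi_B, ratio (B/A; NA where
#'   phi_A = 0).
#' @export
compare_media_flux_sums <- function(model, mediumA, mediumB, metabolite_ids) {
  comp <- model$mets$compartment[match(metabolite_ids, model$mets$id)]
  if (anyNA(comp)) stop("unknown metabolite: ",
                        metabolite_ids[is.na(comp)][1])
  if (any(comp != "c"))
    stop("flux-sum comparison is cytosol-only; not cytosolic: ",
         metabolite_ids[comp != "c"][1])
  phi_of <- function(medium) {
    d <- solve_pfba(set_medium(model, medium))
    if (d$status != "optimal") stop("medium infeasible: pFBA ", d$status)
    fs <- compute_flux_sum(model, d, "c")
    fs$flux_sum[match(metabolite_ids, fs$metabolite)]
  }
  a <- unname(phi_of(mediumA)); b <- unname(phi_of(mediumB))
  tibble::tibble(metabolite = metabolite_ids, phi_A = a, phi_B = b,
                 ratio = ifelse(a > 0, b / a, NA_real_))
}

#' Maximum NADH yield per mol glucose equivalent
#'
#' LP probe of the reducing-equivalent stoichiometry of a substrate's
#' assimilation route: all uptakes are closed except the given substrate at
#' one glucose-equivalent (1 mol glucose or 2 mol glycerol), PEP is given a
#' free drain (downstream metabolism is not the question), NADH a counting
#' drain (NADH -> NAD), maintenance and biomass are silenced, and the
#' counting drain is maximized.
#'
#' @param model a valid \code{sm_model} containing \code{PEP_c},
#'   \code{NADH_c}/\code{NAD_c} and the substrate exchange.
#' @param substrate_exchange exchange id, e.g. "EX_glc" or "EX_gol".
#' @param mol_per_geq mol substrate per mol glucose equivalent; inferred
#'   (glucose 1, glycerol 2) from the exchanged metabolite when NULL.
#' @return mol NADH per mol glucose equivalent.
#' @export
nadh_yield_per_glucose_equivalent <- function(model, substrate_exchange,
                                              mol_per_geq = NULL) {
  i <- match(substrate_exchange, model$rxns$id)
  if (is.na(i) || !model$rxns$is_exchange[i])
    stop("not an exchange reaction: ", substrate_exchange)
  if (is.null(mol_per_geq)) {
    met <- names(model$stoich[[substrate_exchange]])
    known <- c(GLC_e = 1, GOL_e = 2)
    if (!met %in% names(known))
      stop("cannot infer glucose-equivalent stoichiometry for ", met,
           "; supply mol_per_geq")
    mol_per_geq <- known[[met]]
  }
  m <- model
  ex <- m$rxns$is_exchange
  m$rxns$lb[ex] <- pmax(m$rxns$lb[ex], 0)          # close all uptakes
  m$rxns$lb[i] <- -mol_per_geq                     # one glucose equivalent
  if ("BIOMASS" %in% m$rxns$id)
    m <- knockout_reactions(m, "BIOMASS")
  if ("ATPM" %in% m$rxns$id)
    m$rxns$lb[m$rxns$id == "ATPM"] <- 0
  m <- add_reaction(m, "PEP_DRAIN", "1 PEP_c ->", 0, 1000, "probe")
  m <- add_reaction(m, "NADH_COUNT", "1 NADH_c -> 1 NAD_c", 0, 1000, "probe")
  m$objective_id <- "NADH_COUNT"
  d <- solve_fba(m)
  if (d$status != "optimal") stop("yield probe LP ", d$status)
  if (d$objective_value <= 1e-9)
    warning("no NADH-generating route from ", substrate_exchange, " to PEP")
  d$objective_value
}
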