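#' Build the enforced-production schedule for an FVSEOF scan
#'
#' Determines the feasible range of the target exchange at the required
#' growth fraction by FVA, then lays out \code{n_steps} evenly spaced
#' enforcement levels from the base (the FVA minimum, i.e. the production
#' the network already commits to at that growth) up to
#' \code{base + top_fraction * (vmax - base)}. The top level is strictly
#' inside the attainable range for any \code{top_fraction < 1}, so every
#' level is enforceable.
#'
#' @param model a valid \code{sm_model}.
#' @param target_id exchange reaction id of the target product.
#' @param n_steps number of enforcement levels (>= 2).
#' @param growth_fraction objective floor used throughout the scan.
#' @param top_fraction position of the top level within (vmin, vmax].
#' @return list of class \code{enforcement_schedule}: target_id, levels,
#'   n_steps, base_level, top_fraction, growth_fraction.
#' @export
compute_enforcement_schedule <- function(model, target_id, n_steps = 10,
                                         growth_fraction = 0.95,
                                         top_fraction = 0.9) {
  stopifnot(n_steps >= 2, top_fraction > 0, top_fraction <= 1)
  i <- match(target_id, model$rxns$id)
  if (is.na(i)) stop("unknown target reaction: ", target_id)
  if (!model$rxns$is_exchange[i])
    stop("target must be an exchange reaction: ", target_id)
  fr <- run_fva(model, growth_fraction, reactions = target_id)
  base <- fr$vmin; top <- base + top_fraction * (fr$vmax - base)
  if (top <= base + 1e-9)
    stop("target ", target_id, " has no enforceable range at growth ",
         "fraction ", growth_fraction, " (vmin ", signif(base, 6),
         ", vmax ", signif(fr$vmax, 6), ")")
  structure(list(target_id = target_id,
                 levels = seq(base, top, length.out = n_steps),
                 n_steps = n_steps, base_level = base,
                 top_fraction = top_fraction,
                 growth_fraction = growth_fraction),
            class = "enforcement_schedule")
}

#' Scan flux variability under enforced target production
#'
#' For each enforcement level the target exchange's lower bound is raised
#' to the level and flux variability (with the optional total-flux cap and
#' cycle removal) is recomputed for every non-exchange reaction plus the
#' target itself; the growth floor is re-derived from the maximal growth
#' attainable at that level. The input model is unmodified.
#'
#' @param model a valid \code{sm_model}.
#' @param schedule an \code{enforcement_schedule}.
#' @param flux_cap_fraction passed to \code{\link{run_fva}} (NULL = no cap).
#' @param loopless passed to \code{\link{run_fva}}.
#' @return list of class \code{fvseof_result}: schedule, vmin and vmax
#'   matrices (reactions x levels), reaction ids.
#' @export
scan_enforced_flux <- function(model, schedule, flux_cap_fraction = 0.10,
                               loopless = FALSE) {
  stopifnot(inherits(schedule, "enforcement_schedule"))
  ti <- match(schedule$target_id, model$rxns$id)
  scan_ids <- model$rxns$id[!model$rxns$is_exchange |
                            model$rxns$id == schedule$target_id]
  L <- schedule$levels
  vmin <- vmax <- matrix(NA_real_, length(scan_ids), length(L),
                         dimnames = list(scan_ids, NULL))
  for (k in seq_along(L)) {
    m <- model
    m$rxns$lb[ti] <- max(m$rxns$lb[ti], L[k])
    fr <- tryCatch(
      run_fva(m, schedule$growth_fraction, flux_cap_fraction, loopless,
              reactions = scan_ids),
      error = function(e) stop("enforcement level ", signif(L[k], 8),
                               " (step ", k, ") failed: ",
                               conditionMessage(e), call. = FALSE))
    vmin[, k] <- fr$vmin
    vmax[, k] <- fr$vmax
  }
  structure(list(schedule = schedule, reaction_id = scan_ids,
                 vmin = vmin, vmax = vmax),
            class = "fvseof_result")
}

#' Regress minimum fluxes on the enforced production level
#'
#' Ordinary least squares of each reaction's Vmin series against the
#' enforcement levels (closed-form normal equations): the Vmin slope,
#' intercept and r-squared per reaction.
#'
#' @param result an \code{fvseof_result} from \code{\link{scan_enforced_flux}}.
#' @return the result with a \code{slopes} tibble added (reaction_id,
#'   slope, intercept, r_squared).
#' @export
regress_vmin_slopes <- function(result) {
  stopifnot(inherits(result, "fvseof_result"))
  x <- result$schedule$levels
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) stop("zero variance in enforcement levels")
  fit_one <- function(y) {
    slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
    int <- mean(y) - slope * mean(x)
    syy <- sum((y - mean(y))^2)
    r2 <- if (syy <= 1e-24) NA_real_ else slope^2 * sxx / syy
    c(slope, int, r2)
  }
  co <- t(apply(result$vmin, 1, fit_one))
  result$slopes <- tibble::tibble(reaction_id = result$reaction_id,
                                  slope = unname(co[, 1]),
                                  intercept = unname(co[, 2]),
                                  r_squared = unname(co[, 3]))
  result
}

#' Select amplification targets from an FVSEOF scan
#'
#' A reaction is an amplification target when its minimum flux rises with
#' the enforced production rate: Vmin slope above \code{slope_tol}, a
#' (numerically) non-decreasing Vmin series, and a strictly positive Vmin
#' at the top level (so a reversible reaction whose reverse flux merely
#' narrows toward zero is not flagged). Exchanges, the enforced target, the
#' biomass pseudo-reaction and pure transport steps (see
#' \code{\link{is_transport_reaction}}) are not candidates: the scan looks
#' for intracellular enzymatic conversions to amplify.
#'
#' @param result an \code{fvseof_result} with slopes computed.
#' @param model the scanned \code{sm_model} (identifies the objective).
#' @param slope_tol minimal Vmin slope.
#' @return the result with \code{targets} (ids, sorted by slope descending)
#'   and an \code{is_target} column in \code{slopes}.
#' @export
select_amplification_targets <- function(result, model, slope_tol = 1e-6) {
  stopifnot(inherits(result, "fvseof_result"), !is.null(result$slopes))
  ids <- result$reaction_id
  nondec <- apply(result$vmin, 1, function(y) all(diff(y) >= -1e-6))
  top_pos <- result$vmin[, ncol(result$vmin)] > 1e-9
  excluded <- ids == result$schedule$target_id | ids == model$objective_id |
    is_transport_reaction(model, ids)
  sl <- result$slopes$slope
  sel <- !excluded & sl > slope_tol & nondec & top_pos
  result$slopes$is_target <- sel
  result$targets <- ids[sel][order(sl[sel], decreasing = TRUE)]
  result
}

#' @export
print.fvseof_result <- function(x, ...) {
  cat(sprintf("<fvseof_result> %d reactions x %d levels (target %s)\n",
              length(x$reaction_id), length(x$schedule$levels),
              x$schedule$target_id))
  if (!is.null(x$targets))
    cat("amplification targets:", paste(x$targets, collapse = ", "), "\n")
  invisible(x)
}

#' Run a full FVSEOF analysis
#'
#' Convenience wrapper: schedule, scan, slope regression and target
#' selection in one call.
#'
#' @inheritParams compute_enforcement_schedule
#' @inheritParams scan_enforced_flux
#' @inheritParams select_amplification_targets
#' @return an \code{fvseof_result} with slopes and targets.
#' @export
fvseof <- function(model, target_id, n_steps = 10, growth_fraction = 0.95,
                   top_fraction = 0.9, flux_cap_fraction = 0.10,
                   loopless = FALSE, slope_tol = 1e-6) {
  sched <- compute_enforcement_schedule(model, target_id, n_steps,
                                        growth_fraction, top_fraction)
  res <- scan_enforced_flux(model, sched, flux_cap_fraction, loopless)
  res <- regress_vmin_slopes(res)
  select_amplification_targets(res, model, slope_tol)
}

#' Export an FVSEOF result as a tidy table
#'
#' @param result an \code{fvseof_result} with slopes.
#' @return tibble: reaction_id, slope, r_squared, is_target and one
#'   \code{vmin_<k>} column per enforcement level.
#' @export
fvseof_table <- function(result) {
  stopifnot(!is.null(result$slopes))
  vm <- result$vmin
  colnames(vm) <- sprintf("vmin_%d", seq_len(ncol(vm)))
  tibble::as_tibble(cbind(result$slopes[, c("reaction_id", "slope",
                                            "r_squared", "is_target")],
                          as.data.frame(vm)))
}
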