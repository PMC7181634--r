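#' Constrain uptake rates of exchange reactions
#'
#' Sets the lower bound of each listed exchange reaction to minus the given
#' uptake magnitude (uptake is a negative exchange flux in the
#' export-positive convention). Unlisted exchanges keep their bounds. The
#' input model is not modified (value semantics).
#'
#' @param model a \code{sm_model}.
#' @param medium named numeric vector: exchange reaction id -> allowed
#'   uptake magnitude in mmol/gDCW/h (non-negative).
#' @return a new \code{sm_model}.
#' @export
set_medium <- function(model, medium) {
  if (length(medium) == 0L) return(model)
  ids <- names(medium)
  unknown <- setdiff(ids, model$rxns$id)
  if (length(unknown)) stop("unknown exchange reaction: ", unknown[1])
  nonex <- ids[!model$rxns$is_exchange[match(ids, model$rxns$id)]]
  if (length(nonex)) stop("not an exchange reaction: ", nonex[1])
  if (any(medium < 0)) stop("uptake magnitudes must be non-negative")
  model$rxns$lb[match(ids, model$rxns$id)] <- -as.numeric(medium)
  model
}

#' Knock out reactions
#'
#' Forces both flux bounds of the given reactions to zero (reaction-level
#' deletions; no gene-protein-reaction logic).
#'
#' @param model a \code{sm_model}.
#' @param ids character vector of reaction ids.
#' @return a new \code{sm_model}.
#' @export
knockout_reactions <- function(model, ids) {
  if (length(ids) == 0L) return(model)
  unknown <- setdiff(ids, model$rxns$id)
  if (length(unknown)) stop("unknown reaction id: ", unknown[1])
  i <- match(ids, model$rxns$id)
  model$rxns$lb[i] <- 0
  model$rxns$ub[i] <- 0
  model
}

new_flux_distribution <- function(fluxes, objective_value, status) {
  structure(list(fluxes = fluxes, objective_value = objective_value,
                 status = status),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat(sprintf("<flux_distribution> status %s, objective %.6g, %d reactions\n",
              x$status, x$objective_value, length(x$fluxes)))
  invisible(x)
}

#' Flux balance analysis
#'
#' Maximizes the model objective subject to steady state (S v = 0) and flux
#' bounds.
#'
#' @param model a valid \code{sm_model}.
#' @return a \code{flux_distribution} with fields \code{fluxes} (named by
#'   reaction id), \code{objective_value} and \code{status}
#'   ("optimal"/"infeasible"/"unbounded"); no flux vector unless optimal.
#' @export
solve_fba <- function(model) {
  validate_model(model)
  S <- s_matrix(model)
  obj <- as.numeric(model$rxns$id == model$objective_id)
  r <- lp_solve(obj, S, rep(0, nrow(S)), model$rxns$lb, model$rxns$ub,
                maximize = TRUE)
  if (r$status != "optimal")
    return(new_flux_distribution(NULL, NA_real_, r$status))
  new_flux_distribution(stats::setNames(r$x, model$rxns$id), r$objval, "optimal")
}

## split-variable LP skeleton shared by pFBA / capped FVA / cycle removal:
## v = vp - vn with vp in [max(lb,0), max(ub,0)], vn in [max(-ub,0), max(-lb,0)]
split_bounds <- function(lb, ub) {
  list(lp = pmax(lb, 0), up = pmax(ub, 0),
       ln = pmax(-ub, 0), un = pmax(-lb, 0))
}

#' Parsimonious flux balance analysis
#'
#' Two-stage LP: fix the objective at its FBA maximum, then minimize the sum
#' of absolute fluxes via flux splitting (v = v+ - v-, v+/- >= 0).
#'
#' @param model a valid \code{sm_model}.
#' @return a \code{flux_distribution} with an extra field
#'   \code{total_abs_flux}.
#' @export
solve_pfba <- function(model) {
  fba <- solve_fba(model)
  if (fba$status != "optimal") return(fba)
  S <- s_matrix(model)
  n <- ncol(S)
  sb <- split_bounds(model$rxns$lb, model$rxns$ub)
  A <- cbind(S, -S)
  iobj <- which(model$rxns$id == model$objective_id)
  objrow <- numeric(2L * n); objrow[iobj] <- 1; objrow[n + iobj] <- -1
  A <- rbind(A, objrow)
  b <- c(rep(0, nrow(S)), fba$objective_value)
  r <- lp_solve(rep(1, 2L * n), A, b, c(sb$lp, sb$ln), c(sb$up, sb$un),
                maximize = FALSE)
  if (r$status != "optimal")
    stop("pFBA stage-2 LP unexpectedly ", r$status)
  v <- r$x[seq_len(n)] - r$x[n + seq_len(n)]
  d <- new_flux_distribution(stats::setNames(v, model$rxns$id),
                             fba$objective_value, "optimal")
  d$total_abs_flux <- sum(abs(v))
  d
}

#' Sum of absolute fluxes
#'
#' @param dist a \code{flux_distribution} with fluxes.
#' @return numeric, \eqn{\sum_j |v_j|}.
#' @export
total_abs_flux <- function(dist) {
  if (is.null(dist$fluxes)) stop("distribution has no flux vector")
  sum(abs(dist$fluxes))
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to steady state, bounds and
#' an objective floor \code{v_obj >= growth_fraction * max}. With
#' \code{flux_cap_fraction} set, a parsimonious solution is computed first
#' and the total absolute flux of every FVA subproblem is capped at
#' \code{(1 + flux_cap_fraction)} times the parsimonious total (via flux
#' splitting). With \code{loopless = TRUE} each subproblem optimum is
#' post-processed by \code{\link{remove_thermodynamic_cycles}} and the
#' cycle-free flux of the scanned reaction is reported, so loop-only flux
#' does not inflate the envelope.
#'
#' @param model a valid \code{sm_model}.
#' @param growth_fraction fraction of the maximal objective enforced (0..1).
#' @param flux_cap_fraction allowed relative excess of total absolute flux
#'   over the parsimonious total (e.g. 0.10), or NULL for no cap.
#' @param loopless logical; apply cycle removal to each optimum.
#' @param reactions reaction ids to scan (default: all).
#' @return a \code{flux_range}: tibble with columns \code{reaction_id},
#'   \code{vmin}, \code{vmax}.
#' @export
run_fva <- function(model, growth_fraction = 0.95, flux_cap_fraction = NULL,
                    loopless = FALSE, reactions = NULL) {
  validate_model(model)
  stopifnot(growth_fraction >= 0, growth_fraction <= 1)
  fba <- solve_fba(model)
  if (fba$status != "optimal") stop("FBA not optimal: ", fba$status)
  iobj <- which(model$rxns$id == model$objective_id)
  lb <- model$rxns$lb; ub <- model$rxns$ub
  floor_obj <- growth_fraction * fba$objective_value
  lb[iobj] <- max(lb[iobj], floor_obj)
  if (lb[iobj] > ub[iobj] + 1e-9)
    stop("objective floor exceeds objective upper bound")
  S <- s_matrix(model)
  n <- ncol(S)
  if (is.null(reactions)) reactions <- model$rxns$id
  ridx <- match(reactions, model$rxns$id)
  if (anyNA(ridx)) stop("unknown reaction id in 'reactions'")

  cap_total <- NULL
  if (!is.null(flux_cap_fraction)) {
    pf <- solve_pfba(model)
    cap_total <- (1 + flux_cap_fraction) * pf$total_abs_flux
  }

  solve_sub <- function(j, maximize) {
    if (is.null(cap_total)) {
      obj <- numeric(n); obj[j] <- 1
      r <- lp_solve(obj, S, rep(0, nrow(S)), lb, ub, maximize = maximize)
    } else {
      sb <- split_bounds(lb, ub)
      ## sum(vp + vn) + slack = cap_total
      A <- rbind(cbind(S, -S, 0), c(rep(1, 2L * n), 1))
      b <- c(rep(0, nrow(S)), cap_total)
      obj <- numeric(2L * n + 1L); obj[j] <- 1; obj[n + j] <- -1
      r <- lp_solve(obj, A, b, c(sb$lp, sb$ln, 0), c(sb$up, sb$un, cap_total),
                    maximize = maximize)
    }
    if (r$status != "optimal")
      stop("FVA subproblem ", if (maximize) "max " else "min ",
           model$rxns$id[j], " is ", r$status,
           "; binding constraint: objective floor ", signif(floor_obj, 6),
           if (!is.null(cap_total)) paste0(" or flux cap ", signif(cap_total, 6))
           else "")
    v <- if (is.null(cap_total)) r$x else r$x[seq_len(n)] - r$x[n + seq_len(n)]
    if (loopless) {
      d <- new_flux_distribution(stats::setNames(v, model$rxns$id),
                                 v[iobj], "optimal")
      v <- remove_thermodynamic_cycles(d, model)$fluxes
    }
    v[j]
  }

  vmin <- vapply(ridx, solve_sub, numeric(1), maximize = FALSE)
  vmax <- vapply(ridx, solve_sub, numeric(1), maximize = TRUE)
  structure(tibble::tibble(reaction_id = model$rxns$id[ridx],
                           vmin = vmin, vmax = pmax(vmax, vmin)),
            class = c("flux_range", "tbl_df", "tbl", "data.frame"))
}

#' Remove thermodynamically infeasible cycles from a flux distribution
#'
#' CycleFreeFlux-style post-processing: holding every exchange flux and the
#' objective flux fixed at their input values, minimize the total absolute
#' internal flux with each internal reaction restricted to its input
#' direction and magnitude. Pure loops (net-zero stoichiometry cycles)
#' collapse to zero; loop-free distributions are returned unchanged. Always
#' feasible because the input is a witness.
#'
#' @param dist a steady-state feasible \code{flux_distribution}.
#' @param model the \code{sm_model} the distribution was computed on.
#' @return a \code{flux_distribution} with identical exchange fluxes and
#'   objective value.
#' @export
remove_thermodynamic_cycles <- function(dist, model, tol = 1e-9) {
  if (is.null(dist$fluxes)) stop("distribution has no flux vector")
  v0 <- dist$fluxes[model$rxns$id]
  fixed <- model$rxns$is_exchange | model$rxns$id == model$objective_id
  lb <- ifelse(fixed, v0, ifelse(v0 > tol, 0, ifelse(v0 < -tol, v0, 0)))
  ub <- ifelse(fixed, v0, ifelse(v0 > tol, v0, 0))
  obj <- ifelse(fixed, 0, sign(v0) * (abs(v0) > tol))
  S <- s_matrix(model)
  r <- lp_solve(obj, S, rep(0, nrow(S)), lb, ub, maximize = FALSE)
  if (r$status != "optimal")
    stop("cycle-removal LP unexpectedly ", r$status)
  out <- new_flux_distribution(stats::setNames(r$x, model$rxns$id),
                               dist$objective_value, dist$status)
  out$fluxes[fixed] <- v0[fixed]  # bit-identical exchange and objective flux
  out
}
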