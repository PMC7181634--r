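#' Published kinetic parameter sets for the three malate dehydrogenases
#'
#' Substrate-inhibition parameters (toward oxaloacetate) of the native
#' enzyme of the production strain (MsMDH), the Corynebacterium glutamicum
#' enzyme (CgMDH) and the engineered G11Q variant (MsMDH_G11Q), each at pH
#' 5-9, with their reported standard errors. \code{ki = Inf} encodes "no
#' measurable substrate inhibition". Units: kcat 1/s; km, ki uM; kcat_km
#' 1/s/uM.
#'
#' @return tibble with columns enzyme, ph, kcat, se_kcat, km, se_km,
#'   kcat_km, se_kcat_km, ki, se_ki.
#' @export
mdh_kinetic_params <- function() {
  tab <- rbind(
    c(5, 287.4,  93.5,  15.9,  9.0, 18.1, 3.9,  34.7,  15.9),
    c(6, 187.0,  29.6,  12.3,  3.6, 15.2, 0.9,  67.4,  18.6),
    c(7, 376.1, 119.1,  18.2, 10.5, 20.7, 4.5,  47.3,  22.1),
    c(8, 635.8, 312.6,  65.1, 45.3,  9.8, 3.5,  80.3,  59.1),
    c(9, 1310.9, 273.0, 143.3, 44.5,  9.1, 0.6, 500.1, 214.2),
    c(5, 617.8,  72.8,  61.4, 14.3, 10.1, 0.3, 716.1, 248.1),
    c(6, 689.1,  86.0,  52.0, 12.3, 13.3, 0.5, 588.9, 196.2),
    c(7, 919.8,  77.0,  46.1,  7.3, 19.9, 0.3, 500.0, 114.1),
    c(8, 524.8, 103.4,  47.8, 18.7, 11.0, 1.0, 786.4, 486.1),
    c(9, 213.2,   6.6,  30.2,  3.5,  7.1, 0.1,   Inf,    NA),
    c(5, 664.9,  62.8,  62.0,  9.1, 10.7, 0.2, 125.0,  19.1),
    c(6, 762.4, 204.6,  99.0, 39.0,  7.7, 0.9, 188.1,  80.1),
    c(7, 927.4, 152.4, 103.5, 25.9,  9.0, 0.4, 302.4,  92.7),
    c(8, 1005.4, 171.6,  94.1, 29.7, 10.7, 0.7, 914.3, 368.4),
    c(9, 1037.9, 186.6, 207.1, 53.2,  5.0, 0.2,   Inf,    NA))
  tibble::tibble(
    enzyme = rep(c("MsMDH", "CgMDH", "MsMDH_G11Q"), each = 5),
    ph = tab[, 1], kcat = tab[, 2], se_kcat = tab[, 3],
    km = tab[, 4], se_km = tab[, 5],
    kcat_km = tab[, 6], se_kcat_km = tab[, 7],
    ki = tab[, 8], se_ki = tab[, 9])
}

#' Measured physiological state of the production strain
#'
#' Intracellular pH and oxaloacetate concentration of the homo-succinate
#' production strain, used to evaluate in-vivo enzyme velocities.
#'
#' @param ph,ph_sd intracellular pH (mean, sd).
#' @param oaa_uM,oaa_sd_uM intracellular oxaloacetate, uM (mean, sd).
#' @return list with the four values.
#' @export
physiological_state <- function(ph = 6.86, ph_sd = 0.21,
                                oaa_uM = 26.11, oaa_sd_uM = 4.47) {
  stopifnot(ph > 0, ph < 14, oaa_uM >= 0)
  list(ph = ph, ph_sd = ph_sd, oaa_uM = oaa_uM, oaa_sd_uM = oaa_sd_uM)
}

#' Convert an absorbance slope to a volumetric rate
#'
#' Beer-Lambert conversion of the 340 nm NADH depletion slope using the
#' NADH extinction coefficient of 6.22 /mM/cm.
#'
#' @param dA340_per_min absorbance change per minute.
#' @param extinction_coeff /mM/cm (default 6.22, NADH at 340 nm).
#' @param path_length_cm cuvette path length, cm.
#' @return rate in uM/s.
#' @export
rate_from_absorbance <- function(dA340_per_min, extinction_coeff = 6.22,
                                 path_length_cm = 1) {
  if (extinction_coeff <= 0 || path_length_cm <= 0)
    stop("extinction coefficient and path length must be positive")
  mM_per_min <- dA340_per_min / (extinction_coeff * path_length_cm)
  mM_per_min * 1000 / 60
}

#' Uncompetitive substrate-inhibition rate law
#'
#' v = kcat * S / (km + S + S^2/ki). With \code{ki = Inf} this reduces to
#' the Michaelis-Menten law. The velocity peaks at S* = sqrt(km*ki) and
#' declines beyond it.
#'
#' @param params named list/vector with \code{kcat}, \code{km}, \code{ki}.
#' @param S substrate concentration(s), uM (non-negative).
#' @return turnover velocity, 1/s.
#' @export
substrate_inhibition_velocity <- function(params, S) {
  if (any(S < 0)) stop("substrate concentration must be non-negative")
  kcat <- params[["kcat"]]; km <- params[["km"]]; ki <- params[["ki"]]
  stopifnot(kcat > 0, km > 0, ki > 0)
  inhib <- if (is.finite(ki)) S^2 / ki else 0
  kcat * S / (km + S + inhib)
}

#' Catalytic efficiency
#' @param params named list/vector with \code{kcat}, \code{km}.
#' @return kcat/km, 1/s/uM.
#' @export
catalytic_efficiency <- function(params) {
  params[["kcat"]] / params[["km"]]
}

#' Fit the substrate-inhibition law to assay data
#'
#' Weighted nonlinear least squares on v = kcat*S/(km + S + S^2/ki):
#' relative residuals (v - vhat)/vhat are minimized, the appropriate
#' weighting for assay noise with a constant coefficient of variation.
#' Parameters are fitted in logs to enforce positivity, with deterministic
#' multi-start (km started from the quartiles of the substrate grid, ki
#' from {max S, 10 max S, effectively infinite}); the best start is
#' polished by Levenberg-Marquardt and standard errors are taken from the
#' asymptotic covariance sigma^2 (J'J)^-1. If the inhibition term does not improve the fit
#' (relative SSE improvement below \code{mm_tol}) or ki runs away beyond
#' \code{ki_cap} times the largest substrate concentration, a pure
#' Michaelis-Menten fit is reported with \code{ki = Inf} and
#' \code{inhibition = FALSE}.
#'
#' @param points data frame with columns \code{conc_uM} and
#'   \code{velocity_per_s} (turnover, 1/s); volumetric velocities can be
#'   converted beforehand with \code{\link{rate_from_absorbance}} and the
#'   enzyme concentration.
#' @param mm_tol relative SSE improvement below which inhibition is deemed
#'   absent.
#' @param ki_cap multiple of max(S) beyond which ki is reported as Inf.
#' @return list of class \code{kinetic_fit}: kcat, km, ki, se_kcat, se_km,
#'   se_ki, kcat_km, sse (weighted, i.e. sum of squared relative
#'   residuals), inhibition, n.
#' @export
fit_substrate_inhibition <- function(points, mm_tol = 1e-6, ki_cap = 1e4) {
  pts <- as.data.frame(points)
  S <- pts$conc_uM; v <- pts$velocity_per_s
  keep <- S > 0
  if (length(unique(S[keep])) < 5L)
    stop("need at least 5 distinct positive substrate concentrations")
  S <- S[keep]; v <- v[keep]

  vmax0 <- max(v)
  starts <- expand.grid(
    km = stats::quantile(S, c(0.25, 0.5, 0.75), names = FALSE),
    ki = c(max(S), 10 * max(S), 1e8))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    th0 <- log(c(2 * vmax0, starts$km[i], starts$ki[i]))
    f <- tryCatch(
      minpack.lm::nls.lm(
        par = th0,
        fn = function(th) {
          p <- exp(th)
          vhat <- p[1] * S / (p[2] + S + S^2 / p[3])
          (v - vhat) / vhat
        },
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(f)) next
    sse <- sum(f$fvec^2)
    if (is.null(best) || sse < best$sse - 1e-12) best <- list(fit = f, sse = sse)
  }
  if (is.null(best)) stop("substrate-inhibition fit failed from all starts")

  ## Michaelis-Menten reference fit (ki fixed at +Inf)
  mm <- NULL
  for (km0 in stats::quantile(S, c(0.25, 0.5, 0.75), names = FALSE)) {
    f <- tryCatch(
      minpack.lm::nls.lm(
        par = log(c(vmax0, km0)),
        fn = function(th) {
          p <- exp(th)
          vhat <- p[1] * S / (p[2] + S)
          (v - vhat) / vhat
        },
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(f)) next
    sse <- sum(f$fvec^2)
    if (is.null(mm) || sse < mm$sse) mm <- list(fit = f, sse = sse)
  }

  use_mm <- !is.null(mm) &&
    (mm$sse <= best$sse * (1 + mm_tol) ||
     exp(best$fit$par[3]) > ki_cap * max(S))
  if (use_mm) {
    p <- exp(mm$fit$par)
    se <- fit_se(mm$fit, p)
    out <- list(kcat = p[1], km = p[2], ki = Inf,
                se_kcat = se[1], se_km = se[2], se_ki = NA_real_,
                sse = mm$sse, inhibition = FALSE, n = length(S))
  } else {
    p <- exp(best$fit$par)
    se <- fit_se(best$fit, p)
    out <- list(kcat = p[1], km = p[2], ki = p[3],
                se_kcat = se[1], se_km = se[2], se_ki = se[3],
                sse = best$sse, inhibition = TRUE, n = length(S))
  }
  out$kcat_km <- out$kcat / out$km
  class(out) <- "kinetic_fit"
  out
}

## delta-method SEs on the natural scale from a log-parameterized nls.lm fit
fit_se <- function(fit, p) {
  se_log <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                     error = function(e) rep(NA_real_, length(p)))
  as.numeric(se_log) * p   # d exp(th)/d th = exp(th)
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("<kinetic_fit> kcat %.4g +/- %.2g /s | km %.4g +/- %.2g uM | ",
              x$kcat, x$se_kcat, x$km, x$se_km))
  if (is.finite(x$ki))
    cat(sprintf("ki %.4g +/- %.2g uM\n", x$ki, x$se_ki))
  else cat("no substrate inhibition (ki = Inf)\n")
  invisible(x)
}

#' Activity of one enzyme relative to a reference
#'
#' Evaluates both rate laws at the standard assay point (100 uM
#' oxaloacetate by default, matching the comparative assay conditions) and
#' returns the fold difference.
#'
#' @param test,reference kinetic parameter sets (named: kcat, km, ki).
#' @param S_uM assay substrate concentration.
#' @return fold activity, v_test / v_reference.
#' @export
relative_activity <- function(test, reference, S_uM = 100) {
  vref <- substrate_inhibition_velocity(reference, S_uM)
  if (vref <= 0) stop("reference velocity is zero at S = ", S_uM)
  substrate_inhibition_velocity(test, S_uM) / vref
}

#' pH profile summary of an enzyme's parameter sets
#'
#' Evaluates the rate law at a stated assay substrate concentration for
#' each tabulated pH and reports the optimum (ties resolved toward the
#' lower pH, with a warning).
#'
#' @param params_by_ph data frame with columns ph, kcat, km, ki.
#' @param S_uM assay substrate concentration, uM.
#' @return list with \code{optimum_ph} and \code{table} (tibble: ph,
#'   velocity).
#' @export
ph_profile_summary <- function(params_by_ph, S_uM = 100) {
  tab <- as.data.frame(params_by_ph)
  if (nrow(tab) == 0L) stop("empty parameter table")
  if (nrow(tab) == 1L) warning("single pH point; optimum is that point")
  vel <- vapply(seq_len(nrow(tab)), function(i)
    substrate_inhibition_velocity(tab[i, ], S_uM), numeric(1))
  top <- which(vel >= max(vel) - 1e-12)
  if (length(top) > 1L) warning("tied optima; reporting the lowest pH")
  list(optimum_ph = min(tab$ph[top]),
       table = tibble::tibble(ph = tab$ph, velocity = vel))
}

#' Enzyme velocity under physiological conditions
#'
#' Interpolates the kinetic parameters to the intracellular pH (linearly in
#' log-parameter space between the bracketing tabulated pH values; no
#' extrapolation) and evaluates the rate law at the intracellular substrate
#' concentration. Also reports the inhibition factor, the ratio of the
#' velocity to the inhibition-free (ki = Inf) velocity at the same
#' parameters: (km + S) / (km + S + S^2/ki).
#'
#' @param params_by_ph data frame with columns ph, kcat, km, ki for one
#'   enzyme.
#' @param state a \code{\link{physiological_state}}.
#' @return list: ph, S_uM, params (interpolated), velocity (1/s),
#'   inhibition_factor.
#' @export
physiological_velocity <- function(params_by_ph, state = physiological_state()) {
  tab <- as.data.frame(params_by_ph)
  tab <- tab[order(tab$ph), ]
  ph <- state$ph
  if (ph < min(tab$ph) || ph > max(tab$ph))
    stop("state pH ", ph, " outside the fitted grid [",
         min(tab$ph), ", ", max(tab$ph), "]; no extrapolation")
  i <- findInterval(ph, tab$ph, rightmost.closed = TRUE)
  if (tab$ph[i] == ph) {
    par <- as.list(tab[i, c("kcat", "km", "ki")])
  } else {
    w <- (ph - tab$ph[i]) / (tab$ph[i + 1] - tab$ph[i])
    interp <- function(a, b) {
      if (is.infinite(a) || is.infinite(b)) return(Inf)
      exp((1 - w) * log(a) + w * log(b))
    }
    par <- list(kcat = interp(tab$kcat[i], tab$kcat[i + 1]),
                km = interp(tab$km[i], tab$km[i + 1]),
                ki = interp(tab$ki[i], tab$ki[i + 1]))
  }
  S <- state$oaa_uM
  v <- substrate_inhibition_velocity(par, S)
  fac <- if (is.finite(par$ki)) (par$km + S) / (par$km + S + S^2 / par$ki) else 1
  list(ph = ph, S_uM = S, params = par, velocity = v,
       inhibition_factor = fac)
}
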