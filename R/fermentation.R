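#' Molar masses used for unit conversion
#'
#' @return named numeric, g/mol: succinate (succinic acid), glucose,
#'   glycerol.
#' @export
molar_masses <- function() {
  c(succinate = 118.09, glucose = 180.16, glycerol = 92.09)
}

#' Convert optical density to dry cell weight
#'
#' Uses the strain's predetermined standard curve,
#' 1 OD600 = 0.451 gDCW/L.
#'
#' @param od600 optical density at 600 nm (non-negative).
#' @return dry cell weight, gDCW/L.
#' @export
dcw_from_od <- function(od600) {
  if (any(od600 < 0)) stop("od600 must be non-negative")
  od600 * 0.451
}

#' Glucose-equivalent moles of a glucose/glycerol mixture
#'
#' Glycerol (C3) counts for half a glucose (C6): the carbon contents differ
#' by a factor of two, so dual-carbon yields are expressed per mol glucose
#' equivalent.
#'
#' @param glc_mol,gly_mol consumed moles of glucose and glycerol.
#' @return mol glucose equivalent.
#' @export
glucose_equivalents <- function(glc_mol, gly_mol) {
  stopifnot(all(glc_mol >= 0), all(gly_mol >= 0))
  glc_mol + gly_mol / 2
}

#' Production-index container
#' @param titer g/L; @param yield_mol_per_mol mol product per mol glucose
#'   equivalent; @param overall_productivity,max_productivity g/L/h;
#'   @param specific_productivity g/gDCW/h; @param max_dcw gDCW/L.
#' @return object of class \code{production_indices}.
#' @export
production_indices <- function(titer, yield_mol_per_mol,
                               overall_productivity, max_productivity,
                               specific_productivity, max_dcw) {
  stopifnot(titer >= 0, yield_mol_per_mol >= 0, overall_productivity >= 0,
            max_productivity >= overall_productivity - 1e-9)
  structure(list(titer = titer, yield_mol_per_mol = yield_mol_per_mol,
                 overall_productivity = overall_productivity,
                 max_productivity = max_productivity,
                 specific_productivity = specific_productivity,
                 max_dcw = max_dcw),
            class = "production_indices")
}

#' @export
print.production_indices <- function(x, ...) {
  cat(sprintf(paste0("<production_indices> titer %.2f g/L | yield %.3f",
                     " mol/mol glc-eq | overall %.2f, max %.2f g/L/h |",
                     " specific %.3f g/gDCW/h | max DCW %.2f gDCW/L\n"),
              x$titer, x$yield_mol_per_mol, x$overall_productivity,
              x$max_productivity, x$specific_productivity, x$max_dcw))
  invisible(x)
}

#' Compute production indices from a fermentation profile
#'
#' Titer is the final product concentration; consumed substrate per carbon
#' source is initial + cumulative fed - residual (constant working-volume
#' approximation), converted to moles and pooled as glucose equivalents;
#' yield is mol product per mol glucose equivalent; overall productivity is
#' titer over elapsed time; maximum productivity is the largest
#' product increment rate over one sampling interval; specific productivity
#' is titer divided by the time-averaged (trapezoidal) biomass times the
#' duration.
#'
#' @param profile data frame with columns \code{time_h}, \code{dcw_g_l}
#'   (or \code{od600}), \code{glucose_g_l}, \code{glycerol_g_l},
#'   \code{succinate_g_l}, \code{fed_glucose_g_l}, \code{fed_glycerol_g_l}.
#' @return a \code{production_indices}.
#' @export
compute_indices <- function(profile) {
  p <- as.data.frame(profile)
  if (nrow(p) < 2L) stop("profile needs at least two time points")
  if (is.unsorted(p$time_h, strictly = TRUE))
    stop("time must be strictly increasing")
  if (!"dcw_g_l" %in% names(p)) p$dcw_g_l <- dcw_from_od(p$od600)
  for (col in c("glycerol_g_l", "fed_glucose_g_l", "fed_glycerol_g_l"))
    if (!col %in% names(p)) p[[col]] <- 0
  n <- nrow(p)
  sa_g <- p$succinate_g_l[n] - p$succinate_g_l[1]
  if (sa_g < 0) stop("final product concentration below initial")
  mm <- molar_masses()

  consumed_g <- function(resid, fed)
    resid[1] + (fed[n] - fed[1]) - resid[n]
  glc_mol <- consumed_g(p$glucose_g_l, p$fed_glucose_g_l) / mm[["glucose"]]
  gly_mol <- consumed_g(p$glycerol_g_l, p$fed_glycerol_g_l) / mm[["glycerol"]]
  if (glc_mol < -1e-9 || gly_mol < -1e-9)
    stop("negative substrate consumption; check feed columns")
  geq <- glucose_equivalents(max(glc_mol, 0), max(gly_mol, 0))
  if (geq <= 0) stop("no substrate consumed; yield undefined")

  dt <- diff(p$time_h)
  duration <- p$time_h[n] - p$time_h[1]
  rate <- diff(p$succinate_g_l) / dt
  dcw_mean <- sum((p$dcw_g_l[-1] + p$dcw_g_l[-n]) / 2 * dt) / duration

  production_indices(
    titer = p$succinate_g_l[n],
    yield_mol_per_mol = (sa_g / mm[["succinate"]]) / geq,
    overall_productivity = p$succinate_g_l[n] / duration,
    max_productivity = max(rate),
    specific_productivity = p$succinate_g_l[n] / (dcw_mean * duration),
    max_dcw = max(p$dcw_g_l))
}
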