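# Scalar assays: spheroid dispersal-area ratio and trypsinization
# detachment-fraction kinetics.

#' Spheroid dispersal ratio
#'
#' Ratio of the total outgrowth area (spheroid core plus dispersed cells)
#' to the core area: `dispersal = total area / sphere area`. A value of 1
#' means no dispersal. The ratio is dimensionless and therefore invariant
#' to the pixel calibration. Filled-region areas are used (interior holes
#' of a traced outline count as area).
#'
#' @param total_mask [region_mask] of the full dispersal footprint.
#' @param core_mask [region_mask] of the remaining spheroid core; must be
#'   contained in `total_mask`.
#' @param pixel_size micrometres per pixel.
#' @return list `total_area_um2`, `core_area_um2`, `ratio` (>= 1).
#' @export
dispersal_ratio <- function(total_mask, core_mask, pixel_size) {
  stopifnot(inherits(total_mask, "region_mask"),
            inherits(core_mask, "region_mask"))
  if (!mask_is_subset(core_mask, total_mask))
    stop("core mask is not contained in the total dispersal mask")
  total <- cell_area(total_mask, pixel_size)
  core <- cell_area(core_mask, pixel_size)
  list(total_area_um2 = total, core_area_um2 = core, ratio = total / core)
}

#' Detachment fraction after trypsinization
#'
#' Fraction of cells removed by a timed trypsinization: detached count over
#' the total (detached plus the residual recovered by a second, complete
#' trypsinization). Vectorised over time points.
#'
#' @param detached_count cells detached at the assay time (>= 0).
#' @param residual_count cells recovered by the second round (>= 0).
#' @return fraction(s) in \[0, 1\].
#' @export
detachment_fraction <- function(detached_count, residual_count) {
  stopifnot(length(detached_count) == length(residual_count))
  if (any(detached_count < 0) || any(residual_count < 0))
    stop("counts must be non-negative")
  total <- detached_count + residual_count
  if (any(total == 0)) stop("zero total cell count")
  detached_count / total
}

#' Diagnostic detachment-rate fit
#'
#' For first-order detachment kinetics, `fraction(t) = 1 - exp(-k t)`, so
#' `log(1 - fraction)` is linear in time with slope `-k`. Fits that line
#' through the origin and returns `k`. Time points with fraction 1 carry no
#' information about the rate and are dropped (with a message).
#'
#' @param time_min times in minutes (> 0).
#' @param fraction detachment fractions in \[0, 1\].
#' @return rate constant `k` per minute.
#' @export
fit_detachment_rate <- function(time_min, fraction) {
  stopifnot(length(time_min) == length(fraction), all(time_min > 0),
            all(fraction >= 0 & fraction <= 1))
  keep <- fraction < 1
  if (!all(keep)) message("dropping ", sum(!keep), " saturated time point(s)")
  if (sum(keep) < 1) stop("no informative time points (all fractions are 1)")
  t <- time_min[keep]
  z <- log(1 - fraction[keep])
  -unname(stats::coef(stats::lm(z ~ 0 + t))["t"])
}
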