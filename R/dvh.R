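#' Cumulative dose-volume histogram of a structure
#'
#' Voxel-counting DVH: the relative volume at dose D is the fraction of the
#' structure's voxels receiving at least D. No sub-voxel dose averaging is
#' applied, consistent with ~1 mm calculation grids.
#'
#' @param grid a [dose_grid()] of dose in Gy.
#' @param structure a non-empty [binary_mask()] aligned to `grid`.
#' @param bin_width histogram bin width in Gy; default 1/1000 of the
#'   structure's maximum dose (use 0.1% of the reference dose for plan
#'   evaluation).
#' @return A data frame of class `dvh` with columns `dose_gy` (ascending,
#'   starting at 0) and `relative_volume` (non-increasing, 1 at zero dose, 0
#'   above the structure maximum); attributes `structure_volume_mm3`,
#'   `min_dose`, `max_dose`.
#' @export
compute_dvh <- function(grid, structure, bin_width = NULL) {
  stopifnot(inherits(grid, "dose_grid"), inherits(structure, "binary_mask"))
  check_aligned(grid, structure, "grid and structure")
  if (!any(structure$values)) stop("structure mask is empty")
  doses <- sort(grid$values[structure$values])
  n <- length(doses)
  mx <- doses[n]
  if (is.null(bin_width)) bin_width <- max(mx, .Machine$double.eps) / 1000
  if (bin_width <= 0) stop("'bin_width' must be positive")
  bins <- seq(0, mx + bin_width, by = bin_width)
  rv <- (n - findInterval(bins, doses, left.open = TRUE)) / n
  structure(data.frame(dose_gy = bins, relative_volume = rv),
            structure_volume_mm3 = n * voxel_volume(grid),
            min_dose = doses[1], max_dose = mx,
            bin_width = bin_width,
            class = c("dvh", "data.frame"))
}

#' Dose covering a given fraction of a structure
#'
#' Inverts a cumulative DVH: the largest dose received by at least the
#' requested volume fraction, with linear interpolation between bins.
#' `d_at_volume(dvh, 1)` is D100%, the minimum dose covering the whole
#' structure (within one bin).
#'
#' @param dvh a [compute_dvh()] result.
#' @param volume_fraction requested fraction in `(0, 1]`.
#' @return Dose in Gy.
#' @export
d_at_volume <- function(dvh, volume_fraction) {
  stopifnot(inherits(dvh, "dvh"))
  if (!is.numeric(volume_fraction) || length(volume_fraction) != 1L ||
      volume_fraction <= 0 || volume_fraction > 1)
    stop("'volume_fraction' must be a single value in (0, 1]")
  rv <- dvh$relative_volume
  dd <- dvh$dose_gy
  i <- max(which(rv >= volume_fraction))
  if (i == length(rv)) return(dd[i])
  if (rv[i] == rv[i + 1L]) return(dd[i])
  dd[i] + (rv[i] - volume_fraction) / (rv[i] - rv[i + 1L]) * (dd[i + 1L] - dd[i])
}

#' Gradient index (GI)
#'
#' The classical volume-based gradient score: the ratio of the volume of
#' half the prescription isodose to that of the prescription isodose,
#' \eqn{GI = V_{50\%} / V_{100\%}}. Values closer to 1 indicate a steeper
#' fall-off; the index is at least 1 for nested isodoses but depends
#' strongly on target volume and shape.
#'
#' @param levels an `isodose_levels` (or derived) table containing the 50%
#'   and 100% levels; pooled all-component volumes are used.
#' @return Dimensionless GI.
#' @export
gradient_index <- function(levels) {
  v50 <- level_volume(levels, 50)
  v100 <- level_volume(levels, 100)
  v50 / v100
}

#' R50% dose spillage index
#'
#' Ratio of the 50% prescription isodose volume to the planning target
#' volume, \eqn{R_{50\%} = V_{50\%} / V_{PTV}}; a benchmark for dose spill
#' beyond the target into normal tissue. Equals the GI when the
#' prescription isodose volume coincides with the PTV.
#'
#' @param levels an `isodose_levels` (or derived) table containing the 50%
#'   level.
#' @param ptv_volume planning target volume in mm^3, `> 0`.
#' @return Dimensionless R50%.
#' @export
r50 <- function(levels, ptv_volume) {
  if (!is.numeric(ptv_volume) || length(ptv_volume) != 1L || ptv_volume <= 0)
    stop("'ptv_volume' must be a single positive number")
  level_volume(levels, 50) / ptv_volume
}

level_volume <- function(levels, pct) {
  if (is.null(levels$dose_pct) || all(is.na(levels$dose_pct)))
    stop("level table has no percent dose column (build it with a reference dose)")
  i <- which(abs(levels$dose_pct - pct) < 1e-6)
  if (length(i) != 1L)
    stop(sprintf("the %g%% isodose level is missing from the table", pct))
  levels$volume_mm3[i]
}
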