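#' Bundled multi-layer verification measurements
#'
#' Surface areas and volumes of a 14-layer structure produced by uniformly
#' expanding an irregular 2.5 cm^3 structure (concave and convex surface)
#' at regular 1 mm intervals on a treatment planning system, together with
#' the DGI evaluated over 1, 2 and 3 mm layer gaps. The DGI columns are the
#' regression reference for [dgi()]: every value should be recovered from
#' the printed areas/volumes to within the rounding of the inputs, and all
#' lie within ~2% of the true layer spacing.
#'
#' @return Data frame with columns `layer`, `surface_area_mm2`,
#'   `volume_mm3`, `dgi_1mm_mm`, `dgi_2mm_mm`, `dgi_3mm_mm` (NA where no
#'   complete pair exists).
#' @export
example_multilayer_table <- function() {
  read.csv(system.file("extdata", "multilayer_layers.csv",
                       package = "dgcurve", mustWork = TRUE))
}

#' Bundled SRS plan isodose-level table
#'
#' Worked example: isodose levels of a single-fraction stereotactic plan
#' for a 3 cm diameter spherical virtual target, 15 Gy prescribed at the
#' 100% level, tabulated at a 1% calculation interval. Columns carry the
#' pooled surface area and volume per level plus the reported differential
#' and cumulative DGI (2 decimals; the middle of the level range is
#' omitted, so consecutive rows exist only for 24-30% and 90-121%). The
#' dDGI of this plan ranges from 0.10 mm near the steepest fall-off to
#' 2.29 mm at the 120% level; the cumulative curve reaches 17.26 mm at the
#' 24% level.
#'
#' @return Data frame with columns `dose_pct`, `dose_gy`,
#'   `surface_area_mm2`, `volume_mm3`, `ddgi_mm`, `cdgi_mm`.
#' @export
example_srs_table <- function() {
  read.csv(system.file("extdata", "srs_sphere_levels.csv",
                       package = "dgcurve", mustWork = TRUE))
}
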