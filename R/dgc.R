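#' Fit dose gradient curves to a 3D dose distribution
#'
#' The main entry point. Crops the body mask away from the skin surface,
#' tabulates one isodose surface per dose level (marching-tetrahedra
#' extraction, pooled over disconnected components), and builds the
#' differential and cumulative dose gradient curves
#' \deqn{dDGI_i = \frac{V_i - V_{i+d}}{(S_i + S_{i+d})/2}, \qquad
#'       cDGI_i = \sum_{j=i}^{D_0 - d} dDGI_j,}
#' together with the target DVH and the classical indices (GI, R50%) when a
#' target mask is supplied. The analysed range runs from the maximum dose
#' down to the lowest isodose surface that stays strictly inside the
#' cropped body; lower levels are excluded (their surfaces would be clipped
#' and their areas corrupted).
#'
#' @param dose a [dose_grid()] of absolute dose in Gy.
#' @param prescription prescription dose in Gy (the default reference dose
#'   and 100% level).
#' @param body optional [binary_mask()] of the body; when given, the
#'   evaluation domain is the body eroded by `crop_margin` mm. Without it
#'   the whole grid is the domain (isodoses touching the grid boundary are
#'   still excluded).
#' @param ptv optional [binary_mask()] of the planning target volume;
#'   enables the DVH, D100%, GI and R50% outputs and the `"d100"`
#'   reference.
#' @param step calculation interval, in % of the reference dose
#'   (`dose_scale = "percent"`) or Gy. Steps above 1% / 1 Gy inflate the
#'   raw differential curve (normalize to compare); the cumulative curve is
#'   step-invariant.
#' @param dose_scale `"percent"` (default) or `"gy"`.
#' @param reference `"prescription"` (default) or `"d100"`: anchor of the
#'   cumulative curve. `"d100"` uses the minimum dose covering 100% of the
#'   target, snapped to the nearest tabulated level, so the cumulative
#'   curve originates from the point of full target coverage.
#' @param crop_margin body crop margin in mm (default 3).
#' @param range optional dose span (scale units) to tabulate.
#' @param resample_to resample the dose grid trilinearly to this spacing
#'   (mm) when coarser; default 1 mm. `NULL` disables.
#' @param dvh_bin DVH bin width in Gy; default 0.1% of the reference dose.
#' @return An object of class `dgc`: list with elements
#'   \describe{
#'     \item{table}{`dgc_table` with columns `dose_pct`, `dose_gy`,
#'       `surface_area_mm2`, `volume_mm3`, `n_components`, `ddgi_mm`,
#'       `ddgi_norm_mm`, `cdgi_mm`.}
#'     \item{dvh}{target [compute_dvh()] curve, or `NULL`.}
#'     \item{indices}{named list: `gradient_index`, `r50`, `ptv_volume_mm3`,
#'       `d100_gy` (`NA` where not computable).}
#'     \item{config}{the fitting configuration, including the realised
#'       reference level and truncation dose.}
#'   }
#' @seealso [plot.dgc()], [build_level_table()], [differential_dgc()],
#'   [cumulative_dgc()]
#' @export
#' @examples
#' plan <- make_radial_dose(target_radius = 15, reference_dose = 15,
#'                          body_radius = 40)
#' fit <- dgc(plan$dose, prescription = 15, body = plan$body, ptv = plan$ptv)
#' fit
#' coef(fit)
dgc <- function(dose, prescription, body = NULL, ptv = NULL,
                step = 1, dose_scale = c("percent", "gy"),
                reference = c("prescription", "d100"),
                crop_margin = 3, range = NULL, resample_to = 1,
                dvh_bin = NULL) {
  stopifnot(inherits(dose, "dose_grid"))
  dose_scale <- match.arg(dose_scale)
  reference <- match.arg(reference)
  if (!is.numeric(prescription) || length(prescription) != 1L || prescription <= 0)
    stop("'prescription' must be a single positive dose in Gy")
  if (any(dose$values < 0)) stop("dose values must be non-negative")
  if (reference == "d100" && is.null(ptv))
    stop("reference = \"d100\" requires a target mask")

  if (!is.null(resample_to) && any(dose$spacing > resample_to + 1e-9)) {
    dose <- resample_grid(dose, resample_to)
    if (!is.null(body)) body <- resample_grid(body, resample_to)
    if (!is.null(ptv)) ptv <- resample_grid(ptv, resample_to)
  }

  domain <- if (!is.null(body)) crop_body(body, crop_margin) else NULL

  dvh <- NULL
  d100 <- NA_real_
  ptv_vol <- NA_real_
  if (!is.null(ptv)) {
    check_aligned(dose, ptv, "dose and ptv")
    if (is.null(dvh_bin)) dvh_bin <- prescription / 1000
    dvh <- compute_dvh(dose, ptv, bin_width = dvh_bin)
    d100 <- d_at_volume(dvh, 1)
    ptv_vol <- attr(dvh, "structure_volume_mm3")
  }

  tbl <- build_level_table(dose, domain = domain,
                           reference_dose = prescription, step = step,
                           dose_scale = dose_scale, range = range)
  tbl <- differential_dgc(tbl)

  ref_level <- if (dose_scale == "percent") 100 else prescription
  if (reference == "d100") {
    want <- if (dose_scale == "percent") d100 / prescription * 100 else d100
    ax <- level_axis(tbl)
    ref_level <- ax[which.min(abs(ax - want))]  # snap to the level grid
  }
  tbl <- cumulative_dgc(tbl, reference = ref_level)

  gi <- tryCatch(gradient_index(tbl), error = function(e) NA_real_)
  r50v <- if (!is.na(ptv_vol))
    tryCatch(r50(tbl, ptv_vol), error = function(e) NA_real_) else NA_real_

  structure(list(
    table = tbl,
    dvh = dvh,
    indices = list(gradient_index = gi, r50 = r50v,
                   ptv_volume_mm3 = ptv_vol, d100_gy = d100),
    config = list(prescription_gy = prescription, step = step,
                  dose_scale = dose_scale, reference = reference,
                  reference_level = ref_level, crop_margin_mm = crop_margin,
                  truncation_dose = attr(tbl, "truncation_dose"),
                  spacing_mm = dose$spacing)
  ), class = "dgc")
}

#' @export
print.dgc <- function(x, digits = 2, ...) {
  cfg <- x$config
  unit <- if (cfg$dose_scale == "percent") "%" else "Gy"
  cat("Dose gradient curve fit\n")
  cat(sprintf("  prescription: %g Gy; step: %g%s; reference: %s (%g%s)\n",
              cfg$prescription_gy, cfg$step, unit, cfg$reference,
              cfg$reference_level, unit))
  ax <- level_axis(x$table)
  cat(sprintf("  analysed levels: %g-%g%s (%d levels; truncated at %g%s)\n",
              min(ax), max(ax), unit, nrow(x$table), cfg$truncation_dose, unit))
  cd <- x$table$cdgi_mm
  if (any(!is.na(cd)))
    cat(sprintf("  cDGI at the lowest analysed level: %.*f mm\n", digits,
                cd[which.max(!is.na(cd))]))
  ix <- x$indices
  if (!is.na(ix$gradient_index))
    cat(sprintf("  GI = %.3f", ix$gradient_index))
  if (!is.na(ix$r50)) cat(sprintf("; R50%% = %.3f", ix$r50))
  if (!is.na(ix$gradient_index) || !is.na(ix$r50)) cat("\n")
  invisible(x)
}

#' @export
summary.dgc <- function(object, ...) {
  structure(list(fit = object), class = "summary.dgc")
}

#' @export
print.summary.dgc <- function(x, ...) {
  f <- x$fit
  print(f)
  tbl <- f$table
  dd <- tbl$ddgi_mm[!is.na(tbl$ddgi_mm)]
  cat(sprintf("  dDGI: min %.2f, median %.2f, max %.2f mm\n",
              min(dd), stats::median(dd), max(dd)))
  ax <- level_axis(tbl)
  imin <- which.min(tbl$ddgi_mm)
  cat(sprintf("  steepest gradient (min dDGI) at the %g%s level\n",
              ax[imin], if (f$config$dose_scale == "percent") "%" else " Gy"))
  if (!is.null(f$dvh))
    cat(sprintf("  target: %.1f mm^3, D100%% = %.2f Gy\n",
                f$indices$ptv_volume_mm3, f$indices$d100_gy))
  rounded <- as.data.frame(tbl)
  num <- vapply(rounded, is.numeric, TRUE)
  rounded[num] <- lapply(rounded[num], round, 2)
  cat("  head of the curve table (2 dp):\n")
  print(utils::head(rounded, 5))
  invisible(x)
}

#' @export
as.data.frame.dgc <- function(x, ...) as.data.frame(x$table)

#' @export
coef.dgc <- function(object, ...) {
  tbl <- object$table
  cd50 <- tryCatch(cdgi_at(tbl, if (object$config$dose_scale == "percent") 50
                           else object$config$prescription_gy / 2),
                   error = function(e) NA_real_)
  c(gradient_index = object$indices$gradient_index,
    r50 = object$indices$r50,
    cdgi_50 = cd50,
    d100_gy = object$indices$d100_gy,
    ptv_volume_mm3 = object$indices$ptv_volume_mm3)
}
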