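#' Tabulate isodose surfaces over a range of dose levels
#'
#' Extracts one isodose surface per dose level at a uniform step and records
#' its pooled surface area and enclosed volume (all disconnected components
#' of a level are pooled into a single record). Levels whose isosurface
#' intersects the boundary of the evaluation domain are excluded and
#' truncate the analysed range from below: the table runs from the lowest
#' level that closes strictly inside the domain up to the highest level
#' below the maximum dose.
#'
#' @param grid a [dose_grid()] of dose in Gy.
#' @param domain optional [binary_mask()] evaluation domain, normally the
#'   body cropped 3 mm from the skin surface ([crop_body()]).
#' @param reference_dose reference dose D0 in Gy defining the 100% level
#'   (usually the prescription). Required when `dose_scale = "percent"`.
#' @param step calculation interval between levels, in % of the reference
#'   dose (`dose_scale = "percent"`, default) or in Gy. Steps not greater
#'   than 1% or 1 Gy are recommended.
#' @param dose_scale `"percent"` or `"gy"`.
#' @param range optional numeric length 2: requested dose span (in scale
#'   units) to tabulate; defaults to the full span of the dose within the
#'   domain. The realised range is still truncated by the open-surface rule.
#' @return A data frame of class `isodose_levels`, sorted by ascending dose,
#'   with columns `dose_pct`, `dose_gy`, `surface_area_mm2`, `volume_mm3`,
#'   `n_components`, and attributes `step`, `dose_scale`, `reference_dose`
#'   and `truncation_dose` (the lowest retained level, in scale units).
#' @export
build_level_table <- function(grid, domain = NULL, reference_dose = NULL,
                              step = 1, dose_scale = c("percent", "gy"),
                              range = NULL) {
  stopifnot(inherits(grid, "dose_grid"))
  dose_scale <- match.arg(dose_scale)
  if (!is.numeric(step) || length(step) != 1L || step <= 0)
    stop("'step' must be a single positive number")
  if (dose_scale == "percent" && is.null(reference_dose))
    stop("'reference_dose' is required on the percent scale")
  if (!is.null(reference_dose) && reference_dose <= 0)
    stop("'reference_dose' must be positive")

  dom <- NULL
  if (!is.null(domain)) {
    stopifnot(inherits(domain, "binary_mask"))
    check_aligned(grid, domain, "grid and domain")
    dom <- as.integer(domain$values)
    vals <- grid$values[domain$values]
  } else {
    vals <- grid$values
  }
  if (!length(vals)) stop("evaluation domain is empty")
  if (any(vals < 0)) stop("dose values must be non-negative")
  to_gy <- if (dose_scale == "percent") reference_dose / 100 else 1

  span <- range(vals) / to_gy
  lo <- if (!is.null(range)) max(range[1], span[1]) else span[1]
  hi <- if (!is.null(range)) min(range[2], span[2]) else span[2]
  if (lo >= hi) stop("requested dose range is empty within the grid span")
  levels <- seq(step * ceiling(max(lo, step * 1e-9) / step), hi, by = step)
  levels <- levels[levels * to_gy > span[1] * to_gy & levels * to_gy < span[2] * to_gy]
  if (!length(levels)) stop("no isodose levels fall inside the dose range")

  st <- cpp_isosurface_stats(as.numeric(grid$values), dim(grid$values),
                             grid$spacing, grid$origin, levels * to_gy, dom)
  nonempty <- st$n_faces > 0L
  open <- st$open_edges > 0L & nonempty
  keep <- nonempty & !open
  if (any(open)) {
    # the open-surface rule: everything at or below the highest open level
    # is outside the trustworthy range
    keep <- keep & (levels > max(levels[open]))
  }
  if (!any(keep))
    stop("no isodose level closes inside the evaluation domain: range is empty after truncation")

  out <- data.frame(
    dose_pct = if (!is.null(reference_dose)) levels[keep] * to_gy / reference_dose * 100 else NA_real_,
    dose_gy = levels[keep] * to_gy,
    surface_area_mm2 = st$area[keep],
    volume_mm3 = st$volume[keep],
    n_components = st$n_components[keep]
  )
  if (any(diff(out$volume_mm3) > 0))
    warning("isodose volumes are not strictly decreasing with dose; check the dose grid")
  structure(out,
            step = step, dose_scale = dose_scale,
            reference_dose = reference_dose,
            truncation_dose = min(levels[keep]),
            class = c("isodose_levels", "data.frame"))
}

level_axis <- function(tbl, dose_scale = attr(tbl, "dose_scale")) {
  if (identical(dose_scale, "gy") || all(is.na(tbl$dose_pct))) tbl$dose_gy
  else tbl$dose_pct
}

#' Differential dose gradient curve
#'
#' Computes the differential DGI for every consecutive pair of isodose
#' levels at uniform spacing `step`:
#' \deqn{dDGI_i = \frac{V_i - V_{i+d}}{(S_i + S_{i+d})/2},}
#' the average distance (mm) crossed by the dose while falling from level
#' `i + d` to level `i`. The top level has no dDGI. A flat dose plateau
#' (equal consecutive volumes) is reported as 0 with a warning rather than
#' as a nesting error.
#'
#' @param levels an `isodose_levels` table from [build_level_table()], or
#'   any data frame with the same columns, sorted by ascending dose at
#'   uniform spacing.
#' @param step the calculation interval in the table's dose units; taken
#'   from the table attribute when absent.
#' @return The table with columns `ddgi_mm` and `ddgi_norm_mm`
#'   (`ddgi_mm / step`) appended; class `dgc_table`.
#' @export
differential_dgc <- function(levels, step = NULL) {
  tbl <- as.data.frame(levels)
  if (nrow(tbl) < 2L) stop("at least two isodose levels are required")
  if (is.null(step)) step <- attr(levels, "step")
  if (is.null(step)) stop("'step' is unknown: pass it explicitly")
  if (step <= 0) stop("'step' must be positive")
  ax <- level_axis(levels)
  if (is.unsorted(ax, strictly = TRUE))
    stop("levels must be sorted by strictly ascending dose")
  if (max(abs(diff(ax) - step)) > 1e-6 * max(step, 1))
    stop("levels are not uniformly spaced at the stated step")

  v <- tbl$volume_mm3
  s <- tbl$surface_area_mm2
  n <- nrow(tbl)
  i <- seq_len(n - 1L)
  if (any(v[i] < v[i + 1L]))
    stop("nesting violation: isodose volume increases with dose")
  dd <- rep(NA_real_, n)
  flat <- v[i] == v[i + 1L]
  if (any(flat))
    warning("flat dose plateau: dDGI reported as 0 for levels with equal volumes")
  dd[i][flat] <- 0
  if (any(!flat))
    dd[i][!flat] <- dgi(v[i][!flat], s[i][!flat], v[i + 1L][!flat], s[i + 1L][!flat])
  tbl$ddgi_mm <- dd
  tbl$ddgi_norm_mm <- dd / step
  structure(tbl,
            step = step,
            dose_scale = attr(levels, "dose_scale"),
            reference_dose = attr(levels, "reference_dose"),
            truncation_dose = attr(levels, "truncation_dose"),
            class = c("dgc_table", "data.frame"))
}

#' Cumulative dose gradient curve
#'
#' Sums the differential DGI from the reference dose downward:
#' \deqn{cDGI_i = \sum_{j=i}^{D_0 - d} dDGI_j, \qquad cDGI_{D_0} = 0,}
#' so each value is the average distance from the reference isodose surface
#' to the surface of level `i`. The cumulative curve is defined only at and
#' below the reference dose; rows above it carry `NA`.
#'
#' @param ddgc a `dgc_table` from [differential_dgc()].
#' @param reference the reference dose level D0 in the table's dose units
#'   (default 100 on the percent scale, the table's reference dose in Gy
#'   otherwise). Must coincide with a tabulated level.
#' @return The table with a `cdgi_mm` column appended; attribute
#'   `reference_level` records D0.
#' @export
cumulative_dgc <- function(ddgc, reference = NULL) {
  if (!inherits(ddgc, "dgc_table") || is.null(ddgc$ddgi_mm))
    stop("'ddgc' must be a dgc_table with a ddgi_mm column (see differential_dgc)")
  tbl <- as.data.frame(ddgc)
  ax <- level_axis(ddgc)
  if (is.null(reference)) {
    reference <- if (identical(attr(ddgc, "dose_scale"), "gy"))
      attr(ddgc, "reference_dose") else 100
  }
  if (is.null(reference)) stop("no reference dose available")
  step <- attr(ddgc, "step")
  ref_idx <- which(abs(ax - reference) <= 1e-6 * max(step, 1))
  if (length(ref_idx) != 1L)
    stop(sprintf("reference dose %g does not coincide with a tabulated level (range %g-%g)",
                 reference, min(ax), max(ax)))
  dd <- tbl$ddgi_mm
  below <- seq_len(ref_idx - 1L)
  if (length(below) && anyNA(dd[below]))
    stop("dDGI missing for levels below the reference dose")
  cd <- rep(NA_real_, nrow(tbl))
  cd[ref_idx] <- 0
  if (length(below)) cd[below] <- rev(cumsum(rev(dd[below])))
  tbl$cdgi_mm <- cd
  out <- structure(tbl,
                   step = step,
                   dose_scale = attr(ddgc, "dose_scale"),
                   reference_dose = attr(ddgc, "reference_dose"),
                   truncation_dose = attr(ddgc, "truncation_dose"),
                   reference_level = reference,
                   class = c("dgc_table", "data.frame"))
  out
}

#' Normalize a differential DGC by its step size
#'
#' The raw dDGI grows proportionally with the calculation interval; dividing
#' by the step expresses it in mm per % (or mm per Gy), putting curves
#' computed at different steps on a common scale. With a 1% step the
#' normalized curve equals the raw one.
#'
#' @param ddgc a `dgc_table` with a `ddgi_mm` column.
#' @param step the step size; taken from the table attribute when absent.
#' @return The table with `ddgi_norm_mm` recomputed.
#' @export
normalize_ddgc <- function(ddgc, step = NULL) {
  if (is.null(ddgc$ddgi_mm)) stop("'ddgc' has no ddgi_mm column")
  if (is.null(step)) step <- attr(ddgc, "step")
  if (is.null(step)) stop("'step' is unknown: pass it explicitly")
  if (!is.numeric(step) || length(step) != 1L || step == 0)
    stop("'step' must be a single non-zero number")
  if (step < 0) stop("'step' must be positive")
  ddgc$ddgi_norm_mm <- ddgc$ddgi_mm / step
  ddgc
}

#' Interpolate the cumulative DGI at a dose level
#'
#' @param ddgc a `dgc_table` carrying a `cdgi_mm` column.
#' @param level dose level(s) in the table's dose units; must not exceed the
#'   reference dose (the cumulative curve is undefined above it).
#' @return cDGI in mm, linearly interpolated between tabulated levels.
#' @export
cdgi_at <- function(ddgc, level) {
  if (is.null(ddgc$cdgi_mm)) stop("'ddgc' has no cdgi_mm column (see cumulative_dgc)")
  ref <- attr(ddgc, "reference_level")
  if (!is.null(ref) && any(level > ref + 1e-9))
    stop("cumulative DGI is undefined above the reference dose")
  ax <- level_axis(ddgc)
  ok <- !is.na(ddgc$cdgi_mm)
  if (any(level < min(ax[ok]) - 1e-9))
    stop("level below the analysed (truncated) range")
  approx(ax[ok], ddgc$cdgi_mm[ok], xout = level, rule = 1)$y
}
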