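#' Plot dose gradient curves
#'
#' Base-graphics rendering of a fitted [dgc()] object. Four layouts are
#' available: the differential curve (dDGI versus dose, U-shaped for
#' typical single-target plans with its minimum marking the steepest
#' gradient), the step-normalized differential curve, the cumulative curve
#' (anchored at 0 at the reference dose and rising as the dose falls), and
#' the combined plot that overlays the cumulative curve on the target DVH
#' with a double y-axis (volume % on the left, mm on the right, shared dose
#' axis) for simultaneous reading of dose gradient and target coverage.
#'
#' @param x a [dgc()] fit.
#' @param type `"differential"`, `"normalized"`, `"cumulative"` or
#'   `"combined"`.
#' @param add overlay onto an existing plot of the same type (for comparing
#'   rival plans); not available for `"combined"`.
#' @param col curve colour.
#' @param lwd line width.
#' @param dvh_col DVH colour in the combined layout.
#' @param main plot title.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.dgc <- function(x, type = c("cumulative", "differential", "normalized",
                                 "combined"),
                     add = FALSE, col = "firebrick", lwd = 2,
                     dvh_col = "steelblue", main = NULL, ...) {
  type <- match.arg(type)
  tbl <- x$table
  unit <- if (x$config$dose_scale == "percent") "%" else "Gy"
  ax <- level_axis(tbl)
  xlab <- sprintf("Dose (%s of reference)", unit)

  if (type == "combined") {
    if (add) stop("'add' is not supported for the combined layout")
    if (is.null(x$dvh)) stop("combined plot requires a DVH (fit with a ptv mask)")
    plot_dgc_combined(x, col = col, dvh_col = dvh_col, lwd = lwd,
                      main = if (is.null(main)) "cDGC + DVH" else main, ...)
    return(invisible(x))
  }

  sel <- switch(type,
    differential = list(y = tbl$ddgi_mm, ylab = "dDGI (mm)",
                        ttl = "Differential dose gradient curve"),
    normalized = list(y = tbl$ddgi_norm_mm,
                      ylab = sprintf("dDGI / step (mm per %s)", unit),
                      ttl = "Normalized differential dose gradient curve"),
    cumulative = list(y = tbl$cdgi_mm, ylab = "cDGI (mm)",
                      ttl = "Cumulative dose gradient curve"))
  ok <- !is.na(sel$y)
  if (!any(ok)) stop("nothing to plot: curve values are all missing")
  if (add) {
    graphics::lines(ax[ok], sel$y[ok], col = col, lwd = lwd, ...)
  } else {
    plot(ax[ok], sel$y[ok], type = "l", col = col, lwd = lwd,
         xlab = xlab, ylab = sel$ylab,
         main = if (is.null(main)) sel$ttl else main, ...)
    if (type == "cumulative")
      graphics::points(x$config$reference_level, 0, pch = 19, col = col)
  }
  invisible(x)
}

plot_dgc_combined <- function(x, col, dvh_col, lwd, main, ...) {
  tbl <- x$table
  ax <- level_axis(tbl)
  dvh <- x$dvh
  pres <- x$config$prescription_gy
  dvh_x <- if (x$config$dose_scale == "percent") dvh$dose_gy / pres * 100
           else dvh$dose_gy
  xlim <- range(c(ax, dvh_x[dvh$relative_volume > 0]))

  op <- graphics::par(mar = c(5, 4, 4, 4) + 0.1)
  on.exit(graphics::par(op))
  plot(dvh_x, dvh$relative_volume * 100, type = "l", col = dvh_col,
       lwd = lwd, xlim = xlim, ylim = c(0, 100),
       xlab = sprintf("Dose (%s of reference)",
                      if (x$config$dose_scale == "percent") "%" else "Gy"),
       ylab = "Volume (%)", main = main, ...)
  graphics::par(new = TRUE)
  ok <- !is.na(tbl$cdgi_mm)
  plot(ax[ok], tbl$cdgi_mm[ok], type = "l", col = col, lwd = lwd,
       xlim = xlim, axes = FALSE, xlab = "", ylab = "")
  graphics::axis(4, col.axis = col)
  graphics::mtext("cDGI (mm)", side = 4, line = 2.5, col = col)
  graphics::legend("topright", legend = c("DVH (PTV)", "cDGC"),
                   col = c(dvh_col, col), lwd = lwd, bty = "n")
  invisible(NULL)
}

#' Plot a dose-volume histogram
#'
#' @param x a [compute_dvh()] curve.
#' @param add overlay onto an existing plot.
#' @param col curve colour.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.dvh <- function(x, add = FALSE, col = "steelblue", ...) {
  if (add) graphics::lines(x$dose_gy, x$relative_volume * 100, col = col, ...)
  else plot(x$dose_gy, x$relative_volume * 100, type = "l", col = col,
            xlab = "Dose (Gy)", ylab = "Volume (%)",
            main = "Dose-volume histogram", ...)
  invisible(x)
}
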