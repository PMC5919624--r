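#' Dose gradient index between two nested isodose surfaces
#'
#' The DGI estimates the average distance (mm) between two nested isodose
#' surfaces from their volumes and surface areas:
#' \deqn{DGI = \frac{V_L - V_H}{(S_L + S_H)/2},}
#' where the subscripts L and H denote the lower- and higher-dose surfaces.
#' Isodose surfaces never intersect and the lower-dose volume is always the
#' larger, so the index is strictly positive; the shorter the distance, the
#' steeper the dose gradient. The estimate is exact in the limit of
#' vanishing gap and its curvature error has the closed form of
#' [dgi_relative_error()].
#'
#' @param v_low,s_low volume (mm^3) and surface area (mm^2) of the
#'   lower-dose (outer) isodose surface.
#' @param v_high,s_high volume and surface area of the higher-dose (inner)
#'   surface. `v_low > v_high` (superlevel-set nesting) is required.
#' @return Average inter-surface distance in mm. Vectorised over all four
#'   arguments.
#' @export
#' @examples
#' dgi(5778.131, 1802.676, 4099.663, 1477.332) # ~ 1.0235 mm for a 1 mm gap
dgi <- function(v_low, s_low, v_high, s_high) {
  n <- vapply(list(v_low, s_low, v_high, s_high), length, 1L)
  if (length(unique(n[n > 1L])) > 1L) stop("argument lengths differ")
  if (any(!is.finite(c(v_low, s_low, v_high, s_high))))
    stop("all inputs must be finite")
  if (any(v_high < 0)) stop("volumes must be non-negative")
  if (any(v_low <= v_high))
    stop("nesting violation: the lower-dose volume must exceed the higher-dose volume")
  denom <- (s_low + s_high) / 2
  if (any(denom <= 0)) stop("surface areas must be positive")
  (v_low - v_high) / denom
}

#' Closed-form DGI of two concentric spheres
#'
#' For a sphere of radius `r` expanded uniformly by `d`, the DGI evaluates
#' exactly to
#' \deqn{DGI_{sphere} = d \cdot \frac{(r+d) + d^2/(3r)}{(r+d) + d^2/(2r)},}
#' slightly below the true gap `d`. Used as an analytic oracle for the
#' voxel pipeline.
#'
#' @param r sphere radius in mm, `> 0`.
#' @param d gap between the two spheres in mm, `> 0`.
#' @return DGI in mm. Vectorised.
#' @export
dgi_sphere_analytic <- function(r, d) {
  stopifnot(all(r > 0), all(d > 0))
  d * ((r + d) + d^2 / (3 * r)) / ((r + d) + d^2 / (2 * r))
}

#' Closed-form DGI of two nested cubes
#'
#' For an axis-aligned cube of edge `a` expanded uniformly by `d` (outer
#' edge `a + 2d`):
#' \deqn{DGI_{cube} = d \cdot \frac{(a+2d) + 4d^2/(3a)}{(a+2d) + 4d^2/(2a)}.}
#'
#' @param a cube edge length in mm, `> 0`.
#' @param d uniform gap in mm, `> 0`.
#' @return DGI in mm. Vectorised.
#' @export
dgi_cube_analytic <- function(a, d) {
  stopifnot(all(a > 0), all(d > 0))
  d * ((a + 2 * d) + 4 * d^2 / (3 * a)) / ((a + 2 * d) + 4 * d^2 / (2 * a))
}

#' Relative error of the DGI estimator for simple shapes
#'
#' The DGI underestimates the true gap `d` by a curvature-driven factor; for
#' a sphere of radius `r`
#' \deqn{e_r = 1 - \frac{(r+d) + d^2/(3r)}{(r+d) + d^2/(2r)},}
#' for a cube with edge `a = 2r` the analogous expression reduces
#' algebraically to the same value, so the two simple shapes share one error
#' formula. For a 10 mm diameter and a 1 mm gap the error is 0.0055; at a
#' 0.3 mm gap it is 0.0006, i.e. negligible at clinical step sizes.
#'
#' @param size sphere radius `r` (mm) for `shape = "sphere"`, cube edge `a`
#'   (mm) for `shape = "cube"`.
#' @param d gap in mm, `> 0`.
#' @param shape `"sphere"` (default) or `"cube"`.
#' @return Dimensionless relative error in `[0, 1)`. Vectorised over `size`
#'   and `d`.
#' @export
#' @examples
#' dgi_relative_error(5, 1)    # 0.0055
#' dgi_relative_error(5, 0.3)  # 0.0006
dgi_relative_error <- function(size, d, shape = c("sphere", "cube")) {
  shape <- match.arg(shape)
  stopifnot(all(size > 0), all(d > 0))
  if (shape == "sphere") 1 - dgi_sphere_analytic(size, d) / d
  else 1 - dgi_cube_analytic(size, d) / d
}
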