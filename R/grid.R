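#' Rectilinear 3D scalar grid
#'
#' The basic volumetric container: a 3D array of scalar values (typically
#' dose in Gy) on a rectilinear grid with per-axis voxel spacing and an
#' origin, both in mm. Voxel `[i, j, k]` is centred at
#' `origin + (i - 1, j - 1, k - 1) * spacing`.
#'
#' @param values numeric 3D array. All values must be finite; dose grids are
#'   expected to be non-negative (checked by [dgc()]).
#' @param spacing numeric length 3, voxel size in mm per axis; strictly
#'   positive.
#' @param origin numeric length 3, position of the centre of voxel
#'   `[1, 1, 1]` in mm.
#' @return An object of class `dose_grid`: a list with elements `values`,
#'   `spacing`, `origin`.
#' @seealso [binary_mask()], [extract_isosurface()], [resample_grid()]
#' @export
#' @examples
#' g <- dose_grid(array(1, c(4, 4, 4)), spacing = c(1, 1, 2))
#' voxel_volume(g)
dose_grid <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  storage.mode(values) <- "double"
  if (!all(is.finite(values)))
    stop("grid values must all be finite")
  spacing <- rep_len(as.numeric(spacing), 3L)
  origin <- rep_len(as.numeric(origin), 3L)
  if (!all(is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be strictly positive on all axes")
  if (!all(is.finite(origin)))
    stop("'origin' must be finite")
  structure(list(values = values, spacing = spacing, origin = origin),
            class = "dose_grid")
}

#' Binary mask aligned to a dose grid
#'
#' A boolean 3D grid marking a structure (body, PTV, expansion layer) on the
#' same lattice as a companion [dose_grid()].
#'
#' @param values logical (or coercible) 3D array.
#' @inheritParams dose_grid
#' @return An object of class `binary_mask`: list with `values` (logical
#'   array), `spacing`, `origin`.
#' @export
binary_mask <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3D array")
  v <- array(as.logical(values), dim(values))
  if (anyNA(v)) stop("mask values must not contain NA")
  g <- dose_grid(array(0, dim(v)), spacing, origin)
  structure(list(values = v, spacing = g$spacing, origin = g$origin),
            class = "binary_mask")
}

#' @export
print.dose_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<dose_grid> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x ")))
  cat(sprintf("  origin (%s) mm, values in [%.4g, %.4g]\n",
              paste(signif(x$origin, 4), collapse = ", "),
              min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.binary_mask <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<binary_mask> %d x %d x %d voxels, spacing %s mm, %d voxels set (%.3g mm^3)\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = " x "),
              sum(x$values), sum(x$values) * prod(x$spacing)))
  invisible(x)
}

#' @export
dim.dose_grid <- function(x) dim(x$values)

#' @export
dim.binary_mask <- function(x) dim(x$values)

#' Voxel volume of a grid or mask
#' @param x a `dose_grid` or `binary_mask`.
#' @return Voxel volume in mm^3.
#' @export
voxel_volume <- function(x) prod(x$spacing)

#' Physical axis coordinates of a grid
#' @param x a `dose_grid` or `binary_mask`.
#' @return List of three numeric vectors: voxel-centre coordinates (mm) along
#'   each axis.
#' @export
grid_coords <- function(x) {
  d <- dim(x$values)
  lapply(1:3, function(a) x$origin[a] + (seq_len(d[a]) - 1) * x$spacing[a])
}

#' Volume of a binary mask
#' @param mask a `binary_mask`.
#' @return Total volume of the set voxels in mm^3.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  sum(mask$values) * voxel_volume(mask)
}

# check that two grid-like objects live on the same lattice
check_aligned <- function(a, b, what = "grids") {
  ok <- identical(dim(a$values), dim(b$values)) &&
    max(abs(a$spacing - b$spacing)) < 1e-9 &&
    max(abs(a$origin - b$origin)) < 1e-6
  if (!ok) stop(sprintf("%s are not aligned (shape/spacing/origin differ)", what))
  invisible(TRUE)
}

#' Trilinear resampling of a grid to a new spacing
#'
#' Dose grids coarser than 1 mm are conventionally resampled to 1 mm before
#' isodose extraction so that surface placement is not limited by the
#' calculation grid. Masks are resampled by thresholding the trilinear
#' interpolant at 0.5.
#'
#' @param x a `dose_grid` or `binary_mask`.
#' @param new_spacing numeric length 1 or 3, target spacing in mm.
#' @return Object of the same class as `x` covering the same physical extent.
#' @export
resample_grid <- function(x, new_spacing = 1) {
  is_mask <- inherits(x, "binary_mask")
  vals <- if (is_mask) array(as.numeric(x$values), dim(x$values)) else x$values
  sp <- rep_len(as.numeric(new_spacing), 3L)
  if (any(sp <= 0)) stop("'new_spacing' must be positive")
  d <- dim(vals)
  ext <- (d - 1) * x$spacing
  nd <- pmax(2L, as.integer(floor(ext / sp)) + 1L)
  co <- lapply(1:3, function(a) seq(0, by = sp[a], length.out = nd[a]))

  # fractional source indices per axis (0-based)
  fi <- lapply(1:3, function(a) pmin(pmax(co[[a]] / x$spacing[a], 0), d[a] - 1))
  lo <- lapply(seq_along(fi), function(a) pmin(as.integer(floor(fi[[a]])), d[a] - 2L))
  fr <- lapply(seq_along(fi), function(a) fi[[a]] - lo[[a]])

  ix <- lo[[1]] + 1L; jx <- lo[[2]] + 1L; kx <- lo[[3]] + 1L
  fx <- fr[[1]]; fy <- fr[[2]]; fz <- fr[[3]]

  out <- array(0, nd)
  FX <- array(fx, nd)
  FY <- array(rep(fy, each = nd[1]), nd)
  FZ <- array(rep(fz, each = nd[1] * nd[2]), nd)
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dx) FX else 1 - FX) * (if (dy) FY else 1 - FY) *
         (if (dz) FZ else 1 - FZ)
    out <- out + w * vals[ix + dx, jx + dy, kx + dz, drop = FALSE]
  }
  if (is_mask)
    binary_mask(out >= 0.5, spacing = sp, origin = x$origin)
  else
    dose_grid(out, spacing = sp, origin = x$origin)
}
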