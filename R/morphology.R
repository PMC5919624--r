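#' Euclidean distance transform of a binary mask
#'
#' Exact Euclidean distance (mm) from every voxel centre to the nearest set
#' voxel centre, aware of anisotropic spacing (separable
#' Felzenszwalb-Huttenlocher algorithm). Set voxels have distance 0.
#'
#' @param mask a [binary_mask()] with at least one voxel set.
#' @return A [dose_grid()] holding distances in mm.
#' @export
distance_transform <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$values)) stop("mask is empty: distance transform undefined")
  d <- cpp_edt(as.logical(mask$values), dim(mask$values), mask$spacing)
  dose_grid(array(d, dim(mask$values)), mask$spacing, mask$origin)
}

#' Signed distance field of a binary mask
#'
#' Negative inside the mask, positive outside, zero crossing halfway between
#' boundary voxel centres. The sub-voxel carrier used by [mask_surface()]
#' and the mask route of [make_multilayer()].
#'
#' @param mask a [binary_mask()] that is neither empty nor full.
#' @return A [dose_grid()] of signed distances in mm.
#' @export
signed_distance <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!any(mask$values) || all(mask$values))
    stop("signed distance requires a mask that is neither empty nor full")
  d_out <- distance_transform(mask)$values
  inv <- binary_mask(!mask$values, mask$spacing, mask$origin)
  d_in <- distance_transform(inv)$values
  dose_grid(d_out - d_in, mask$spacing, mask$origin)
}

#' Uniform expansion of a binary mask
#'
#' Isotropic margin growth: the result contains every voxel whose Euclidean
#' distance (mm, spacing-aware, voxel-centre convention) from the input
#' region is at most `distance`. Always a superset of the input. This is the
#' operation used to build multi-layer verification structures at known
#' spacing.
#'
#' @param mask a [binary_mask()].
#' @param distance expansion distance in mm, `>= 0`. Erosion is not
#'   expressed as negative expansion; see [crop_body()].
#' @return The expanded [binary_mask()].
#' @export
uniform_expand <- function(mask, distance) {
  stopifnot(inherits(mask, "binary_mask"))
  if (!is.numeric(distance) || length(distance) != 1L || !is.finite(distance))
    stop("'distance' must be a single finite number")
  if (distance < 0) stop("'distance' must be >= 0 (erosion is not an expansion)")
  if (distance == 0) return(mask)
  d <- distance_transform(mask)
  binary_mask(d$values <= distance, mask$spacing, mask$origin)
}

#' Crop a body mask away from the skin surface
#'
#' Erodes the body by `margin` mm (spacing-aware Euclidean erosion). The
#' cropped body is the evaluation domain for isodose extraction: isodose
#' surfaces are only trusted where they lie fully inside it, which keeps
#' build-up artefacts at the skin out of the analysis. The conventional
#' margin is 3 mm.
#'
#' @param body a [binary_mask()] of the patient/phantom body.
#' @param margin erosion margin in mm, `>= 0`.
#' @return The eroded [binary_mask()].
#' @export
crop_body <- function(body, margin = 3) {
  stopifnot(inherits(body, "binary_mask"))
  if (!is.numeric(margin) || length(margin) != 1L || !is.finite(margin) || margin < 0)
    stop("'margin' must be a single number >= 0")
  if (margin == 0) return(body)
  if (all(body$values)) {
    # no outside voxels on the grid: erode from the grid boundary instead
    d <- dim(body$values)
    shell <- array(TRUE, d)
    shell[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- FALSE
    inv <- binary_mask(shell, body$spacing, body$origin)
  } else {
    inv <- binary_mask(!body$values, body$spacing, body$origin)
  }
  d <- distance_transform(inv)
  out <- body$values & (d$values > margin)
  if (!any(out))
    stop(sprintf("cropping by %g mm empties the body mask", margin))
  binary_mask(out, body$spacing, body$origin)
}
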