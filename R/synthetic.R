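#' @title Synthetic verification structures and plans
#' @description Generators for every fixture the verification workflow
#'   needs: voxelized simple shapes, a smooth irregular "blob" with concave
#'   and convex surface, multi-layer uniformly expanded structures at known
#'   spacing, and SRS-like radial dose fields whose isodose surfaces are
#'   spheres of closed-form radius. All randomness is driven by explicit
#'   seeds; identical spec plus seed gives bit-identical output.
#' @name synthetic
NULL

# evaluate expr under a local RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  expr
}

# centred cubic grid: odd dimension count so a voxel centre sits at 0
centred_axis <- function(half_extent, spacing) {
  n <- 2L * as.integer(floor(half_extent / spacing)) + 1L
  (seq_len(n) - (n + 1L) / 2) * spacing
}

grid_points <- function(coords) {
  cbind(rep(coords[[1]], times = length(coords[[2]]) * length(coords[[3]])),
        rep(rep(coords[[2]], each = length(coords[[1]])), times = length(coords[[3]])),
        rep(coords[[3]], each = length(coords[[1]]) * length(coords[[2]])))
}

# smooth star-shaped blob: unit-sphere radius profile perturbed by Gaussian
# bumps (chordal kernel); amplitudes capped so the surface stays star-shaped
blob_spec <- function(volume, seed, n_bumps = 6) {
  with_seed(seed, {
    dirs <- matrix(stats::rnorm(3 * n_bumps), ncol = 3)
    dirs <- dirs / sqrt(rowSums(dirs^2))
    amp <- stats::runif(n_bumps, -0.22, 0.25)
    sigma <- stats::runif(n_bumps, 0.45, 0.8)
    # need both a concavity and a convexity
    if (all(amp >= 0)) amp[which.min(abs(amp))] <- -0.12
    if (all(amp <= 0)) amp[which.min(abs(amp))] <- 0.12
    cap <- 0.45
    if (sum(abs(amp)) > cap) amp <- amp * cap / sum(abs(amp))
    # calibrate r0 so the enclosed volume matches the request:
    # V = (r0^3 / 3) * integral (1 + P)^3 dOmega
    nq <- 120
    th <- (seq_len(nq) - 0.5) * pi / nq
    ph <- (seq_len(2 * nq) - 0.5) * pi / nq
    u <- cbind(rep(sin(th), times = 2 * nq) * rep(cos(ph), each = nq),
               rep(sin(th), times = 2 * nq) * rep(sin(ph), each = nq),
               rep(cos(th), times = 2 * nq))
    p <- blob_profile(u, dirs, amp, sigma)
    w <- rep(sin(th), times = 2 * nq) * (pi / nq)^2
    c3 <- sum(w * p^3) / (4 * pi)
    r0 <- (3 * volume / (4 * pi * c3))^(1 / 3)
    list(type = "blob", r0 = r0, dirs = dirs, amp = amp, sigma = sigma,
         max_radius = r0 * max(p), volume = volume, seed = seed)
  })
}

# radius profile multiplier (1 + perturbation) for unit directions u (n x 3)
blob_profile <- function(u, dirs, amp, sigma) {
  p <- rep(1, nrow(u))
  for (j in seq_along(amp)) {
    d2 <- (u[, 1] - dirs[j, 1])^2 + (u[, 2] - dirs[j, 2])^2 + (u[, 3] - dirs[j, 3])^2
    p <- p + amp[j] * exp(-d2 / (2 * sigma[j]^2))
  }
  p
}

# signed distance (mm, negative inside) from points (n x 3) to a shape spec
shape_signed_distance <- function(pts, spec) {
  if (spec$type == "sphere") {
    sqrt(rowSums(pts^2)) - spec$radius
  } else if (spec$type == "cube") {
    q <- abs(pts) - spec$edge / 2
    qp <- pmax(q, 0)
    sqrt(rowSums(qp^2)) + pmin(pmax(q[, 1], q[, 2], q[, 3]), 0)
  } else if (spec$type == "blob") {
    ntheta <- max(96L, as.integer(ceiling(pi * spec$r0 / 0.15)))
    cpp_star_signed_distance(pts, spec$dirs, spec$amp, spec$sigma,
                             spec$r0, ntheta, 9L)
  } else stop("unknown shape type")
}

shape_max_radius <- function(spec) {
  switch(spec$type,
         sphere = spec$radius,
         cube = sqrt(3) * spec$edge / 2,
         blob = spec$max_radius)
}

#' Voxelized shape mask
#'
#' Builds a centred binary mask of a sphere, an axis-aligned cube, or a
#' smooth irregular blob (a sphere perturbed by seeded smooth bumps, with
#' both concave and convex surface, calibrated so the enclosed volume is
#' within a few percent of `volume`).
#'
#' @param shape `"sphere"`, `"cube"` or `"blob"`.
#' @param size sphere radius or cube edge length in mm.
#' @param volume target blob volume in mm^3 (default 2500).
#' @param spacing voxel spacing in mm.
#' @param padding clearance between the shape and the grid boundary in mm.
#' @param half_extent optional grid half-width in mm; errors if the shape
#'   does not fit.
#' @param seed integer seed for the blob perturbation.
#' @return A [binary_mask()] with the generating spec attached as attribute
#'   `shape_spec`.
#' @export
#' @examples
#' m <- make_shape_mask("sphere", size = 15, spacing = 1)
#' mask_volume(m) / (4 / 3 * pi * 15^3) # ~ 1
make_shape_mask <- function(shape = c("sphere", "cube", "blob"), size = NULL,
                            volume = 2500, spacing = 1, padding = 2,
                            half_extent = NULL, seed = 1) {
  shape <- match.arg(shape)
  spec <- switch(shape,
    sphere = { stopifnot(is.numeric(size), size > 0); list(type = "sphere", radius = size) },
    cube = { stopifnot(is.numeric(size), size > 0); list(type = "cube", edge = size) },
    blob = { stopifnot(volume > 0); blob_spec(volume, seed) })
  maxr <- shape_max_radius(spec)
  he <- if (is.null(half_extent)) maxr + padding else half_extent
  if (maxr + spacing > he)
    stop("shape exceeds the grid: increase 'half_extent' or 'padding'")
  ax <- centred_axis(he, spacing)
  pts <- grid_points(list(ax, ax, ax))
  s <- shape_signed_distance(pts, spec)
  n <- length(ax)
  m <- binary_mask(array(s <= 0, c(n, n, n)), spacing = spacing,
                   origin = rep(ax[1], 3))
  attr(m, "shape_spec") <- spec
  m
}

#' Multi-layer uniformly expanded structure
#'
#' Builds the nested layer family `layer_n = base expanded by n * interval`
#' used to verify the DGI against a known ground-truth spacing. For the
#' analytic base shapes the layers are thresholds of the exact signed
#' distance to the continuous base surface, and that continuous field is
#' returned alongside the masks so isodose-style surfaces of each layer can
#' be extracted with sub-voxel accuracy (`field` holds the negated signed
#' distance: layer `n` is its superlevel set at `-n * interval`). A raw
#' [binary_mask()] base is also accepted, in which case the field is the
#' signed Euclidean distance transform of the mask ([signed_distance()]),
#' and the layers coincide with [uniform_expand()] of the base.
#'
#' @param base `"blob"` (default), `"sphere"`, `"cube"`, or a
#'   [binary_mask()].
#' @param size sphere radius / cube edge (mm) for the simple shapes.
#' @param volume blob volume target in mm^3.
#' @param n_layers number of layers including the base, `>= 2`.
#' @param interval layer spacing in mm, `> 0`.
#' @param spacing voxel spacing in mm.
#' @param seed blob seed.
#' @param padding grid clearance beyond the outermost layer in mm.
#' @return Object of class `multilayer`: list with `masks` (list of
#'   [binary_mask()], innermost first), `field` (a [dose_grid()]),
#'   `interval`, `n_layers` and the base `spec`.
#' @export
make_multilayer <- function(base = c("blob", "sphere", "cube"), size = NULL,
                            volume = 2500, n_layers = 4, interval = 1,
                            spacing = 0.5, seed = 1, padding = 2) {
  if (n_layers < 2) stop("'n_layers' must be at least 2")
  if (interval <= 0) stop("'interval' must be positive")
  reach <- (n_layers - 1) * interval

  if (inherits(base, "binary_mask")) {
    spec <- list(type = "mask")
    f <- signed_distance(base)
    # outermost layer must stay inside the grid
    edge <- f$values
    d <- dim(edge)
    shell <- c(edge[c(1, d[1]), , ], edge[, c(1, d[2]), ], edge[, , c(1, d[3])])
    if (min(shell) <= reach + spacing)
      stop("outermost layer exceeds the grid of the base mask")
    field <- dose_grid(-f$values, f$spacing, f$origin)
    msk <- function(t) binary_mask(f$values <= t, f$spacing, f$origin)
  } else {
    base <- match.arg(base)
    spec <- switch(base,
      sphere = { stopifnot(is.numeric(size), size > 0); list(type = "sphere", radius = size) },
      cube = { stopifnot(is.numeric(size), size > 0); list(type = "cube", edge = size) },
      blob = blob_spec(volume, seed))
    he <- shape_max_radius(spec) + reach + padding
    ax <- centred_axis(he, spacing)
    n <- length(ax)
    pts <- grid_points(list(ax, ax, ax))
    s <- array(shape_signed_distance(pts, spec), c(n, n, n))
    field <- dose_grid(-s, spacing = spacing, origin = rep(ax[1], 3))
    msk <- function(t) binary_mask(s <= t, spacing = spacing, origin = rep(ax[1], 3))
  }

  masks <- lapply(0:(n_layers - 1), function(i) msk(i * interval))
  structure(list(masks = masks, field = field, interval = interval,
                 n_layers = n_layers, spec = spec),
            class = "multilayer")
}

#' @export
print.multilayer <- function(x, ...) {
  cat(sprintf("<multilayer> %d layers at %g mm intervals, base %s, %d^3-ish grid at %g mm\n",
              x$n_layers, x$interval, x$spec$type,
              dim(x$field$values)[1], x$field$spacing[1]))
  invisible(x)
}

#' DGI recovered from a multi-layer structure
#'
#' Runs the full surface pipeline on a [make_multilayer()] fixture: extracts
#' the sub-voxel surface of each layer from the structure's continuous
#' expansion field, measures pooled area and volume, and evaluates the DGI
#' of layer pairs `gap` intervals apart. For an ideal pipeline every value
#' equals `gap * interval` up to the curvature error of the estimator
#' ([dgi_relative_error()]).
#'
#' @param ml a `multilayer` object.
#' @param gap layer separation (1 = adjacent layers, 2 = every second
#'   layer, ...).
#' @return Data frame with columns `inner_layer`, `outer_layer`,
#'   `surface_area_mm2` and `volume_mm3` of the outer layer, and `dgi_mm`.
#' @export
multilayer_dgi <- function(ml, gap = 1) {
  stopifnot(inherits(ml, "multilayer"))
  gap <- as.integer(gap)
  if (gap < 1 || gap > ml$n_layers - 1) stop("'gap' out of range")
  tt <- (0:(ml$n_layers - 1)) * ml$interval
  lv <- sort(-tt)  # ascending field levels, outermost layer first
  st <- cpp_isosurface_stats(as.numeric(ml$field$values), dim(ml$field$values),
                             ml$field$spacing, ml$field$origin, lv, NULL)
  if (any(st$open_edges > 0))
    stop("a layer surface touches the grid boundary; enlarge the fixture padding")
  # st rows: level -t ascending => layer index descending
  layer_of <- as.integer(round(-st$level / ml$interval))
  o <- order(layer_of)
  A <- st$area[o]; V <- st$volume[o]
  n <- ml$n_layers
  inner <- 0:(n - 1 - gap)
  outer <- inner + gap
  data.frame(inner_layer = inner, outer_layer = outer,
             surface_area_mm2 = A[outer + 1L], volume_mm3 = V[outer + 1L],
             dgi_mm = dgi(V[outer + 1L], A[outer + 1L], V[inner + 1L], A[inner + 1L]))
}

#' Synthetic SRS-like plan with closed-form isodose geometry
#'
#' Emulates a single-target stereotactic plan: a spherical target of radius
#' `target_radius` receiving `reference_dose` at its surface, a hot core
#' capped at `core_max_pct` percent, and a monotone radial power-law
#' fall-off outside,
#' \deqn{D(r) = D_{ref} \cdot \min(c_{max}/100, (R_t / r)^k),}
#' so every isodose surface between the core cap and the lowest analysed
#' dose is a sphere of radius \eqn{r_f = R_t f^{-1/k}} for dose fraction
#' `f` (see [isodose_radius()]). This makes the whole dose-gradient pipeline
#' verifiable against closed forms without a treatment planning system.
#'
#' @param target_radius PTV radius in mm (3 cm diameter target: 15).
#' @param reference_dose prescription dose in Gy at the target surface
#'   (100% level).
#' @param falloff_exponent radial power `k > 0`; ~2 mimics steep SRS
#'   gradients.
#' @param core_max_pct maximum dose inside the target as % of reference.
#' @param grid_spacing voxel spacing in mm.
#' @param body_radius body (phantom) sphere radius in mm; must exceed the
#'   lowest isodose of interest plus the crop margin.
#' @param center target centre in mm.
#' @param noise_sd optional Gaussian dose noise (Gy) added with `seed`.
#' @param seed integer seed for the noise.
#' @return Object of class `radial_plan`: list with `dose` ([dose_grid()]),
#'   `body`, `ptv` ([binary_mask()]) and the generating parameters.
#' @export
make_radial_dose <- function(target_radius = 15, reference_dose = 15,
                             falloff_exponent = 2, core_max_pct = 125,
                             grid_spacing = 1, body_radius = 40,
                             center = c(0, 0, 0), noise_sd = 0, seed = NULL) {
  stopifnot(target_radius > 0, reference_dose > 0, falloff_exponent > 0,
            core_max_pct > 100, grid_spacing > 0)
  if (body_radius <= target_radius)
    stop("body must be larger than the target (and than the lowest analysed isodose)")
  he <- body_radius + 2 * grid_spacing
  ax <- centred_axis(he, grid_spacing)
  n <- length(ax)
  pts <- grid_points(list(ax, ax, ax))  # centred on the target
  rho <- sqrt(rowSums(pts^2))
  frac <- ifelse(rho < 1e-12, core_max_pct / 100,
                 pmin(core_max_pct / 100, (target_radius / rho)^falloff_exponent))
  dose <- reference_dose * frac
  if (noise_sd > 0)
    dose <- pmax(0, dose + with_seed(seed, stats::rnorm(length(dose), 0, noise_sd)))
  org <- ax[1] + as.numeric(center)
  dg <- dose_grid(array(dose, c(n, n, n)), spacing = grid_spacing, origin = org)
  body <- binary_mask(array(rho <= body_radius, c(n, n, n)), grid_spacing, org)
  ptv <- binary_mask(array(rho <= target_radius, c(n, n, n)), grid_spacing, org)
  structure(list(dose = dg, body = body, ptv = ptv,
                 target_radius = target_radius, reference_dose = reference_dose,
                 falloff_exponent = falloff_exponent, core_max_pct = core_max_pct,
                 body_radius = body_radius),
            class = "radial_plan")
}

#' @export
print.radial_plan <- function(x, ...) {
  cat(sprintf("<radial_plan> target r = %g mm, %g Gy at 100%%, fall-off r^-%g, core %g%%, body r = %g mm\n",
              x$target_radius, x$reference_dose, x$falloff_exponent,
              x$core_max_pct, x$body_radius))
  invisible(x)
}

#' Closed-form isodose radius of a radial plan
#'
#' @param plan a [make_radial_dose()] plan.
#' @param pct isodose level(s) in % of the reference dose; must lie at or
#'   below the core cap (`NA` above it, where no surface exists).
#' @return Radius in mm: `target_radius * (pct/100)^(-1/k)`.
#' @export
isodose_radius <- function(plan, pct) {
  stopifnot(inherits(plan, "radial_plan"))
  out <- plan$target_radius * (pct / 100)^(-1 / plan$falloff_exponent)
  out[pct > plan$core_max_pct] <- NA_real_
  out
}

#' Rescale a dose grid to prescribe at a different isodose level
#'
#' Linear renormalization: scales the dose so that the surface previously
#' receiving `isodose_pct` percent of `reference` now receives the
#' prescription. After renormalizing to 80%, the old 80% isodose surface is
#' the new 100% surface with identical geometry (area and volume are
#' untouched by the relabelling).
#'
#' @param grid a [dose_grid()].
#' @param prescription prescription dose in Gy.
#' @param isodose_pct prescription isodose level in `(0, 100]`.
#' @param reference dose in Gy corresponding to the grid's 100% level
#'   (default `prescription`).
#' @return The rescaled [dose_grid()].
#' @export
renormalize_to_isodose <- function(grid, prescription, isodose_pct,
                                   reference = prescription) {
  stopifnot(inherits(grid, "dose_grid"))
  if (!is.numeric(isodose_pct) || length(isodose_pct) != 1L ||
      isodose_pct <= 0 || isodose_pct > 100)
    stop("'isodose_pct' must be in (0, 100]")
  factor <- prescription / (isodose_pct / 100 * reference)
  if (!is.finite(factor) || factor <= 0)
    stop("non-positive scaling factor")
  dose_grid(grid$values * factor, grid$spacing, grid$origin)
}
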