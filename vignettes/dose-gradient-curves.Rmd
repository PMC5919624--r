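---
title: "Dose gradient curves: model, estimator and verification strategy"
author: "dgcurve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose gradient curves: model, estimator and verification strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4.2)
library(dgcurve)
```

## The problem and the model

Stereotactic radiosurgery (SRS) and ablative radiotherapy deliver very high
doses in few fractions, so plan quality hinges not only on covering the
target but on how *fast* the dose falls off outside it. The dose-volume
histogram answers the coverage question; the classical gradient scores
(GI = $V_{50\%}/V_{100\%}$, R50% = $V_{50\%}/V_{PTV}$) compress the entire
fall-off into one volume ratio, are blind to everything between two isodose
levels, and scale strongly with target volume and shape.

This package evaluates the fall-off as a *distance*. Because isodose
surfaces of a dose distribution are nested and never intersect, the average
distance between the surfaces of a lower dose $L$ and a higher dose $H$ can
be estimated from their enclosed volumes $V$ and surface areas $S$ alone:

$$\mathrm{DGI} = \frac{V_L - V_H}{\tfrac12 (S_L + S_H)} \quad [\mathrm{mm}].$$

Geometrically this is the width of the shell between the two surfaces
divided by its mean wall area; the shorter the distance, the steeper the
gradient, independent of how large or irregular the target is.

Two curves are built from the index over a uniform grid of dose levels with
calculation interval $d$:

* the **differential curve** $dDGI_i = (V_i - V_{i+d}) / \tfrac12 (S_i +
  S_{i+d})$, the local gradient at each dose level; for a typical
  single-target plan it is U-shaped, with the minimum (steepest gradient)
  just below the prescription;
* the **cumulative curve** $cDGI_i = \sum_{j=i}^{D_0-d} dDGI_j$ with
  $cDGI_{D_0} = 0$: the average distance from the reference isodose surface
  $D_0$ to every lower surface. It is strictly increasing as dose falls,
  and — unlike the raw differential curve — independent of the step size,
  which makes it the right curve for comparing rival plans.

The raw differential curve scales with the step ($dDGI \approx d \cdot
|\nabla D|^{-1}$ locally), so curves computed at different steps are
compared after dividing by the step (`normalize_ddgc()`).

### Estimator error

For two concentric spheres of radius $r$ and $r + d$ the index evaluates in
closed form to

$$\mathrm{DGI}_{sphere} = d \cdot
  \frac{(r+d) + d^2/(3r)}{(r+d) + d^2/(2r)} < d,$$

and for nested cubes (edge $a$, gap $d$) to the analogous expression with
$4d^2/(3a)$ and $4d^2/(2a)$. Substituting $a = 2r$ into the cube expression
cancels a factor 2 and reproduces the sphere expression *exactly*: the two
simple shapes share one relative-error formula,

$$e_r = 1 - \frac{(r+d) + d^2/(3r)}{(r+d) + d^2/(2r)},$$

which is 0.0055 for a 10 mm diameter and a 1 mm gap and 0.0006 at a 0.3 mm
gap. The error is quadratic in $d/r$, so at the recommended step sizes
(≤ 1% or 1 Gy) the index is exact to well under $10^{-2}$ mm in any
clinically relevant geometry. These closed forms are implemented as
`dgi_sphere_analytic()`, `dgi_cube_analytic()` and `dgi_relative_error()`
and serve as machine-precision oracles for the estimator
(`dgi()` fed exact sphere/cube areas and volumes must agree to $10^{-12}$).

## From dose grid to curve

`dgc()` runs the pipeline:

1. **Body crop.** The body mask is eroded by `crop_margin` (default 3 mm,
   exact Euclidean erosion) and becomes the evaluation domain. Surfaces in
   the build-up region at the skin are dosimetrically meaningless; the crop
   keeps them out.
2. **Isodose extraction.** Each superlevel set $\{D \ge$ level$\}$ is
   triangulated by marching tetrahedra (each grid cell split into six
   tetrahedra around a fixed diagonal, surface vertices placed by linear
   interpolation along grid edges). The decomposition is translation
   invariant, so the mesh is watertight by construction wherever the set
   stays inside the domain, and sub-voxel accurate on smooth fields. All
   disconnected components of a level are pooled into a single area/volume
   record, because the index is defined on totals.
3. **Range truncation.** A level whose surface would be clipped by the
   domain boundary yields open mesh edges; such levels — and everything
   below the highest of them — are excluded rather than capped, since
   capping would corrupt the surface area. The analysed range therefore
   runs from the highest level below the dose maximum down to the lowest
   level that closes strictly inside the cropped body, and the fit records
   that truncation dose.
4. **Curves and indices.** Differential, normalized and cumulative curves
   are tabulated; with a target mask the DVH, D100%, GI and R50% are
   computed as well (voxel-counting DVH, default bin 0.1% of the reference
   dose).

### Parameters that matter

| parameter | unit | default | meaning |
|---|---|---|---|
| `step` | % of reference (or Gy) | 1 | calculation interval $d$; ≤ 1% recommended — the cumulative curve is step-free anyway |
| `crop_margin` | mm | 3 | body erosion before extraction |
| `reference` | — | `"prescription"` | anchor $D_0$ of the cumulative curve; `"d100"` anchors at the minimum dose covering the full target, so the curve starts at 100% coverage |
| `dose_scale` | — | `"percent"` | percent is relative to the *reference* dose; `"gy"` gives the same physical levels when `step` is scaled accordingly |
| `resample_to` | mm | 1 | grids coarser than this are resampled trilinearly before extraction |

The reference level must coincide with a tabulated level ("d100" is snapped
to the nearest one); the cumulative curve is undefined above it and the
table carries `NA` there by design. Flat dose plateaus (equal consecutive
volumes) report $dDGI = 0$ with a warning instead of failing the strict
nesting precondition — they occur at the artificial core cap of synthetic
plans, not in realistic dose fields.

## Numerical choices

* **Superlevel convention.** An "isodose volume" is the closed set
  $\{D \ge \mathrm{level}\}$, matching the usage "volume of the half-
  prescription isodose". Volumes are then non-increasing in the level by
  construction, and a violation in a table is rejected as a nesting error.
* **Exact-level degeneracy.** A grid node lying exactly on the level would
  create zero-area triangles and ambiguous topology; node values equal to
  the level are nudged by $10^{-9}(1 + |\mathrm{level}|)$ before
  classification, deterministically.
* **Distance transforms.** Expansion and erosion use the exact separable
  Euclidean distance transform with anisotropic spacing; voxels are
  classified by centre position. Expansion by $t$ keeps voxels whose centre
  lies within $t$ of the structure, erosion is its dual.
* **Mask surfaces.** The surface of a *binary* structure is extracted from
  its signed distance field at level zero and then faired with
  volume-preserving Taubin smoothing (default 60 passes,
  $\lambda = 0.5, \mu = -0.53$). The raw mid-surface carries the voxel
  staircase, which inflates area by 15–20% while leaving volume nearly
  unbiased; Taubin fairing removes the staircase without the inward
  curvature bias that field-space smoothing would introduce (a Gaussian on
  the distance field shifts the zero level by $\sigma^2 \kappa$, several
  percent of volume for small spheres). With fairing, voxelized spheres of
  5–15 mm radius on a 1 mm grid recover analytic volume within 2% and area
  within 3%, tightening as the grid is refined.
* **Rounding.** All arithmetic is kept in double precision; two-decimal
  rounding happens only in printed summaries, and the CSV serialization
  stores 17 significant digits so tables round-trip exactly.

## What the synthetic plans emulate — and what they do not

Clinical SRS dose grids come from a treatment planning system that is not
reproducible at desk scale, so verification rests on three synthetic
families whose isodose geometry is known in closed form:

* `make_radial_dose()` builds a single spherical target of radius $R_t$
  receiving the reference dose at its surface, a hot core capped at
  `core_max_pct` (default 125%), and a radial power-law fall-off
  $D(r) = D_{ref} \min(c_{max}/100, (R_t/r)^k)$. Every isodose surface at
  fraction $f$ of the reference is a sphere of radius
  $r_f = R_t f^{-1/k}$, so the whole pipeline — extraction, curves, GI —
  can be checked against exact radii. The default $k = 2$ produces
  fall-off distances (e.g. $cDGI_{50\%} \approx 6.2$ mm for a 3 cm target)
  of the same order as published single-target dynamic-arc plans. The cap
  is an exact `min`, not a smooth blend, so the closed forms stay exact;
  analysed levels sit below the cap.
* `make_multilayer()` reproduces the classical expansion experiment: a
  base structure uniformly expanded $n$ times at a known interval, the
  ground truth for the DGI being the interval itself. For the analytic
  bases (sphere, cube, blob) the layers are thresholds of the *exact*
  signed distance to the continuous base surface and that field is carried
  along for sub-voxel surface extraction; thresholding a voxel-mask
  distance transform instead would quantize the base surface at half a
  voxel and dominate the error budget at sub-voxel intervals (0.3 mm).
  A raw mask base falls back to the mask distance-transform route and then
  agrees with `uniform_expand()` voxel for voxel.
* The **blob** (`make_shape_mask("blob")`) is a sphere whose radius
  profile is perturbed by a handful of seeded smooth Gaussian bumps on the
  sphere, with at least one concavity and one convexity, amplitudes capped
  so the shape stays star-shaped (total relative amplitude ≤ 0.45), and
  the base radius calibrated by quadrature so the enclosed volume hits the
  request within a few percent. Signed distances to the blob surface are
  computed by descent over a dense surface sample grid (~0.15 mm arc
  spacing) with nine rounds of local refinement, i.e. exact to well below
  the grid resolution.

All generators take explicit seeds and are bit-reproducible; none of them
model arc geometry, collimator effects, tissue heterogeneity, dose noise
(available only as an optional additive term) or multi-target plans. A
passing pipeline on these fields demonstrates correctness of the geometry
and curve arithmetic — it does not validate any particular planning
system's dose calculation.

## Verification problem sizes

The shipped tests run the full pipeline at the sizes a desk verification
needs: the multi-layer recovery uses a 2.5 cm³ blob on a 0.5 mm grid with
four layers at intervals of 0.3, 1, 2 and 3 mm (recovered DGI within 3% of
the interval; the bundled reference table for the same experiment on a
planning system showed 0.991–1.023 mm at a 1 mm interval); the step-size
study uses the 3 cm target plan on a 1 mm grid, 40 mm body, steps of 0.5,
1, 2 and 4% (normalized differential curves agree within 5%, cumulative
curves within 0.1 mm); sphere recovery uses radii of 5–15 mm at 1 and
0.5 mm spacing.

## A worked example

```{r example}
plan <- make_radial_dose(target_radius = 15, reference_dose = 15,
                         falloff_exponent = 2, body_radius = 40)
fit <- dgc(plan$dose, prescription = 15, body = plan$body, ptv = plan$ptv)
fit
coef(fit)
```

The cumulative value at 50% is, up to the curvature error of the
estimator, the distance between the 50% and 100% isodose spheres,
$15(\sqrt2 - 1) \approx 6.21$ mm:

```{r cdgi50}
c(fitted = cdgi_at(fit$table, 50),
  analytic = isodose_radius(plan, 50) - isodose_radius(plan, 100))
```

```{r plots, fig.show = "hold"}
plot(fit, type = "differential")
plot(fit, type = "combined")
```

## Known limitations

* The curve is an *average* distance; it carries no directional
  information. A sector-restricted variant would be needed to interrogate
  the gradient toward a specific organ at risk.
* Surface areas of clipped isodose levels are undefined in this framework;
  the truncation rule drops those levels entirely, so a plan whose
  low-dose spill reaches the cropped body surface is only characterised
  down to the truncation dose (which the fit reports).
* DICOM input is not parsed; dose grids and masks arrive as NRRD or NIfTI
  volumes, and structure-set contours must be rasterised upstream.
* The DVH uses voxel counting without sub-voxel averaging, adequate at
  ~1 mm grids but coarse for very small structures.
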