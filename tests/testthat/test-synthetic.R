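test_that("voxelized shapes hit their target sizes", {
  sph <- make_shape_mask("sphere", size = 15, spacing = 1)
  expect_equal(mask_volume(sph), 4 / 3 * pi * 15^3, tolerance = 0.02)

  cb <- make_shape_mask("cube", size = 10, spacing = 0.5)
  # voxel-centre counting is exact up to the half-voxel boundary shell
  expect_equal(mask_volume(cb), 1000, tolerance = 0.16)

  bl <- make_shape_mask("blob", volume = 2500, spacing = 0.5, seed = 11)
  expect_equal(mask_volume(bl), 2500, tolerance = 0.05)
})

test_that("the blob is star-shaped with concave and convex regions, reproducibly", {
  b1 <- make_shape_mask("blob", volume = 2500, spacing = 1, seed = 5)
  b2 <- make_shape_mask("blob", volume = 2500, spacing = 1, seed = 5)
  expect_identical(b1$values, b2$values)
  b3 <- make_shape_mask("blob", volume = 2500, spacing = 1, seed = 6)
  expect_false(identical(b1$values, b3$values))
  spec <- attr(b1, "shape_spec")
  expect_true(any(spec$amp > 0) && any(spec$amp < 0))
  expect_lt(sum(abs(spec$amp)), 1)  # radius stays positive: star-shaped
})

test_that("shape generation errors when the shape exceeds the grid", {
  expect_error(make_shape_mask("sphere", size = 30, spacing = 1,
                               half_extent = 20), "exceeds the grid")
})

test_that("multilayer structures are strictly nested and reproducible", {
  ml <- make_multilayer("blob", volume = 2000, n_layers = 4, interval = 1.5,
                        spacing = 1, seed = 2)
  for (i in 1:3) {
    inner <- ml$masks[[i]]$values
    outer <- ml$masks[[i + 1]]$values
    expect_true(all(outer[inner]))          # nesting
    expect_gt(sum(outer), sum(inner))       # strict growth
  }
  ml2 <- make_multilayer("blob", volume = 2000, n_layers = 4, interval = 1.5,
                         spacing = 1, seed = 2)
  expect_identical(ml$field$values, ml2$field$values)
  expect_error(make_multilayer("sphere", size = 5, n_layers = 1), "at least 2")
})

test_that("mask-based multilayer layers coincide with uniform expansion", {
  base <- make_shape_mask("sphere", size = 6, spacing = 1, padding = 7)
  ml <- make_multilayer(base, n_layers = 3, interval = 2)
  expect_identical(ml$masks[[1]]$values, base$values)
  expect_identical(ml$masks[[2]]$values, uniform_expand(base, 2)$values)
  expect_identical(ml$masks[[3]]$values, uniform_expand(base, 4)$values)
})

test_that("adjacent-layer DGI recovers the 1 mm interval within the reference band", {
  ml <- make_multilayer("blob", volume = 2500, n_layers = 5, interval = 1,
                        spacing = 0.5, seed = 7)
  res <- multilayer_dgi(ml, gap = 1)
  # reference implementation reported 0.991-1.023 mm for this experiment
  expect_true(all(res$dgi_mm > 0.97 & res$dgi_mm < 1.03))
  res2 <- multilayer_dgi(ml, gap = 2)
  expect_true(all(abs(res2$dgi_mm - 2) < 0.05))
})

test_that("radial plans expose exact closed-form isodose geometry", {
  plan <- fix_radial_plan()
  # dose at the target surface equals the reference exactly (closed form)
  expect_equal(isodose_radius(plan, 100), 15)
  expect_equal(isodose_radius(plan, 50), 15 * sqrt(2))
  expect_true(is.na(isodose_radius(plan, 130)))
  # voxel just outside the target carries slightly less than the reference
  co <- grid_coords(plan$dose)
  i0 <- which.min(abs(co[[1]]))
  i15 <- which.min(abs(co[[1]] - 15))
  expect_equal(plan$dose$values[i15, i0, i0],
               15 * (15 / abs(co[[1]][i15]))^2, tolerance = 1e-12)
  expect_error(make_radial_dose(target_radius = 15, body_radius = 10),
               "body must be larger")
})

test_that("renormalization is a pure relabelling of isodose surfaces", {
  plan <- fix_small_plan()
  re <- renormalize_to_isodose(plan$dose, prescription = 18, isodose_pct = 80)
  # voxelwise ratio is constant
  expect_equal(max(abs(re$values / plan$dose$values - 100 / 80)), 0,
               tolerance = 1e-12)
  # the old 80% surface is the new 100% surface: identical V and S
  m_old <- extract_isosurface(plan$dose, 0.8 * 18)
  m_new <- extract_isosurface(re, 18)
  expect_equal(mesh_volume(m_new), mesh_volume(m_old), tolerance = 1e-10)
  expect_equal(mesh_surface_area(m_new), mesh_surface_area(m_old),
               tolerance = 1e-10)
  # unchanged when prescribing at 100% of an already-normalized plan
  same <- renormalize_to_isodose(plan$dose, 18, 100)
  expect_equal(same$values, plan$dose$values)
  expect_error(renormalize_to_isodose(plan$dose, 18, 0), "\\(0, 100\\]")
})
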