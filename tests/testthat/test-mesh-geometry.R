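test_that("triangle areas and cube surface area are exact", {
  tri <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                       rbind(c(1, 2, 3)))
  expect_equal(mesh_surface_area(tri), 0.5)

  cm <- cube_mesh(1)
  expect_equal(mesh_surface_area(cm), 6)
  expect_equal(mesh_volume(cm), 1)

  # degenerate triangle contributes zero area, no error
  dg <- triangle_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                      rbind(c(1, 2, 3)))
  expect_equal(mesh_surface_area(dg), 0)
})

test_that("icosphere area and volume converge to the sphere from below", {
  r <- 10
  prev_a <- 0
  prev_v <- 0
  for (s in 1:4) {
    m <- icosphere(r, subdiv = s)
    a <- mesh_surface_area(m)
    v <- mesh_volume(m)
    expect_lt(a, 4 * pi * r^2)
    expect_lt(v, 4 / 3 * pi * r^3)
    expect_gt(a, prev_a)
    expect_gt(v, prev_v)
    prev_a <- a
    prev_v <- v
  }
  expect_equal(prev_a, 4 * pi * 100, tolerance = 3e-3)
  expect_equal(prev_v, 4 / 3 * pi * 1000, tolerance = 3e-3)
})

test_that("flipping all faces negates the signed volume", {
  m <- icosphere(5, 1)
  flipped <- triangle_mesh(m$vertices, m$faces[, c(1, 3, 2)])
  expect_equal(mesh_volume(flipped), -mesh_volume(m))
})

test_that("volume of a non-closed mesh errors with the open-edge count", {
  cm <- cube_mesh(1)
  open_mesh <- triangle_mesh(cm$vertices, cm$faces[-1, ])
  expect_equal(mesh_open_edges(open_mesh), 3L)
  expect_error(mesh_volume(open_mesh), "3 open edges")
})

test_that("isosurface of an analytic radial dose sits at the analytic radius", {
  # D(r) = 18 * min(1, (7.5 / r)^2) Gy on a 0.5 mm grid: the 9 Gy surface is
  # the sphere of radius 7.5 * sqrt(2)
  plan <- make_radial_dose(target_radius = 7.5, reference_dose = 18,
                           falloff_exponent = 2, core_max_pct = 100.01,
                           grid_spacing = 0.5, body_radius = 14)
  m <- extract_isosurface(plan$dose, 9)
  radii <- sqrt(rowSums(m$vertices^2))
  expect_lt(max(abs(radii - 7.5 * sqrt(2))), 0.25)  # within half a voxel
  expect_equal(mesh_volume(m), 4 / 3 * pi * (7.5 * sqrt(2))^3, tolerance = 0.01)
})

test_that("levels outside the dose range raise an empty-isodose error", {
  plan <- fix_small_plan()
  expect_error(extract_isosurface(plan$dose, 100), "empty isodose")
  expect_error(extract_isosurface(plan$dose, 0), "empty isodose")
})

test_that("disjoint hot spots yield one mesh with two components whose area/volume add", {
  ax <- seq(-20, 20, by = 1)
  n <- length(ax)
  pts <- as.matrix(expand.grid(x = ax, y = ax, z = ax))
  d1 <- sqrt(rowSums(sweep(pts, 2, c(-10, 0, 0))^2))
  d2 <- sqrt(rowSums(sweep(pts, 2, c(10, 0, 0))^2))
  dose <- 10 * exp(-(d1 / 6)^2) + 10 * exp(-(d2 / 6)^2)
  g <- dose_grid(array(dose, c(n, n, n)), spacing = 1, origin = c(-20, -20, -20))

  m <- extract_isosurface(g, 5)
  expect_equal(attr(m, "n_components"), 2L)

  # each sphere alone
  g1 <- dose_grid(array(10 * exp(-(d1 / 6)^2), c(n, n, n)), 1, c(-20, -20, -20))
  g2 <- dose_grid(array(10 * exp(-(d2 / 6)^2), c(n, n, n)), 1, c(-20, -20, -20))
  m1 <- extract_isosurface(g1, 5)
  m2 <- extract_isosurface(g2, 5)
  expect_equal(mesh_surface_area(m),
               mesh_surface_area(m1) + mesh_surface_area(m2), tolerance = 1e-3)
  expect_equal(mesh_volume(m), mesh_volume(m1) + mesh_volume(m2),
               tolerance = 1e-3)
})

test_that("superlevel-set volumes are non-increasing in the level", {
  plan <- fix_small_plan()
  vols <- vapply(seq(4, 20, by = 2), function(lv)
    mesh_volume(extract_isosurface(plan$dose, lv)), 0)
  expect_true(all(diff(vols) < 0))
})

test_that("voxelized sphere surfaces recover analytic area and volume", {
  # 1 mm grid: volume within 2%, area within 3%; halving the spacing tightens
  for (r in c(5, 10, 15)) {
    mk <- make_shape_mask("sphere", size = r, spacing = 1, padding = 4)
    m <- mask_surface(mk)
    expect_equal(mesh_volume(m), 4 / 3 * pi * r^3, tolerance = 0.02)
    expect_equal(mesh_surface_area(m), 4 * pi * r^2, tolerance = 0.03)
  }
  # halving the spacing tightens the area error (the dominant term) and
  # keeps the already sub-percent volume error sub-percent
  mk1 <- make_shape_mask("sphere", size = 10, spacing = 1, padding = 4)
  mk05 <- make_shape_mask("sphere", size = 10, spacing = 0.5, padding = 4)
  err <- function(m) abs(c(mesh_volume(m) / (4 / 3 * pi * 1e3) - 1,
                           mesh_surface_area(m) / (4 * pi * 100) - 1))
  e1 <- err(mask_surface(mk1))
  e05 <- err(mask_surface(mk05))
  expect_lt(e05[2], e1[2])
  expect_lt(e05[1], 0.01)
})

test_that("extraction restricted to a domain flags clipped surfaces as open", {
  plan <- fix_small_plan()
  small_dom <- uniform_expand(plan$ptv, 2)
  expect_warning(m <- extract_isosurface(plan$dose, 12, domain = small_dom),
                 "touches the domain boundary")
  expect_true(attr(m, "open"))
  expect_gt(mesh_open_edges(m), 0L)
})
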