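test_that("dgi reproduces the reference multi-layer measurements", {
  tb <- layer_table()
  # adjacent layers (1 mm gap)
  got <- dgi(tb$volume_mm3[2], tb$surface_area_mm2[2],
             tb$volume_mm3[1], tb$surface_area_mm2[1])
  expect_equal(got, 1.023454, tolerance = 1e-6)
  # three-layer gap
  got3 <- dgi(tb$volume_mm3[4], tb$surface_area_mm2[4],
              tb$volume_mm3[1], tb$surface_area_mm2[1])
  expect_equal(got3, 3.003796, tolerance = 1e-6)
})

test_that("dgi vanishes in the zero-gap limit and enforces nesting", {
  v <- 1000
  s <- 480
  eps <- 10^seq(-3, -9, by = -1)
  vals <- dgi(v + eps, s, v, s)
  expect_true(all(diff(vals) < 0))
  expect_lt(vals[length(eps)], 1e-11)

  expect_error(dgi(10, 5, 10, 5), "nesting violation")
  expect_error(dgi(5, 5, 10, 5), "nesting violation")
})

test_that("closed forms agree with dgi on exact sphere/cube geometry to machine precision", {
  for (r in c(2.5, 5, 10, 20)) {
    for (d in c(0.3, 1, 2)) {
      exact <- dgi(4 / 3 * pi * (r + d)^3, 4 * pi * (r + d)^2,
                   4 / 3 * pi * r^3, 4 * pi * r^2)
      expect_equal(dgi_sphere_analytic(r, d), exact, tolerance = 1e-13)
      a <- 2 * r
      exact_c <- dgi((a + 2 * d)^3, 6 * (a + 2 * d)^2, a^3, 6 * a^2)
      expect_equal(dgi_cube_analytic(a, d), exact_c, tolerance = 1e-13)
    }
  }
})

test_that("the analytic DGI relative error matches its reference values", {
  expect_equal(round(dgi_relative_error(5, 1), 4), 0.0055)
  expect_equal(round(dgi_relative_error(5, 0.3), 4), 0.0006)
  # exact in the limit d -> 0
  expect_lt(dgi_relative_error(5, 1e-6), 1e-7)
  expect_lt(dgi_relative_error(10, 1e-6, shape = "cube"), 1e-7)
  # under a = 2r the cube expression reduces algebraically to the sphere's:
  # the two shapes share one error formula exactly
  expect_equal(dgi_relative_error(5, 1),
               dgi_relative_error(10, 1, shape = "cube"), tolerance = 1e-14)
})

test_that("dgi_sphere/cube approach the true gap as d shrinks", {
  d <- c(1, 0.3, 0.1, 0.01)
  expect_true(all(diff(dgi_sphere_analytic(5, d) / d) > 0))
  expect_equal(dgi_sphere_analytic(5, 1e-8) / 1e-8, 1, tolerance = 1e-8)
  expect_equal(dgi_cube_analytic(10, 1e-8) / 1e-8, 1, tolerance = 1e-8)
})
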