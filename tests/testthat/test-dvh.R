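test_that("DVH of a uniform dose is a step function", {
  arr <- array(10, c(8, 8, 8))
  g <- dose_grid(arr, spacing = 1)
  st <- binary_mask(array(TRUE, c(8, 8, 8)), spacing = 1)
  dvh <- compute_dvh(g, st, bin_width = 0.5)
  expect_true(all(dvh$relative_volume[dvh$dose_gy <= 10] == 1))
  expect_true(all(dvh$relative_volume[dvh$dose_gy > 10] == 0))
  expect_equal(d_at_volume(dvh, 1), 10, tolerance = 0.5)
})

test_that("DVH invariants hold on an arbitrary synthetic field", {
  plan <- fix_small_plan()
  dvh <- compute_dvh(plan$dose, plan$ptv)
  expect_true(all(diff(dvh$relative_volume) <= 0))
  expect_true(all(dvh$relative_volume >= 0 & dvh$relative_volume <= 1))
  expect_equal(dvh$relative_volume[1], 1)
  expect_equal(dvh$relative_volume[nrow(dvh)], 0)
  # D100% does not exceed any voxel dose (within one bin)
  d100 <- d_at_volume(dvh, 1)
  expect_lte(d100, min(plan$dose$values[plan$ptv$values]) + attr(dvh, "bin_width"))
})

test_that("DVH of a radial dose over a shell matches closed-form volume fractions", {
  # shell between 10 and 15 mm of D = 18 (7.5/r)^2: the fraction receiving
  # >= D(r0) is (r0^3 - 10^3) / (15^3 - 10^3)
  plan <- make_radial_dose(target_radius = 7.5, reference_dose = 18,
                           falloff_exponent = 2, core_max_pct = 120,
                           grid_spacing = 0.5, body_radius = 17)
  co <- grid_coords(plan$dose)
  rho <- sqrt(outer(outer(co[[1]]^2, co[[2]]^2, "+"), co[[3]]^2, "+"))
  shell <- binary_mask(rho >= 10 & rho <= 15,
                       plan$dose$spacing, plan$dose$origin)
  dvh <- compute_dvh(plan$dose, shell, bin_width = 0.01)
  for (r0 in c(11, 12.5, 14)) {
    dose_r0 <- 18 * (7.5 / r0)^2
    frac <- (r0^3 - 10^3) / (15^3 - 10^3)
    i <- which.min(abs(dvh$dose_gy - dose_r0))
    expect_equal(dvh$relative_volume[i], frac, tolerance = 0.02)
  }
})

test_that("d_at_volume recovers the midpoint of a linear dose ramp", {
  n <- 21
  ramp <- array(rep(seq(0, 20, length.out = n), each = 1), c(n, 1, 1))
  g <- dose_grid(array(rep(seq(0, 20, length.out = n), times = 1), c(n, 3, 3)),
                 spacing = 1)
  st <- binary_mask(array(TRUE, c(n, 3, 3)), spacing = 1)
  dvh <- compute_dvh(g, st, bin_width = 0.1)
  expect_equal(d_at_volume(dvh, 0.5), 10, tolerance = 0.6)
  expect_error(d_at_volume(dvh, 0), "in \\(0, 1\\]")
  expect_error(d_at_volume(dvh, 1.2), "in \\(0, 1\\]")
})

test_that("renormalizing to full target coverage gives V100 = 100%", {
  plan <- fix_small_plan()
  dvh0 <- compute_dvh(plan$dose, plan$ptv)
  scale <- 18 / d_at_volume(dvh0, 1)
  g <- dose_grid(plan$dose$values * scale, plan$dose$spacing, plan$dose$origin)
  dvh <- compute_dvh(g, plan$ptv, bin_width = 0.018)
  i100 <- which.min(abs(dvh$dose_gy - 18))
  expect_gte(dvh$relative_volume[i100], 1 - 1e-9)
})

test_that("GI and R50 reproduce the reference SRS ratios", {
  tb <- srs_table()
  tb50 <- tb[tb$dose_pct %in% c(50, 100), ]
  expect_equal(round(gradient_index(tb50), 3), 2.626)
  # 3 cm diameter spherical target
  expect_equal(r50(tb50, 4 / 3 * pi * 15^3), 3.164, tolerance = 1e-3)
  # R50 equals GI when the prescription isodose volume equals the PTV
  expect_equal(r50(tb50, tb50$volume_mm3[tb50$dose_pct == 100]),
               gradient_index(tb50))
  expect_error(gradient_index(tb[tb$dose_pct >= 90, ]), "missing")
  expect_error(r50(tb50, 0), "positive")
})

test_that("GI is invariant to sub-voxel translation of the field", {
  gi_at <- function(cc) {
    ax <- seq(-21, 21, by = 1)
    n <- length(ax)
    pts <- as.matrix(expand.grid(ax, ax, ax))
    rho <- sqrt(rowSums(sweep(pts, 2, cc)^2))
    dose <- 18 * pmin(1.2, (7.5 / pmax(rho, 1e-9))^2)
    g <- dose_grid(array(dose, c(n, n, n)), 1, rep(-21, 3))
    tb <- build_level_table(g, reference_dose = 18, step = 25,
                            range = c(50, 101))
    gradient_index(tb)
  }
  g0 <- gi_at(c(0, 0, 0))
  g1 <- gi_at(c(0.37, -0.21, 0.49))  # off-lattice target position
  expect_equal(g0, (50 / 100)^(-3 / 2), tolerance = 0.02)
  expect_equal(g1, g0, tolerance = 0.02)
})
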