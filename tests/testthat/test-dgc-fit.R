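test_that("the fitted cumulative curve matches closed-form radius differences", {
  fit <- fix_radial_fit()
  plan <- fix_radial_plan()
  tbl <- fit$table
  # cDGI at level f is (up to the small estimator curvature error) the
  # distance between the reference sphere and the f-isodose sphere
  for (pct in c(50, 70, 90)) {
    truth <- isodose_radius(plan, pct) - isodose_radius(plan, 100)
    expect_lt(abs(cdgi_at(tbl, pct) - truth), 0.02)
  }
  expect_identical(tbl$cdgi_mm[tbl$dose_pct == 100], 0)
  # differential values match analytic shell widths
  i99 <- which(tbl$dose_pct == 99)
  expect_equal(tbl$ddgi_mm[i99], 15 * (0.99^(-1 / 2) - 1), tolerance = 0.05)
})

test_that("dgc objects print, summarise and expose coefficients", {
  fit <- fix_radial_fit()
  expect_output(print(fit), "Dose gradient curve fit")
  expect_output(print(summary(fit)), "steepest gradient")
  cf <- coef(fit)
  expect_named(cf, c("gradient_index", "r50", "cdgi_50", "d100_gy",
                     "ptv_volume_mm3"))
  expect_equal(cf[["gradient_index"]], (1 / 2)^(-3 / 2), tolerance = 0.02)
  df <- as.data.frame(fit)
  expect_true(all(c("dose_pct", "surface_area_mm2", "volume_mm3", "ddgi_mm",
                    "cdgi_mm") %in% names(df)))
})

test_that("d100 referencing anchors the cumulative curve at full target coverage", {
  plan <- fix_radial_plan()
  fit <- dgc(plan$dose, prescription = 15, body = plan$body, ptv = plan$ptv,
             step = 1, reference = "d100")
  ref <- fit$config$reference_level
  expect_identical(fit$table$cdgi_mm[fit$table$dose_pct == ref], 0)
  # D100% of the voxelized target sits just below the surface dose
  expect_lte(ref, 100)
  expect_error(dgc(plan$dose, prescription = 15, reference = "d100"),
               "requires a target mask")
})

test_that("plots render for every layout", {
  fit <- fix_radial_fit()
  p <- tempfile(fileext = ".png")
  grDevices::png(p)
  expect_silent({
    plot(fit, type = "differential")
    plot(fit, type = "normalized")
    plot(fit, type = "cumulative")
    plot(fit, type = "combined")
    plot(fit$dvh)
  })
  grDevices::dev.off()
  expect_true(file.size(p) > 0)
  fit_nodvh <- dgc(fix_small_plan()$dose, prescription = 18, step = 2)
  expect_error(plot(fit_nodvh, type = "combined"), "requires a DVH")
})

test_that("gy-scale fitting agrees with percent-scale fitting", {
  plan <- fix_small_plan()
  fp <- dgc(plan$dose, prescription = 18, body = plan$body, step = 10)
  fg <- dgc(plan$dose, prescription = 18, body = plan$body, step = 1.8,
            dose_scale = "gy")
  # same physical levels: identical areas/volumes and dDGI
  expect_equal(fg$table$dose_gy, fp$table$dose_gy, tolerance = 1e-9)
  expect_equal(fg$table$ddgi_mm, fp$table$ddgi_mm, tolerance = 1e-9)
  expect_equal(fg$table$cdgi_mm, fp$table$cdgi_mm, tolerance = 1e-9)
})

test_that("coarse grids are resampled before extraction", {
  plan <- make_radial_dose(target_radius = 7.5, reference_dose = 18,
                           falloff_exponent = 2, core_max_pct = 120,
                           grid_spacing = 2, body_radius = 22)
  fit <- dgc(plan$dose, prescription = 18, step = 5, resample_to = 1)
  expect_equal(fit$config$spacing_mm, c(1, 1, 1))
  fit2 <- dgc(plan$dose, prescription = 18, step = 5, resample_to = NULL)
  expect_equal(fit2$config$spacing_mm, c(2, 2, 2))
  # resampling keeps the curve close to the fine-grid truth
  plan1 <- make_radial_dose(target_radius = 7.5, reference_dose = 18,
                            falloff_exponent = 2, core_max_pct = 120,
                            grid_spacing = 1, body_radius = 22)
  fit1 <- dgc(plan1$dose, prescription = 18, step = 5)
  common <- intersect(fit$table$dose_pct[!is.na(fit$table$cdgi_mm)],
                      fit1$table$dose_pct[!is.na(fit1$table$cdgi_mm)])
  expect_equal(cdgi_at(fit$table, common), cdgi_at(fit1$table, common),
               tolerance = 0.1)
})
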