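test_that("level table volumes match closed-form isodose radii on a radial plan", {
  plan <- fix_radial_plan()
  dom <- crop_body(plan$body, 3)
  tb <- build_level_table(plan$dose, domain = dom, reference_dose = 15,
                          step = 5, range = c(50, 120))
  expect_s3_class(tb, "isodose_levels")
  r_true <- isodose_radius(plan, tb$dose_pct)
  expect_equal(tb$volume_mm3, 4 / 3 * pi * r_true^3, tolerance = 0.02)
  expect_true(all(diff(tb$volume_mm3) < 0))  # strict superlevel nesting
  expect_true(all(tb$surface_area_mm2 > 0))
})

test_that("levels clipped by the cropped body truncate the analysed range", {
  plan <- fix_radial_plan()
  dom <- crop_body(plan$body, 3)
  tb <- build_level_table(plan$dose, domain = dom, reference_dose = 15, step = 1)
  # the lowest closed isodose must fit strictly inside the 37 mm cropped body
  expect_gt(isodose_radius(plan, attr(tb, "truncation_dose") - 1), 35)
  expect_true(all(tb$dose_pct >= attr(tb, "truncation_dose")))
  # every tabulated level must close strictly inside the domain
  expect_lt(max(isodose_radius(plan, tb$dose_pct)), 37)
})

test_that("differential DGC reproduces the printed SRS example at 2 decimals", {
  tb <- srs_table()
  hi <- as_dgc_table(tb[tb$dose_pct >= 90, ], step = 1)
  dd <- differential_dgc(hi)
  expect_equal(round(dd$ddgi_mm[dd$dose_pct == 100], 2), 0.13)
  expect_equal(round(dd$ddgi_mm[dd$dose_pct == 120], 2), 2.29)
  expect_true(is.na(dd$ddgi_mm[dd$dose_pct == 121]))  # top level has no dDGI

  lo <- as_dgc_table(tb[tb$dose_pct <= 30, ], step = 1)
  dl <- differential_dgc(lo)
  expect_equal(round(dl$ddgi_mm[dl$dose_pct == 24], 2), 0.99)
})

test_that("differential DGC validates spacing, nesting and plateaus", {
  tb <- srs_table()
  gappy <- as_dgc_table(tb[tb$dose_pct %in% c(24, 25, 30), ], step = 1)
  expect_error(differential_dgc(gappy), "uniformly spaced")

  df <- data.frame(dose_pct = c(10, 11, 12), dose_gy = c(1, 1.1, 1.2),
                   surface_area_mm2 = c(300, 200, 100),
                   volume_mm3 = c(1000, 1000, 900))
  expect_warning(dd <- differential_dgc(as_dgc_table(df, step = 1)), "plateau")
  expect_equal(dd$ddgi_mm[1], 0)

  bad <- data.frame(dose_pct = c(10, 11), dose_gy = c(1, 1.1),
                    surface_area_mm2 = c(300, 200),
                    volume_mm3 = c(900, 1000))
  expect_error(differential_dgc(as_dgc_table(bad, step = 1)), "nesting")
})

test_that("cumulative DGC sums the printed dDGI series and anchors at zero", {
  tb <- srs_table()
  sub <- tb[tb$dose_pct >= 90 & tb$dose_pct <= 100, ]
  dt <- as_dgc_table(data.frame(sub[c("dose_pct", "dose_gy", "surface_area_mm2",
                                      "volume_mm3")],
                                ddgi_mm = sub$ddgi_mm,
                                ddgi_norm_mm = sub$ddgi_mm), step = 1)
  cd <- cumulative_dgc(dt, reference = 100)
  expect_identical(cd$cdgi_mm[cd$dose_pct == 100], 0)
  expect_equal(cd$cdgi_mm[cd$dose_pct == 90], 1.13, tolerance = 1e-9)
  expect_equal(cd$cdgi_mm[cd$dose_pct == 95], 0.60, tolerance = 1e-9)
  # strictly increasing as the dose falls below the reference
  expect_true(all(diff(cd$cdgi_mm) < 0))
  # undefined above the reference
  expect_error(cdgi_at(cd, 101), "undefined above")
})

test_that("cumulative DGC requires the reference on the level grid", {
  df <- data.frame(dose_pct = 90:95, dose_gy = 0.15 * (90:95),
                   surface_area_mm2 = seq(320, 300, length.out = 6),
                   volume_mm3 = seq(2000, 1700, length.out = 6))
  dd <- differential_dgc(as_dgc_table(df, step = 1))
  expect_error(cumulative_dgc(dd, reference = 100), "does not coincide")
  cd <- cumulative_dgc(dd, reference = 95)
  expect_identical(cd$cdgi_mm[6], 0)
})

test_that("step normalization rescales and rejects a zero step", {
  df <- data.frame(dose_pct = seq(90, 98, by = 2), dose_gy = NA,
                   surface_area_mm2 = seq(320, 300, length.out = 5),
                   volume_mm3 = seq(2000, 1700, length.out = 5))
  df$dose_gy <- 0.15 * df$dose_pct
  dd <- differential_dgc(as_dgc_table(df, step = 2))
  expect_equal(dd$ddgi_norm_mm, dd$ddgi_mm / 2)
  dd1 <- normalize_ddgc(dd, step = 1)
  expect_equal(dd1$ddgi_norm_mm, dd$ddgi_mm)
  expect_error(normalize_ddgc(dd, step = 0), "non-zero")
})
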