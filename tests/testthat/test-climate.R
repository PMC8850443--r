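test_that("climate grid validates geometry and physical ranges", {
  expect_error(climate_grid(matrix(15, 2, 2), c(44.8, 45.3), c(1.75, 2.25)),
               "cell centers")
  expect_error(climate_grid(matrix(100, 2, 2), c(44.75, 45.25),
                            c(1.75, 2.25)), "outside")
  expect_error(climate_grid(matrix(-5, 1, 1), 0.25, 0.25,
                            variable = "annual_total_precip_mm"), "negative")
  expect_s3_class(toy_grid(c(10, 11, 12, 13)), "climate_grid")
})

test_that("climatology is the per-cell mean over the window", {
  lats <- c(44.75, 45.25); lons <- c(1.75, 2.25)
  series <- array(15, dim = c(2, 2, 10),
                  dimnames = list(NULL, NULL, 2001:2010))
  g <- build_climatology(series, lats, lons, 2001:2010)
  expect_true(all(g$values == 15))

  two <- array(rep(c(10, 20), each = 4), dim = c(2, 2, 2),
               dimnames = list(NULL, NULL, 2001:2002))
  expect_true(all(build_climatology(two, lats, lons, 2001:2002)$values == 15))

  old <- array(10, dim = c(2, 2, 2), dimnames = list(NULL, NULL, 1998:1999))
  expect_error(build_climatology(old, lats, lons, 2001:2010), "coverage")

  # commutes with spatial subsetting
  set.seed(1)
  big <- array(rnorm(4 * 6 * 3, 10), dim = c(4, 6, 3),
               dimnames = list(NULL, NULL, 2001:2003))
  lats4 <- seq(44.75, by = 0.5, length.out = 4)
  lons6 <- seq(1.75, by = 0.5, length.out = 6)
  whole <- build_climatology(big, lats4, lons6, 2001:2003)
  sub <- build_climatology(big[2:3, 3:4, , drop = FALSE],
                           lats4[2:3], lons6[3:4], 2001:2003)
  expect_equal(whole$values[2:3, 3:4], sub$values)
})

test_that("point extraction selects the containing cell, NE at corners", {
  g <- toy_grid(c(1, 2, 3, 4)) # rows = lat {44.75,45.25}, cols = lon {1.75,2.25}
  expect_equal(extract_point(g, 44.75, 1.75), 1) # cell center
  expect_equal(extract_point(g, 45.25, 2.25), 4)
  # two points in the same cell agree
  expect_equal(extract_point(g, 44.6, 1.6), extract_point(g, 44.9, 1.9))
  # boundary resolves north-east: 45.0/2.0 is the corner of all four cells
  expect_equal(extract_point(g, 45.0, 2.0), 4)
  # masked cell errors
  gm <- toy_grid(c(NA, 2, 3, 4))
  expect_error(extract_point(gm, 44.75, 1.75), "masked")
  expect_error(extract_point(g, 50, 2), "extent")
})

test_that("area-weighted mean is a weighted average with the stated identities", {
  g <- toy_grid(c(10, 20, 30, 40))
  w <- weight_grid(matrix(1, 2, 2), g$lats, g$lons)
  all_cells <- matrix(TRUE, 2, 2)
  expect_equal(area_weighted_mean(g, w, all_cells), 25) # uniform -> plain mean

  w2 <- weight_grid(matrix(c(1, 3, 0, 0), 2, 2), g$lats, g$lons)
  expect_equal(area_weighted_mean(g, w2, all_cells), 17.5)

  # single positive-weight cell -> that value; equals extract_point
  w1 <- weight_grid(matrix(c(0, 0, 0, 5), 2, 2), g$lats, g$lons)
  expect_equal(area_weighted_mean(g, w1, all_cells), 40)
  one <- matrix(c(FALSE, FALSE, FALSE, TRUE), 2, 2)
  expect_equal(area_weighted_mean(g, w, one), extract_point(g, 45.25, 2.25))

  # invariant under uniform weight scaling
  wk <- weight_grid(7 * w2$harvested_area, g$lats, g$lons)
  expect_equal(area_weighted_mean(g, wk, all_cells),
               area_weighted_mean(g, w2, all_cells))

  wz <- weight_grid(matrix(0, 2, 2), g$lats, g$lons)
  expect_error(area_weighted_mean(g, wz, all_cells), "zero total weight")
  expect_error(area_weighted_mean(g, w, matrix(FALSE, 2, 2)), "empty mask")
})

test_that("CO2 lookup interpolates linearly inside the span only", {
  tr <- scenario_trajectory("RCP8.5", c(2050, 2100), c(540, 936))
  expect_equal(co2_concentration(tr, 2050), 540)
  expect_equal(co2_concentration(tr, 2075), (540 + 936) / 2)
  expect_error(co2_concentration(tr, 1700), "outside")
  expect_error(scenario_trajectory("x", 2050, 400), "at least 2")
  expect_error(scenario_trajectory("x", c(2050, 2050), c(1, 2)), "increase")

  # monotone trajectory gives monotone outputs
  tb <- co2_trajectories()
  yrs <- 2005:2095
  expect_true(all(diff(co2_concentration(tb[["RCP8.5"]], yrs)) > 0))
})

test_that("relative precipitation change converts against the baseline level", {
  expect_equal(precip_change_from_relative(10, 800), 80)
  expect_equal(precip_change_from_relative(0, 1234), 0)
  expect_equal(precip_change_from_relative(-25, 400), -100)
  expect_error(precip_change_from_relative(10, -5), "non-negative")
})

test_that("CSV raster round-trips", {
  g <- toy_grid(c(10.5, 20.25, 30, 40))
  path <- withr::local_tempfile(fileext = ".csv")
  write_grid_csv(g, path)
  back <- read_grid_csv(path)
  expect_equal(back$values, g$values, ignore_attr = TRUE)
  expect_equal(back$lats, g$lats)
  expect_equal(back$lons, g$lons)
})
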