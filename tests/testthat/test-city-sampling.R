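# City sampling: retention rules, QA filtering, background correction,
# rural reference boxes and gridded annual fields.

test_that("monthly means follow the at-least-5-pixel retention rule", {
  reg <- unit_region()
  px <- rbind(pixels_at(2005, 1, 1:5),        # retained, mean 3
              pixels_at(2005, 2, c(2, 4, 6, 8)))  # present, not retained
  ser <- sample_region(px, reg)
  expect_equal(ser$data$mean, c(3, 5))
  expect_identical(ser$data$retained, c(TRUE, FALSE))
  expect_identical(ser$data$n_pixels, c(5L, 4L))
})

test_that("qa-failing pixels never enter any mean", {
  reg <- unit_region()
  px <- rbind(pixels_at(2005, 1, 1:5),
              pixels_at(2005, 1, rep(1000, 3), qa_pass = FALSE))
  ser <- sample_region(px, reg)
  expect_equal(ser$data$mean, 3)
  expect_identical(ser$data$n_pixels, 5L)
})

test_that("sampling is permutation-invariant and matches a brute-force oracle", {
  # irregular pentagon
  ring <- cbind(c(0, 0.35, 0.42, 0.2, -0.05), c(0, -0.04, 0.3, 0.45, 0.25))
  reg <- region_geometry("penta", ring)
  set.seed(7)
  n <- 800
  px <- data.frame(lon = runif(n, -0.15, 0.55), lat = runif(n, -0.15, 0.55),
                   time = as.Date("2005-06-15"), value = rnorm(n),
                   qa_pass = TRUE)
  ser <- sample_region(px, reg)
  inside <- oracle_pip(px$lon, px$lat, ring)
  expect_identical(ser$data$n_pixels, as.integer(sum(inside)))
  expect_equal(ser$data$mean, mean(px$value[inside]))
  perm <- px[sample(n), ]
  expect_equal(sample_region(perm, reg)$data, ser$data)
})

test_that("ocean background series mirrors city mechanics and checks latitude range", {
  ocean <- unit_region(id = "ocean", kind = "ocean_background")
  px <- do.call(rbind, lapply(1:12, function(m) pixels_at(2005, m, rep(2.5, 6))))
  ser <- background_series(px, ocean)
  expect_true(all(ser$data$mean == 2.5))
  city_far <- rect_region("far_city", 30, 30.3, 5, 5.3)
  expect_warning(background_series(px, ocean, paired_city = city_far),
                 "latitude range")
  expect_error(background_series(px, unit_region()), "ocean_background")
  expect_warning(
    empty <- background_series(px[0, ], ocean),
    "empty series")
  expect_identical(nrow(empty$data), 0L)
})

test_that("background subtraction recovers an additive offset and flags negatives", {
  reg <- unit_region(); ocean <- unit_region(id = "oc", kind = "ocean_background")
  sc_bg <- synthetic_scenario(baseline_column = 4, seasonal_amplitude = 0.2,
                              seasonal_phase = 3, seed = 21)
  bg <- background_series(generate_pixels(sc_bg, ocean), ocean)
  bg_fit <- fit_seasonal_trend(bg)
  # city = background + 1.5 everywhere
  city_px <- generate_pixels(sc_bg, reg)
  city_px$value <- city_px$value + 1.5
  city <- sample_region(city_px, reg, species = "HCHO")
  corr <- subtract_background(city, bg_fit)
  expect_equal(corr$data$mean, rep(1.5, nrow(corr$data)), tolerance = 1e-8)
  expect_length(corr$flags, 0)
  # city identical to background: residuals ~0, any negative is kept + flagged
  city0 <- sample_region(generate_pixels(sc_bg, reg), reg, species = "HCHO")
  corr0 <- subtract_background(city0, bg_fit)
  expect_equal(max(abs(corr0$data$mean)), 0, tolerance = 1e-8)
  city_neg_px <- generate_pixels(sc_bg, reg)
  city_neg_px$value <- city_neg_px$value - 1
  corr_neg <- subtract_background(sample_region(city_neg_px, reg, species = "HCHO"),
                                  bg_fit)
  expect_true("negative_residual" %in% corr_neg$flags)
  expect_true(all(corr_neg$data$mean < 0))  # values kept, not clipped
  # months outside the background fit support are an error
  late <- sample_region(pixels_at(2030, 1, 1:5), reg, species = "HCHO")
  expect_error(subtract_background(late, bg_fit), "outside")
})

test_that("rural reference boxes respect the 50-100 km annulus and box size", {
  reg <- unit_region()
  px <- generate_pixels(synthetic_scenario(baseline_column = 3, seed = 31), reg)
  ctr <- region_centroid(reg)
  rr <- suppressWarnings(  # box lies outside the simulated pixel field
    rural_reference(px, ctr, distance_km = 75, bearing_deg = 200))
  expect_s3_class(rr$region, "region_geometry")
  expect_equal(rr$region$kind, "rural_reference")
  side <- diff(range(rr$region$coords[, 1]))
  expect_equal(side, 0.2, tolerance = 1e-9)
  d <- geosphere::distGeo(ctr, region_centroid(rr$region)) / 1000
  expect_equal(d, 75, tolerance = 0.01)
  expect_error(rural_reference(px, ctr, distance_km = 30), "50-100 km")
  expect_error(rural_reference(px, ctr, distance_km = 120), "50-100 km")
})

test_that("gridded annual sampling supports mean and sum modes", {
  # two adjacent equal-area cells on the equator holding 2 and 4
  g <- annual_grid(lon = c(0.05, 0.15), lat = 0.05, years = 2005,
                   values = c(2, 4), cellsize = 0.1)
  reg <- rect_region("both", 0, 0.2, 0, 0.1)
  expect_equal(sample_gridded_annual_field(g, reg, "mean")$value, 3)
  expect_equal(sample_gridded_annual_field(g, reg, "sum")$value, 6)
  # uniform field returns the constant in mean mode over any overlap
  gu <- annual_grid(lon = seq(0.05, 0.45, 0.1), lat = seq(0.05, 0.45, 0.1),
                    years = 2005:2007, values = 7, cellsize = 0.1)
  part <- rect_region("part", 0.02, 0.31, 0.07, 0.22)
  expect_equal(sample_gridded_annual_field(gu, part, "mean")$value, rep(7, 3))
  far <- rect_region("far", 5, 5.1, 5, 5.1)
  expect_error(sample_gridded_annual_field(gu, far), "overlap")
})
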