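# 75th-percentile source partitioning and burned-fraction consistency.

test_that("the worked spike year partitions as expected", {
  # nine months at 1, three burning-season spikes at 9
  vals <- rep(1, 12); vals[c(12, 1, 2)] <- 9
  ser <- series_from_values(vals)
  p <- partition_series(ser, bb_months = c(12, 1, 2))
  # type-7 quantile of {1 x9, 9 x3} at 0.75: v(9) + 0.25*(v(10)-v(9)) = 3
  expect_equal(p$years$p75, 3)
  expect_equal(p$years$anth_annual_mean, 1)
  expect_equal(p$years$n_above, 3L)
  expect_true(p$years$overlap_check)
  expect_equal(nrow(p$bb), 3L)
  expect_equal(p$bb$excess, rep(8, 3))
})

test_that("reconstruction: excess + anthropogenic mean returns the original value", {
  set.seed(23)
  for (i in 1:20) {
    nyr <- sample(3:14, 1)
    vals <- exp(rnorm(nyr * 12))
    ser <- series_from_values(vals)
    bbm <- sort(sample(1:12, sample(2:5, 1)))
    p <- partition_series(ser, bb_months = bbm)
    if (!nrow(p$bb)) next
    anth <- setNames(p$years$anth_annual_mean, p$years$year)
    # exact up to one floating-point rounding of the subtraction
    resid <- abs(p$bb$excess + unname(anth[as.character(p$bb$year)]) - p$bb$value)
    expect_true(all(resid <= 4 * .Machine$double.eps * pmax(abs(p$bb$value), 1)))
    # all excesses come from burning-season months strictly above p75
    expect_true(all(p$bb$month %in% bbm))
    p75 <- setNames(p$years$p75, p$years$year)
    expect_true(all(p$bb$value > unname(p75[as.character(p$bb$year)])))
  }
})

test_that("with 12 distinct months exactly 3 lie strictly above p75", {
  set.seed(9)
  for (i in 1:10) {
    vals <- sample(seq(1, 100, length.out = 60), 12)
    p <- partition_series(series_from_values(vals), bb_months = 1:12)
    expect_identical(p$years$n_above, 3L)
  }
})

test_that("partition is invariant to month ordering and respects the year gate", {
  vals <- exp(rnorm(24))
  ser <- series_from_values(vals)
  shuf <- ser$data[sample(24), ]
  ser2 <- monthly_series("test_city", "NO2", shuf)
  p1 <- partition_series(ser, 1:3); p2 <- partition_series(ser2, 1:3)
  expect_equal(p1$years, p2$years)
  expect_equal(p1$bb[order(p1$bb$year, p1$bb$month), ],
               p2$bb[order(p2$bb$year, p2$bb$month), ])
  # a year with fewer than 8 retained months is not partitioned
  npix <- rep(6L, 24); npix[1:6] <- 2L
  p3 <- partition_series(series_from_values(vals, n_pixels = npix), 1:3)
  expect_identical(p3$years$year, 2006L)
})

test_that("flat years keep a defined p75, empty burning set, and a warning", {
  ser <- series_from_values(rep(3, 12))
  expect_warning(p <- partition_series(ser, bb_months = 1:4), "tied")
  expect_equal(p$years$p75, 3)
  expect_equal(p$years$anth_annual_mean, 3)
  expect_identical(nrow(p$bb), 0L)
})

test_that("spikes outside the burning season fail the overlap check", {
  vals <- rep(1, 12); vals[c(6, 7, 8)] <- 9  # spikes in June-August
  p <- partition_series(series_from_values(vals), bb_months = c(12, 1, 2))
  expect_false(p$years$overlap_check)
  expect_identical(nrow(p$bb), 0L)  # excluded from the biomass-burning series
  expect_false(bb_influenced(p))
})

test_that("partition trends recover generator truth on noise-free series", {
  reg <- unit_region()
  # anthropogenic growth only: anth trend ~ rel_trend, bb trend ~ 0
  sc <- synthetic_scenario(baseline_column = 10, rel_trend = 0.03,
                           bb_months = 1:3, bb_excess = 0.8,
                           bb_trend = 0, seed = 41)
  ser <- sample_region(generate_pixels(sc, reg), reg)
  p <- partition_series(ser, 1:3)
  tr <- partition_trends(p)
  expect_equal(tr$anth_rel, 3, tolerance = 0.15)
  expect_equal(tr$bb$slope, 0, tolerance = 0.05)
  # burning growth only: bb trend positive, anth flat
  sc2 <- synthetic_scenario(baseline_column = 10, rel_trend = 0,
                            bb_months = 1:3, bb_excess = 0.8,
                            bb_trend = 0.05, seed = 42)
  tr2 <- partition_trends(
    partition_series(sample_region(generate_pixels(sc2, reg), reg), 1:3))
  expect_gt(tr2$bb$slope, 0)
  expect_equal(tr2$anth$slope, 0, tolerance = 1e-6)
  # too few years is an explicit refusal
  short <- series_from_values(exp(rnorm(24)))
  expect_error(partition_trends(partition_series(short, 1:3)), "at least")
})

test_that("burned-fraction consistency labels follow CI-aware sign logic", {
  up <- theil_sen(2005:2010, 1:6)            # CI excludes 0, positive
  down <- theil_sen(2005:2010, 6:1)          # CI excludes 0, negative
  set.seed(3)
  flat <- theil_sen(2005:2010, rnorm(6))     # CI spans 0
  expect_true(flat$slope_ci[1] < 0 && flat$slope_ci[2] > 0)
  expect_identical(consistency_with_burned_fraction(up, up), "consistent")
  expect_identical(consistency_with_burned_fraction(up, down), "opposite")
  expect_identical(consistency_with_burned_fraction(flat, up), "indeterminate")
  expect_identical(consistency_with_burned_fraction(up, flat), "indeterminate")
})

test_that("burning-season calendars match the four regional seasons", {
  expect_identical(burning_season("northern_africa"), c(12L, 1L, 2L, 3L))
  expect_identical(burning_season("southern_africa"), 7:11)
  expect_identical(burning_season("south_asia"), 1:4)
  expect_identical(burning_season("southeast_asia_south"), 8:10)
})
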