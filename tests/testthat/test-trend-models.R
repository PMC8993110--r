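# Seasonal+linear fitting, Theil-Sen, relative trends, regime diagnostics.

test_that("noise-free generator truth is recovered to high precision", {
  reg <- unit_region()
  for (par in list(c(rel = 0.05, amp = 0.3, ph = 2),
                   c(rel = -0.02, amp = 0.15, ph = 7.5),
                   c(rel = 0.10, amp = 0, ph = 0))) {
    sc <- synthetic_scenario(baseline_column = 8, rel_trend = par[["rel"]],
                             seasonal_amplitude = par[["amp"]],
                             seasonal_phase = par[["ph"]], seed = 13)
    f <- fit_seasonal_trend(sample_region(generate_pixels(sc, reg), reg))
    expect_equal(f$rel_trend, 100 * par[["rel"]], tolerance = 1e-6)
    expect_equal(f$amp / f$mu0, par[["amp"]], tolerance = 1e-6)
    if (par[["amp"]] > 0)
      expect_equal(f$phase, par[["ph"]], tolerance = 1e-6)
  }
})

test_that("adding a pure annual sinusoid leaves the trend untouched", {
  vals <- truth_curve(168, baseline = 5, rel_trend = 0.04)
  f0 <- fit_seasonal_trend(series_from_values(vals))
  withs <- vals + 2.3 * sin(2 * pi * (seq_len(168) - 1) / 12 + 1.1)
  f1 <- fit_seasonal_trend(series_from_values(withs))
  expect_equal(f1$beta, f0$beta, tolerance = 1e-8)
  expect_equal(f0$beta, 0.2, tolerance = 1e-10)
})

test_that("constant series has zero, non-significant trend", {
  f <- fit_seasonal_trend(series_from_values(rep(4.2, 168)))
  expect_equal(f$beta, 0, tolerance = 1e-12)
  expect_false(f$significant)
})

test_that("the coverage gate refuses sparse records", {
  # 40 retained months scattered over a 168-month record: below the OMI gate
  vals <- truth_curve(168, 5, 0.03)
  npix <- rep(2L, 168); npix[seq(1, 168, length.out = 40)] <- 6L
  ser <- series_from_values(vals, n_pixels = npix)
  f <- fit_seasonal_trend(ser, min_months = 50)
  expect_true(f$insufficient_coverage)
  expect_identical(f$n_months_used, 40L)
  expect_true(is.na(f$rel_trend))
  # the IASI gate (40) also refuses exactly-40-month coverage
  expect_true(fit_seasonal_trend(ser, min_months = 40)$insufficient_coverage)
  # 60 retained months pass
  npix2 <- rep(2L, 168); npix2[seq(1, 168, length.out = 60)] <- 6L
  f2 <- fit_seasonal_trend(series_from_values(vals, n_pixels = npix2))
  expect_false(f2$insufficient_coverage)
  expect_equal(f2$coverage_fraction, 60 / 168)
})

test_that("confidence intervals from both methods bracket a noisy trend", {
  set.seed(5)
  vals <- truth_curve(168, 10, 0.05, amp_frac = 0.2) + rnorm(168, 0, 0.5)
  ser <- series_from_values(vals)
  f_cov <- fit_seasonal_trend(ser, ci_method = "covariance")
  set.seed(6)
  f_boot <- fit_seasonal_trend(ser, ci_method = "bootstrap", boot_n = 200)
  for (f in list(f_cov, f_boot)) {
    expect_lt(f$beta_ci[1], 0.5)
    expect_gt(f$beta_ci[2], 0.5)
    expect_true(f$significant)
  }
})

test_that("theil_sen matches hand-enumerated and oracle slopes", {
  expect_equal(theil_sen(2005:2007, 1:3)$slope, 1)
  # pairwise slopes {1, 5, 9} -> median 5
  expect_equal(theil_sen(c(0, 1, 2), c(0, 1, 10))$slope, 5)
  set.seed(8)
  for (i in 1:25) {
    n <- sample(3:50, 1)
    x <- sample(1980:2060, n)
    y <- rnorm(n, sd = 10)
    fit <- theil_sen(x, y)
    expect_identical(fit$slope, oracle_theil_sen_slope(x, y))
    expect_identical(fit$n_points, n)
    # permutation invariance
    p <- sample(n)
    expect_identical(theil_sen(x[p], y[p])$slope, fit$slope)
  }
  expect_error(theil_sen(c(2005, 2005, 2006), 1:3), "duplicate")
  expect_error(theil_sen(2005:2006, 1:2), "at least 3")
})

test_that("relative trends scale against the record-start baseline", {
  expect_equal(relative_trend(0.5, 10), 5)
  expect_equal(relative_trend(0, 10), 0)
  expect_equal(relative_trend(-0.2, 10), -2)
  ts <- theil_sen(c(0, 1, 2), c(10, 10.5, 11))
  expect_equal(relative_trend(ts, 10), 5)
  expect_error(relative_trend(0.5, 0), "positive")
  expect_error(relative_trend(0.5, -3), "positive")
})

test_that("ozone regime diagnostic finds (or declines to find) the crossing", {
  mk_ratio_series <- function(ratios, no2_level = 2) {
    no2_vals <- rep(no2_level, 12 * length(ratios))
    hcho_vals <- rep(ratios, each = 12) * no2_level
    list(hcho = series_from_values(hcho_vals, species = "HCHO"),
         no2 = series_from_values(no2_vals, species = "NO2"))
  }
  # constant high ratio: NOx-sensitive throughout, no crossing
  s <- mk_ratio_series(rep(23, 4))
  rg <- ozone_regime(s$hcho, s$no2)
  expect_equal(rg$annual_ratio$ratio, rep(23, 4))
  expect_true(is.na(rg$crossing_year))
  # declining 4, 3, 2: crossing in the third year
  s <- mk_ratio_series(c(4, 3, 2))
  rg <- ozone_regime(s$hcho, s$no2)
  expect_identical(rg$crossing_year, 2007L)
  expect_false(rg$degenerate)
  # extrapolated crossing beyond the record
  s <- mk_ratio_series(c(8, 7.5, 7, 6.5))
  rg <- ozone_regime(s$hcho, s$no2)
  expect_identical(rg$crossing_year, 2017L)  # 2 = 8 - 0.5*(y-2005)
  # flat exactly at the threshold: degenerate boundary, first year
  s <- mk_ratio_series(rep(2, 3))
  rg <- ozone_regime(s$hcho, s$no2)
  expect_identical(rg$crossing_year, 2005L)
  expect_true(rg$degenerate)
  # a non-positive NO2 year is omitted with a warning
  s <- mk_ratio_series(c(4, 3, 2, 1.5))
  s$no2$data$mean[s$no2$data$year == 2006] <- -1
  expect_warning(rg <- ozone_regime(s$hcho, s$no2), "omitted")
  expect_false(2006 %in% rg$annual_ratio$year)
})

test_that("subsampling retained months rarely moves the trend beyond its CI half-width", {
  set.seed(77)
  ok <- 0L; reps <- 40L
  for (i in seq_len(reps)) {
    vals <- truth_curve(168, 10, runif(1, -0.05, 0.05), amp_frac = 0.2) +
      rnorm(168, 0, 1)
    ser <- series_from_values(vals)
    f <- fit_seasonal_trend(ser)
    drop <- sample(168, 34)  # remove 20% of months
    npix <- rep(6L, 168); npix[drop] <- 2L
    f2 <- fit_seasonal_trend(series_from_values(vals, n_pixels = npix))
    half <- diff(f$rel_ci) / 2
    if (abs(f2$rel_trend - f$rel_trend) < half) ok <- ok + 1L
  }
  expect_gte(ok / reps, 0.9)
})
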