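# Population exposure, anchor-scaled PM2.5, attributable mortality,
# and the factor decomposition.

flat_fit <- function(level = 2, years = c(2005L, 2018L)) {
  n <- (years[2] - years[1] + 1L) * 12L
  fit_seasonal_trend(series_from_values(rep(level, n), start_year = years[1]))
}

test_that("population exposure is the bilinear product N x annual-mean C", {
  f <- flat_fit(2)
  expect_equal(population_exposure(1e6, f, 2010), 2e6)
  expect_equal(population_exposure(0, f, 2010), 0)
  expect_equal(population_exposure(2e6, f, 2010),
               2 * population_exposure(1e6, f, 2010))
  expect_error(population_exposure(1e6, f, 2030), "outside")
})

test_that("exposure trends follow the linear start-baseline convention", {
  expect_equal(exposure_trend(100, 126, 13), 2)
  expect_equal(exposure_trend(50, 50, 13), 0)
  expect_error(exposure_trend(0, 10, 13), "E_start")
  # first-order additive composition of population and concentration trends
  cmp <- compose_trends(1.3, 0.5)
  expect_equal(cmp$additive, 1.8)
  expect_equal(cmp$cross_term, 0.0065)
})

test_that("PM2.5 anchoring scales the fitted AOD curve exactly", {
  f <- flat_fit(0.5)
  pm <- pm25_timeseries(40, f, c(2005, 2012, 2018))
  expect_equal(pm$pm25, rep(40, 3))  # flat AOD -> constant at the anchor
  # a doubling AOD record doubles PM2.5 end over start
  n <- 14 * 12
  vals <- truth_curve(n, 0.4, 1 / 13)  # doubles over 2005 -> 2018
  fa <- fit_seasonal_trend(series_from_values(vals))
  pm2 <- pm25_timeseries(40, fa, c(2005, 2018))
  r <- (1 + (13 + 5.5 / 12) / 13) / (1 + (5.5 / 12) / 13)  # annual-mean ratio
  expect_equal(pm2$pm25[2] / pm2$pm25[1], r, tolerance = 1e-9)
  # a 10% smaller anchor shrinks every concentration by exactly 10%
  pm3 <- pm25_timeseries(36, fa, c(2005, 2018))
  expect_equal(pm3$pm25, 0.9 * pm2$pm25, tolerance = 1e-12)
  expect_error(pm25_timeseries(40, fa, 2005:2018, anchor_year = 2030),
               "outside")
})

test_that("attributable fraction has its closed-form anchors and is monotone", {
  crf <- default_crf()
  af <- attributable_fraction(crf$counterfactual_c0, crf)
  expect_equal(af$af_central, 0)
  expect_equal(af$af_low, 0)
  # RR = 2 gives AF = 0.5 under any CRF; build one that hits RR = 2 at c = 25
  crf2 <- crf_spec(c(0, 100), rep(log(2) / 20, 2), rep(0.001, 2),
                   rep(0.1, 2), counterfactual_c0 = 5)
  expect_equal(attributable_fraction(25, crf2)$af_central, 0.5)
  scan <- attributable_fraction(seq(0, 150, by = 0.5), crf)
  for (col in c("af_low", "af_central", "af_high")) {
    expect_true(all(diff(scan[[col]]) >= -1e-12))
    expect_true(all(scan[[col]] >= 0 & scan[[col]] < 1))
  }
  expect_true(all(scan$af_low <= scan$af_central),)
  expect_true(all(scan$af_central <= scan$af_high))
})

test_that("premature deaths multiply population, age share, rate and AF", {
  est <- premature_deaths(1e6, 0.7, 0.01, 0.25)
  expect_equal(est$deaths, 1750)
  expect_equal(premature_deaths(1e6, 0.7, 0.01, 0)$deaths, 0)
  # two equal strata at half the population match the single stratum
  est2 <- premature_deaths(c(5e5, 5e5), c(0.7, 0.7), c(0.01, 0.01), 0.25)
  expect_equal(est2$deaths, est$deaths)
  # low/central/high ordering from a CRF-derived AF row
  af <- attributable_fraction(80, default_crf())
  est3 <- premature_deaths(1e6, 0.7, 0.01, af)
  expect_lte(est3$deaths_low, est3$deaths)
  expect_lte(est3$deaths, est3$deaths_high)
})

test_that("mortality change reproduces the worked arithmetic", {
  up <- mortality_change(290000, 470000, n_years = 14)
  expect_equal(up$change, 180000)
  expect_equal(round(up$relative_pct), 62)
  expect_equal(round(up$per_year, -3), 13000)
  down <- mortality_change(180000, 170000)
  expect_equal(round(down$relative_pct), -6)
  expect_equal(mortality_change(5, 5)$relative_pct, 0)
  expect_error(mortality_change(0, 10), "start_deaths")
})

test_that("factor log-ratios sum exactly to the total log mortality ratio", {
  crf <- default_crf()
  base <- list(pop = 2e6, frac_over14 = 0.65, y0 = 0.009, pm25 = 48)
  # all factors unchanged -> all zero
  d0 <- decompose_factors(base, base, crf)
  expect_equal(unname(d0$log_ratio), c(0, 0, 0))
  # population doubling alone -> population log-ratio ln(1/2), others 0
  dbl <- base; dbl$pop <- 2 * base$pop
  d1 <- decompose_factors(base, dbl, crf)
  expect_equal(unname(d1$log_ratio["population"]), log(1 / 2), tolerance = 1e-12)
  expect_equal(unname(d1$log_ratio["pm25"]), 0)
  expect_equal(unname(d1$log_ratio["baseline_mortality"]), 0)
  # identity on random single-stratum inputs
  set.seed(31)
  for (i in 1:25) {
    a <- list(pop = runif(1, 1e5, 1e7), frac_over14 = runif(1, 0.4, 0.9),
              y0 = runif(1, 0.003, 0.02), pm25 = runif(1, 10, 120))
    b <- list(pop = a$pop * runif(1, 0.5, 3), frac_over14 = runif(1, 0.4, 0.9),
              y0 = a$y0 * runif(1, 0.5, 2), pm25 = runif(1, 10, 120))
    d <- decompose_factors(a, b, crf)
    expect_equal(sum(d$log_ratio), d$total_log_ratio, tolerance = 1e-12)
  }
})

test_that("end-to-end synthetic city matches a brute-force truth recomputation", {
  # known truth: concentration growth r, population growth g, fixed y0,
  # log-linear CRF with constant slope
  reg <- unit_region()
  r <- 0.04; g <- 0.03; y0 <- 0.008; frac <- 0.7; anchor <- 50; beta <- 0.005
  sc <- synthetic_scenario(baseline_column = 0.5, rel_trend = r,
                           seasonal_amplitude = 0.2, seasonal_phase = 3,
                           noise_sd = 0, gap_prob = 0, seed = 55)
  fit <- fit_seasonal_trend(sample_region(generate_pixels(sc, reg), reg,
                                          species = "AOD"))
  crf <- crf_spec(c(0, 200), rep(beta, 2), rep(beta / 2, 2), rep(beta * 2, 2),
                  counterfactual_c0 = 5)
  pm <- pm25_timeseries(anchor, fit, c(2005, 2018), anchor_year = 2012)
  demo <- generate_demographics(demographic_scenario(1e6, g, frac, y0), 2005:2018)
  ests <- lapply(c(2005, 2018), function(y) {
    premature_deaths(demo$population[demo$year == y], frac, y0,
                     attributable_fraction(pm$pm25[pm$year == y], crf))
  })
  got <- mortality_change(ests[[1]], ests[[2]])$relative_pct
  # brute force from the closed-form truth (annual mean of the truth curve)
  cbar <- function(y) 0.5 * (1 + r * ((y - 2005) + 5.5 / 12))
  pm_truth <- function(y) anchor * cbar(y) / cbar(2012)
  af_truth <- function(c) 1 - exp(-beta * (c - 5))
  deaths_truth <- function(y) 1e6 * (1 + g)^(y - 2005) * frac * y0 *
    af_truth(pm_truth(y))
  want <- 100 * (deaths_truth(2018) - deaths_truth(2005)) / deaths_truth(2005)
  expect_equal(got, want, tolerance = 1e-9)
})
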