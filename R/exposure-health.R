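# Population exposure and health burden. Exposure is the standard
# population-exposure product E = N * C, with C the annual mean of the fitted
# seasonal-trend curve (AOD as PM2.5 proxy; tropospheric NO2 column as NO2
# proxy). Absolute PM2.5 is anchored to a modelled concentration at the record
# midpoint and scaled by the fitted AOD curve. Premature mortality uses an
# attributable-fraction model AF = 1 - 1/RR(c) with a pluggable
# concentration-response table, age-collapsed to the over-14 population.

#' Population pseudo-exposure E = N * C
#'
#' @param N Total city population in `year`.
#' @param fit A `seasonal_trend_fit` for the pollutant proxy.
#' @param year Calendar year; must lie within the fitted record.
#' @return Exposure in persons x concentration-proxy units.
#' @export
population_exposure <- function(N, fit, year) {
  stopifnot(N >= 0)
  if (year < fit$record_start[1] || year > fit$record_end[1])
    stop("year ", year, " outside fitted record ",
         fit$record_start[1], "-", fit$record_end[1])
  N * annual_fit_mean(fit, year)
}

#' Relative exposure trend between record start and end
#'
#' Linear convention: percent of the start value per year over the interval.
#'
#' @param E_start,E_end Exposure at the record start and end (start > 0).
#' @param n_years Interval length in years (e.g. 13 for 2005 to 2018).
#' @return Percent per year.
#' @export
exposure_trend <- function(E_start, E_end, n_years) {
  stopifnot(E_start > 0, n_years > 0)
  100 * ((E_end - E_start) / E_start) / n_years
}

#' Compose component trends into an exposure trend
#'
#' To first order the exposure trend is the sum of the population and
#' concentration trends; the multiplicative cross-term is reported
#' separately.
#'
#' @param pop_pct Population trend, percent per year.
#' @param conc_pct Concentration trend, percent per year.
#' @return List with `additive` (the first-order sum), `cross_term`, and
#'   `with_cross`.
#' @export
compose_trends <- function(pop_pct, conc_pct) {
  list(additive = pop_pct + conc_pct,
       cross_term = pop_pct * conc_pct / 100,
       with_cross = pop_pct + conc_pct + pop_pct * conc_pct / 100)
}

#' Anchor-scaled PM2.5 time series from an AOD fit
#'
#' `PM2.5(y) = anchor_pm25 * C(y) / C(anchor_year)` where `C` is the annual
#' mean of the fitted AOD curve; the anchor is a modelled annual-mean PM2.5
#' at a single year near the record midpoint.
#'
#' @param anchor_pm25 Annual-mean PM2.5 (ug m^-3) at `anchor_year` (> 0).
#' @param aod_fit A `seasonal_trend_fit` of the AOD series.
#' @param years Calendar years to evaluate.
#' @param anchor_year Anchor year (default 2012, the 2005-2018 midpoint);
#'   must lie within the fitted record.
#' @return Data frame with columns `year`, `pm25`.
#' @export
pm25_timeseries <- function(anchor_pm25, aod_fit, years, anchor_year = 2012L) {
  stopifnot(anchor_pm25 > 0)
  if (anchor_year < aod_fit$record_start[1] || anchor_year > aod_fit$record_end[1])
    stop("anchor_year ", anchor_year, " outside fitted record")
  c_anchor <- annual_fit_mean(aod_fit, anchor_year)
  if (!is.finite(c_anchor) || c_anchor <= 0)
    stop("fitted AOD annual mean at anchor year is non-positive")
  data.frame(year = as.integer(years),
             pm25 = anchor_pm25 * annual_fit_mean(aod_fit, years) / c_anchor)
}

#' Concentration-response function specification
#'
#' Log-linear relative risk `RR(c) = exp(beta(c) * (c - c0))` for
#' `c > c0` and 1 otherwise, with the slope `beta` interpolated from a
#' concentration-indexed table. Central, low and high slope rows drive the
#' mortality confidence interval. The bundled default table
#' (`default_crf()`) is synthetic: the meta-analytic coefficients behind the
#' published health risk model are not reproduced here, so absolute death
#' counts from the default are illustrative only.
#'
#' @param conc Concentration grid (ug m^-3, increasing).
#' @param beta_central,beta_low,beta_high Slopes (per ug m^-3) at `conc`.
#' @param counterfactual_c0 Concentration below which RR = 1 (default 5).
#' @param age_floor Minimum age of the exposed population (default 14).
#' @return An object of class `crf_spec`.
#' @export
crf_spec <- function(conc, beta_central, beta_low, beta_high,
                     counterfactual_c0 = 5, age_floor = 14L) {
  stopifnot(length(conc) == length(beta_central),
            length(conc) == length(beta_low),
            length(conc) == length(beta_high),
            !is.unsorted(conc), counterfactual_c0 >= 0,
            all(beta_low <= beta_central), all(beta_central <= beta_high))
  structure(list(conc = conc, beta_central = beta_central,
                 beta_low = beta_low, beta_high = beta_high,
                 counterfactual_c0 = counterfactual_c0,
                 age_floor = as.integer(age_floor)),
            class = "crf_spec")
}

#' Bundled synthetic concentration-response table
#'
#' Reads `inst/extdata/crf_synthetic.csv`: an attenuating log-linear slope
#' (larger per-unit risk at low concentrations, flattening above
#' 50 ug m^-3, where published risk models are most uncertain). Synthetic —
#' not the coefficients of any published meta-analysis.
#'
#' @return A `crf_spec`.
#' @export
default_crf <- function() {
  path <- system.file("extdata", "crf_synthetic.csv", package = "tropicair")
  read_crf_csv(path)
}

#' Read a concentration-response table from CSV
#'
#' Columns: conc, beta_central, beta_low, beta_high; the counterfactual may
#' be supplied as a `c0` column (constant).
#'
#' @param path CSV path.
#' @return A `crf_spec`.
#' @export
read_crf_csv <- function(path) {
  df <- read.csv(path)
  crf_spec(df$conc, df$beta_central, df$beta_low, df$beta_high,
           counterfactual_c0 = if ("c0" %in% names(df)) df$c0[1] else 5)
}

crf_beta <- function(crf, c, which = "central") {
  tab <- switch(which, central = crf$beta_central, low = crf$beta_low,
                high = crf$beta_high)
  approx(crf$conc, tab, xout = c, rule = 2)$y
}

#' Relative risk at a concentration
#'
#' @param c Annual-mean PM2.5 (ug m^-3), vectorised.
#' @param crf A `crf_spec`.
#' @param which `"central"`, `"low"` or `"high"` slope row.
#' @return RR values (>= 1).
#' @export
relative_risk <- function(c, crf, which = "central") {
  stopifnot(all(c >= 0))
  excess <- pmax(c - crf$counterfactual_c0, 0)
  exp(crf_beta(crf, c, which) * excess)
}

#' Attributable fraction AF = 1 - 1/RR(c)
#'
#' @param c Annual-mean PM2.5 (ug m^-3), vectorised.
#' @param crf A `crf_spec`.
#' @return Data frame with columns `c`, `af_low`, `af_central`, `af_high`.
#' @export
attributable_fraction <- function(c, crf) {
  data.frame(c = c,
             af_low = 1 - 1 / relative_risk(c, crf, "low"),
             af_central = 1 - 1 / relative_risk(c, crf, "central"),
             af_high = 1 - 1 / relative_risk(c, crf, "high"))
}

#' Premature deaths attributable to PM2.5 exposure
#'
#' `deaths = population * frac_over14 * y0 * AF`, summed over age strata when
#' the inputs are vectors.
#'
#' @param pop Population (per stratum when vectorised).
#' @param frac_over14 Fraction of population in the exposed (over-14) stratum.
#' @param y0 Baseline all-cause mortality rate (deaths per person per year).
#' @param af Attributable fraction: a single number, or a length-3 vector /
#'   one-row data frame with low, central, high values.
#' @param region_id,year Labels stored on the estimate.
#' @return An object of class `mortality_estimate` with `deaths` (central),
#'   `deaths_low`, `deaths_high`, `total_deaths_over14`.
#' @export
premature_deaths <- function(pop, frac_over14, y0, af,
                             region_id = NA_character_, year = NA_integer_) {
  stopifnot(all(pop >= 0), all(frac_over14 >= 0), all(frac_over14 <= 1),
            all(y0 >= 0))
  if (is.data.frame(af)) af <- c(af$af_low[1], af$af_central[1], af$af_high[1])
  if (length(af) == 1) af <- rep(af, 3)
  stopifnot(length(af) == 3, all(af >= 0), all(af < 1))
  total <- sum(pop * frac_over14 * y0)
  structure(list(region_id = region_id, year = year,
                 deaths = total * af[2], deaths_low = total * af[1],
                 deaths_high = total * af[3],
                 attributable_fraction = af[2],
                 total_deaths_over14 = total),
            class = "mortality_estimate")
}

#' @export
print.mortality_estimate <- function(x, ...) {
  cat(sprintf("<mortality_estimate> %s %s: %.0f deaths (95%% CI %.0f-%.0f), AF %.3f\n",
              x$region_id, x$year, x$deaths, x$deaths_low, x$deaths_high,
              x$attributable_fraction))
  invisible(x)
}

#' Change in premature mortality between two years
#'
#' @param start_deaths,end_deaths Deaths in the start and end year (numbers
#'   or `mortality_estimate`s); start must be > 0.
#' @param n_years Length of the observing period used for the per-year
#'   average (default 14 years for the 2005-2018 record).
#' @return List with `change` (end - start), `relative_pct`
#'   (100 * change / start), `per_year` (change / n_years).
#' @export
mortality_change <- function(start_deaths, end_deaths, n_years = 14) {
  if (inherits(start_deaths, "mortality_estimate")) start_deaths <- start_deaths$deaths
  if (inherits(end_deaths, "mortality_estimate")) end_deaths <- end_deaths$deaths
  stopifnot(start_deaths > 0, n_years > 0)
  change <- end_deaths - start_deaths
  list(change = change,
       relative_pct = 100 * change / start_deaths,
       per_year = change / n_years)
}

#' Log-ratio decomposition of mortality change into driving factors
#'
#' For each factor (PM2.5 via the attributable fraction, population including
#' the over-14 share, baseline mortality rate) the log-ratio is
#' `ln(M_k / M_end)` with `M_k` the deaths obtained holding factor k at its
#' start-year value and everything else at end-year values. For the
#' multiplicative single-stratum model the factor log-ratios sum exactly to
#' `ln(M_start / M_end)`.
#'
#' @param inputs_start,inputs_end Lists with elements `pop`, `frac_over14`,
#'   `y0`, `pm25` for the start (2005) and end (2018) year.
#' @param crf A `crf_spec`.
#' @return An object of class `decomposition_result`: `log_ratio` (named
#'   vector over pm25, population, baseline_mortality), `total_log_ratio`
#'   (= ln(M_start/M_end)), `deaths_start`, `deaths_end`.
#' @export
decompose_factors <- function(inputs_start, inputs_end, crf) {
  need <- c("pop", "frac_over14", "y0", "pm25")
  stopifnot(all(need %in% names(inputs_start)), all(need %in% names(inputs_end)))
  deaths_of <- function(pop, frac, y0, pm25) {
    af <- 1 - 1 / relative_risk(pm25, crf, "central")
    sum(pop * frac * y0 * af)
  }
  m_start <- deaths_of(inputs_start$pop, inputs_start$frac_over14,
                       inputs_start$y0, inputs_start$pm25)
  m_end <- deaths_of(inputs_end$pop, inputs_end$frac_over14,
                     inputs_end$y0, inputs_end$pm25)
  if (m_start <= 0 || m_end <= 0)
    stop("decomposition undefined: zero attributable deaths in one of the years")
  lr <- c(
    pm25 = log(deaths_of(inputs_end$pop, inputs_end$frac_over14,
                         inputs_end$y0, inputs_start$pm25) / m_end),
    population = log(deaths_of(inputs_start$pop, inputs_start$frac_over14,
                               inputs_end$y0, inputs_end$pm25) / m_end),
    baseline_mortality = log(deaths_of(inputs_end$pop, inputs_end$frac_over14,
                                       inputs_start$y0, inputs_end$pm25) / m_end))
  structure(list(log_ratio = lr, total_log_ratio = log(m_start / m_end),
                 deaths_start = m_start, deaths_end = m_end,
                 reference_years = c(start = NA_integer_, end = NA_integer_)),
            class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat("<decomposition_result> log-ratios (factor at start-year value / all end-year):\n")
  for (nm in names(x$log_ratio))
    cat(sprintf("  %-18s %+.4f\n", nm, x$log_ratio[nm]))
  cat(sprintf("  sum %+.4f = ln(M_start/M_end) %+.4f\n",
              sum(x$log_ratio), x$total_log_ratio))
  invisible(x)
}
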