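# Trend models. The seasonal+linear model
#   f(t) = mu0 + beta*t + amp*sin(2*pi*t + phase),   t = years since record start
# accounts for the pronounced tropical seasonality of all species before a
# linear trend is read off. With the amplitude/phase pair rewritten as
# a*sin(2*pi*t) + b*cos(2*pi*t) the model is linear in its parameters and is
# fit by ordinary least squares on retained months; an optional semi-annual
# harmonic can be added. Annual series (source partitions, burned fraction,
# bottom-up emissions, regime ratios) are trended with the robust Theil-Sen
# median-of-pairwise-slopes estimator, which damps the influence of
# year-to-year variability.

#' Fit the seasonal + linear trend model to a monthly series
#'
#' Uses retained months only (those with at least 5 quality-assured pixels).
#' Applied only to series with sufficient temporal coverage: with the default
#' gate a series must have more than `min_months` retained months (more than
#' 50 months for the 2005-2018 OMI and MODIS records, more than 40 for the
#' 2008-2018 IASI record — both about 30% coverage); otherwise an
#' "insufficient coverage" result is returned rather than a fit.
#'
#' The trend `beta` is significant at the 95% level when its confidence
#' interval does not intersect zero. The relative trend is `100*beta/mu0`,
#' percent of the fitted record-start baseline per year.
#'
#' @param series A `monthly_series`.
#' @param harmonics 1 (annual sinusoid, default) or 2 (adds a semi-annual
#'   term).
#' @param ci_method `"covariance"` (parameter covariance of the least-squares
#'   fit, default) or `"bootstrap"` (block resampling of calendar years).
#' @param min_months Coverage gate: retained months must exceed this.
#' @param conf Confidence level (default 0.95).
#' @param boot_n Bootstrap replicates when `ci_method = "bootstrap"`.
#' @return An object of class `seasonal_trend_fit` with elements `mu0`,
#'   `beta`, `amp`, `phase` (months), `beta_ci`, `rel_trend` (% per year),
#'   `rel_ci`, `significant`, `n_months_used`, `coverage_fraction`; or, below
#'   the gate, the same class with `insufficient_coverage = TRUE`.
#' @export
fit_seasonal_trend <- function(series, harmonics = 1L,
                               ci_method = c("covariance", "bootstrap"),
                               min_months = 50L, conf = 0.95, boot_n = 200L) {
  ci_method <- match.arg(ci_method)
  stopifnot(inherits(series, "monthly_series"), harmonics %in% c(1L, 2L))
  df <- retained_rows(series)
  n_rec <- months_in_record(series)
  base <- list(region_id = series$region_id, species = series$species,
               harmonics = as.integer(harmonics), ci_method = ci_method,
               record_start = series$record_start, record_end = series$record_end,
               n_months_used = nrow(df),
               coverage_fraction = if (n_rec > 0) nrow(df) / n_rec else 0,
               conf = conf)
  if (nrow(df) <= min_months) {
    return(structure(c(base, list(
      insufficient_coverage = TRUE, mu0 = NA_real_, beta = NA_real_,
      amp = NA_real_, phase = NA_real_, beta_ci = c(NA_real_, NA_real_),
      rel_trend = NA_real_, rel_ci = c(NA_real_, NA_real_),
      significant = NA)), class = "seasonal_trend_fit"))
  }
  t <- series_time(series, df$year, df$month)
  X <- data.frame(y = df$mean, t = t,
                  s1 = sin(2 * pi * t), c1 = cos(2 * pi * t))
  form <- y ~ t + s1 + c1
  if (harmonics == 2L) {
    X$s2 <- sin(4 * pi * t); X$c2 <- cos(4 * pi * t)
    form <- y ~ t + s1 + c1 + s2 + c2
  }
  m <- lm(form, data = X)
  cf <- coef(m)
  mu0 <- unname(cf["(Intercept)"]); beta <- unname(cf["t"])
  a <- unname(cf["s1"]); b <- unname(cf["c1"])
  amp <- sqrt(a^2 + b^2)
  phase <- (atan2(b, a) %% (2 * pi)) * 12 / (2 * pi)  # months
  beta_ci <- if (ci_method == "covariance") {
    unname(suppressWarnings(confint(m, "t", level = conf))[1, ])
  } else {
    boot_beta_ci(X, form, df$year, conf, boot_n)
  }
  if (anyNA(beta_ci)) beta_ci <- c(beta, beta)  # perfect fit: zero-width CI
  rel <- if (mu0 > 0) 100 * beta / mu0 else NA_real_
  rel_ci <- if (mu0 > 0) 100 * beta_ci / mu0 else c(NA_real_, NA_real_)
  structure(c(base, list(
    insufficient_coverage = FALSE,
    mu0 = mu0, beta = beta, amp = amp, phase = phase,
    beta_ci = beta_ci, rel_trend = rel, rel_ci = rel_ci,
    significant = beta_ci[1] > 0 || beta_ci[2] < 0,
    coefficients = cf, sigma = suppressWarnings(summary(m)$sigma))),
    class = "seasonal_trend_fit")
}

# Block bootstrap over calendar years: resample years with replacement,
# keep each sampled year's months together.
boot_beta_ci <- function(X, form, year, conf, boot_n) {
  yrs <- unique(year)
  betas <- vapply(seq_len(boot_n), function(i) {
    pick <- sample(yrs, length(yrs), replace = TRUE)
    idx <- unlist(lapply(pick, function(yy) which(year == yy)), use.names = FALSE)
    coef(lm(form, data = X[idx, , drop = FALSE]))["t"]
  }, numeric(1))
  unname(quantile(betas, c((1 - conf) / 2, 1 - (1 - conf) / 2), na.rm = TRUE))
}

#' @export
print.seasonal_trend_fit <- function(x, ...) {
  if (isTRUE(x$insufficient_coverage)) {
    cat(sprintf("<seasonal_trend_fit> %s %s: insufficient coverage (%d months used)\n",
                x$region_id, x$species, x$n_months_used))
    return(invisible(x))
  }
  cat(sprintf(
    "<seasonal_trend_fit> %s %s: baseline %.4g, trend %+.4g / yr (%.2f%% / yr), %s\n",
    x$region_id, x$species, x$mu0, x$beta, x$rel_trend,
    if (isTRUE(x$significant)) "significant at 95% CI" else "not significant"))
  invisible(x)
}

# Evaluate the fitted curve at given calendar months.
predict_seasonal <- function(fit, year, month) {
  if (isTRUE(fit$insufficient_coverage)) stop("cannot predict from an insufficient-coverage fit")
  t <- ((year - fit$record_start[1]) * 12L + (month - fit$record_start[2])) / 12
  cf <- fit$coefficients
  v <- cf["(Intercept)"] + cf["t"] * t +
    cf["s1"] * sin(2 * pi * t) + cf["c1"] * cos(2 * pi * t)
  if (fit$harmonics == 2L)
    v <- v + cf["s2"] * sin(4 * pi * t) + cf["c2"] * cos(4 * pi * t)
  unname(v)
}

#' Annual mean of a fitted seasonal-trend curve
#'
#' Mean of the fitted values over the 12 calendar months of `year`; the
#' concentration term `C` of the population-exposure formula.
#'
#' @param fit A `seasonal_trend_fit`.
#' @param year Calendar year (vectorised).
#' @return Numeric annual mean(s).
#' @export
annual_fit_mean <- function(fit, year) {
  vapply(year, function(y) mean(predict_seasonal(fit, rep(y, 12L), 1:12)),
         numeric(1))
}

#' Theil-Sen robust trend of an annual series
#'
#' The slope is the median of all pairwise slopes `(y_j - y_i)/(x_j - x_i)`,
#' the intercept the median of `y - slope*x`, and the confidence interval the
#' classical rank-based interval on the ordered pairwise slopes.
#'
#' @param x Numeric predictor (calendar years; must be distinct), or a
#'   two-column data frame `(year, value)` when `y` is missing.
#' @param y Numeric response.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `theil_sen_fit` with `slope`, `intercept`,
#'   `slope_ci`, `n_points`.
#' @export
theil_sen <- function(x, y = NULL, conf = 0.95) {
  if (is.null(y)) {
    stopifnot(is.data.frame(x), ncol(x) >= 2)
    y <- x[[2]]; x <- x[[1]]
  }
  keep <- is.finite(x) & is.finite(y)
  x <- as.numeric(x)[keep]; y <- as.numeric(y)[keep]
  n <- length(x)
  if (n < 3) stop("theil_sen needs at least 3 points")
  if (anyDuplicated(x)) stop("duplicate x values (years) in theil_sen input")
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  slopes <- (y[ij[, 2]] - y[ij[, 1]]) / (x[ij[, 2]] - x[ij[, 1]])
  slope <- median(slopes)
  intercept <- median(y - slope * x)
  s <- sort(slopes)
  N <- length(s)
  V <- n * (n - 1) * (2 * n + 5) / 18
  C <- qnorm(1 - (1 - conf) / 2) * sqrt(V)
  lo <- s[max(1L, round((N - C) / 2))]
  hi <- s[min(N, round((N + C) / 2 + 1))]
  structure(list(slope = slope, intercept = intercept,
                 slope_ci = c(lo, hi), n_points = n, conf = conf),
            class = "theil_sen_fit")
}

#' @export
print.theil_sen_fit <- function(x, ...) {
  cat(sprintf("<theil_sen_fit> slope %+.4g / yr [%.4g, %.4g], n = %d\n",
              x$slope, x$slope_ci[1], x$slope_ci[2], x$n_points))
  invisible(x)
}

#' Relative trend against a record-start baseline
#'
#' @param fit A `seasonal_trend_fit` or `theil_sen_fit` (or a bare slope).
#' @param baseline Value at the start of the record (> 0).
#' @return Trend in percent of baseline per year.
#' @export
relative_trend <- function(fit, baseline) {
  if (!is.numeric(baseline) || length(baseline) != 1 || !is.finite(baseline) ||
      baseline <= 0)
    stop("baseline must be a single positive number")
  trend <- if (inherits(fit, "seasonal_trend_fit")) fit$beta
  else if (inherits(fit, "theil_sen_fit")) fit$slope
  else if (is.numeric(fit) && length(fit) == 1) fit
  else stop("fit must be a seasonal_trend_fit, theil_sen_fit or a slope")
  100 * trend / baseline
}

#' Ozone-production regime diagnostic from the HCHO/NO2 column ratio
#'
#' Annual ratios of total-column HCHO (background + reactive NMVOCs) to
#' tropospheric-column NO2 over months retained in both series. Ratios above
#' the threshold (default 2) indicate NOx-sensitive ozone formation; a
#' declining ratio signals a transition toward the VOC-sensitive regime. The
#' threshold-crossing year is extrapolated from the Theil-Sen line through
#' the annual ratios.
#'
#' @param hcho_total A `monthly_series` of total-column HCHO.
#' @param no2 A `monthly_series` of tropospheric-column NO2.
#' @param threshold Regime threshold on the ratio (default 2).
#' @param horizon_years How far beyond the record end a crossing may be
#'   extrapolated (default 30 years).
#' @return An object of class `regime_diagnostic` with `annual_ratio` (data
#'   frame year, ratio), `trend` (a `theil_sen_fit` or NULL), `threshold`,
#'   `crossing_year` (integer or NA) and `degenerate` flag.
#' @export
ozone_regime <- function(hcho_total, no2, threshold = 2, horizon_years = 30) {
  h <- retained_rows(hcho_total); n <- retained_rows(no2)
  common <- merge(h[c("year", "month", "mean")], n[c("year", "month", "mean")],
                  by = c("year", "month"), suffixes = c("_hcho", "_no2"))
  if (!nrow(common)) stop("no overlapping retained months between series")
  ratios <- do.call(rbind, lapply(split(common, common$year), function(dd) {
    no2_mean <- mean(dd$mean_no2)
    if (no2_mean <= 0) {
      warning("non-positive annual NO2 mean in ", dd$year[1], "; year omitted")
      return(NULL)
    }
    data.frame(year = dd$year[1], ratio = mean(dd$mean_hcho) / no2_mean)
  }))
  rownames(ratios) <- NULL
  out <- list(region_id = hcho_total$region_id, annual_ratio = ratios,
              threshold = threshold, trend = NULL,
              crossing_year = NA_integer_, degenerate = FALSE)
  if (nrow(ratios) >= 3) {
    ts <- theil_sen(ratios$year, ratios$ratio)
    out$trend <- ts
    y1 <- min(ratios$year); y2 <- max(ratios$year)
    if (ts$slope == 0) {
      if (isTRUE(all.equal(ts$intercept, threshold))) {
        # flat exactly at the threshold: degenerate boundary case
        out$crossing_year <- as.integer(y1)
        out$degenerate <- TRUE
      }
    } else {
      y_cross <- (threshold - ts$intercept) / ts$slope
      if (y_cross >= y1 - 1e-9 && y_cross <= y2 + horizon_years)
        out$crossing_year <- as.integer(ceiling(y_cross - 1e-8))
    }
  }
  structure(out, class = "regime_diagnostic")
}

#' @export
print.regime_diagnostic <- function(x, ...) {
  cat(sprintf("<regime_diagnostic> %s: %d annual ratios, threshold %.1f, crossing %s%s\n",
              x$region_id, nrow(x$annual_ratio), x$threshold,
              if (is.na(x$crossing_year)) "none" else x$crossing_year,
              if (x$degenerate) " (degenerate: flat at threshold)" else ""))
  invisible(x)
}
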