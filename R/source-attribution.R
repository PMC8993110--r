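# Source attribution: separate each city's monthly means, year by year, into
# months above and below the year's 75th percentile. Months at or below the
# percentile are the nonbiomass-burning (anthropogenic activity) data; from
# burning-season months above it, the annual mean of the below-percentile
# months is removed, leaving the biomass-burning excess. Trend directions of
# the excess are then checked against satellite-derived burned fraction.

#' Default burning-season calendars
#'
#' Month-of-year sets for the four regional burning seasons: December-March
#' in Northern Africa; July-November in Southern Africa; January-April in
#' South Asia and Southeast Asia north of the Equator; August-October in
#' Southeast Asia south of the Equator.
#'
#' @param region One of `"northern_africa"`, `"southern_africa"`,
#'   `"south_asia"`, `"southeast_asia_south"`.
#' @return Integer vector of month indices.
#' @export
burning_season <- function(region = c("northern_africa", "southern_africa",
                                      "south_asia", "southeast_asia_south")) {
  region <- match.arg(region)
  switch(region,
         northern_africa = c(12L, 1L, 2L, 3L),
         southern_africa = 7:11,
         south_asia = 1:4,
         southeast_asia_south = 8:10)
}

#' Partition a monthly series into biomass-burning and anthropogenic data
#'
#' For each calendar year with at least `min_months_year` retained months,
#' the year's 75th percentile (linear-interpolation quantile, R type 7) is
#' computed over retained monthly means. Months with values at or below the
#' percentile form the anthropogenic (nonbiomass-burning) data, summarised by
#' their annual mean; burning-season months strictly above it form the
#' biomass-burning data after removing that annual mean. A year's
#' `overlap_check` is TRUE when every above-percentile month falls in the
#' prescribed burning season — the eligibility signal used to select cities
#' substantially influenced by burning.
#'
#' @param series A `monthly_series`.
#' @param bb_months Integer burning-season month set (see [burning_season()]).
#' @param min_months_year Minimum retained months for a year to be
#'   partitioned (default 8, so the percentile is meaningful).
#' @param quantile_type Quantile convention passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics).
#' @return An object of class `source_partition` with `years` (year, p75,
#'   anth_annual_mean, n_above, overlap_check) and `bb` (year, month, value,
#'   excess) data frames.
#' @export
partition_series <- function(series, bb_months, min_months_year = 8L,
                             quantile_type = 7L) {
  stopifnot(inherits(series, "monthly_series"))
  bb_months <- as.integer(bb_months)
  df <- retained_rows(series)
  yr_rows <- list(); bb_rows <- list()
  for (y in sort(unique(df$year))) {
    dd <- df[df$year == y, , drop = FALSE]
    if (nrow(dd) < min_months_year) next
    p75 <- unname(quantile(dd$mean, 0.75, type = quantile_type))
    above <- dd$mean > p75  # strict: ties classify as anthropogenic
    anth_mean <- mean(dd$mean[!above])
    if (!any(above))
      warning("all months tied in ", series$region_id, " year ", y,
              ": biomass-burning set empty")
    in_season <- above & dd$month %in% bb_months
    yr_rows[[as.character(y)]] <- data.frame(
      year = y, p75 = p75, anth_annual_mean = anth_mean,
      n_above = sum(above),
      overlap_check = !any(above) || all(dd$month[above] %in% bb_months))
    if (any(in_season))
      bb_rows[[as.character(y)]] <- data.frame(
        year = y, month = dd$month[in_season], value = dd$mean[in_season],
        excess = dd$mean[in_season] - anth_mean)
  }
  years <- if (length(yr_rows)) do.call(rbind, yr_rows) else
    data.frame(year = integer(), p75 = numeric(), anth_annual_mean = numeric(),
               n_above = integer(), overlap_check = logical())
  bb <- if (length(bb_rows)) do.call(rbind, bb_rows) else
    data.frame(year = integer(), month = integer(), value = numeric(),
               excess = numeric())
  rownames(years) <- rownames(bb) <- NULL
  structure(list(region_id = series$region_id, species = series$species,
                 bb_month_set = bb_months, years = years, bb = bb,
                 quantile_type = as.integer(quantile_type)),
            class = "source_partition")
}

#' @export
print.source_partition <- function(x, ...) {
  cat(sprintf("<source_partition> %s %s: %d years partitioned, %d burning-season months, overlap in %d/%d years\n",
              x$region_id, x$species, nrow(x$years), nrow(x$bb),
              sum(x$years$overlap_check), nrow(x$years)))
  invisible(x)
}

#' Is a city substantially influenced by biomass burning?
#'
#' TRUE when the above-percentile months coincide with the prescribed burning
#' season (overlap_check) in at least half of the partitioned years.
#'
#' @param partition A `source_partition`.
#' @return Logical.
#' @export
bb_influenced <- function(partition) {
  ny <- nrow(partition$years)
  ny > 0 && sum(partition$years$overlap_check) >= ny / 2
}

#' Theil-Sen trends of the partitioned components
#'
#' The annual biomass-burning value is the mean of burning-season excesses
#' within the year; the annual anthropogenic value is the mean of
#' below-percentile months. Both are trended with [theil_sen()]; relative
#' trends are expressed against the anthropogenic fitted value at the first
#' partitioned year (the record-start anthropogenic baseline).
#'
#' @param partition A `source_partition`.
#' @param min_years Minimum years required on each side (default 3).
#' @return List with `bb` and `anth` (`theil_sen_fit`s), `bb_rel` and
#'   `anth_rel` (% of the anthropogenic baseline per year), `baseline`.
#' @export
partition_trends <- function(partition, min_years = 3L) {
  ya <- partition$years
  if (nrow(ya) < min_years)
    stop("only ", nrow(ya), " partitioned years for ", partition$region_id,
         "; need at least ", min_years)
  bb_annual <- aggregate(excess ~ year, data = partition$bb, FUN = mean)
  if (nrow(bb_annual) < min_years)
    stop("only ", nrow(bb_annual), " years with burning-season excess for ",
         partition$region_id, "; need at least ", min_years)
  anth_fit <- theil_sen(ya$year, ya$anth_annual_mean)
  bb_fit <- theil_sen(bb_annual$year, bb_annual$excess)
  y0 <- min(ya$year)
  baseline <- anth_fit$intercept + anth_fit$slope * y0
  list(bb = bb_fit, anth = anth_fit,
       bb_rel = if (baseline > 0) 100 * bb_fit$slope / baseline else NA_real_,
       anth_rel = if (baseline > 0) 100 * anth_fit$slope / baseline else NA_real_,
       baseline = baseline, baseline_year = y0)
}

#' Directional consistency with burned fraction
#'
#' Compares the sign of the biomass-burning trend with the burned-fraction
#' trend. `"consistent"` when both confidence intervals exclude zero and the
#' slopes share a sign; `"opposite"` when both exclude zero with opposite
#' signs; `"indeterminate"` when either interval spans zero.
#'
#' @param bb_fit `theil_sen_fit` of the biomass-burning data.
#' @param bf_fit `theil_sen_fit` of the annual burned fraction.
#' @return One of `"consistent"`, `"opposite"`, `"indeterminate"`.
#' @export
consistency_with_burned_fraction <- function(bb_fit, bf_fit) {
  excl0 <- function(f) f$slope_ci[1] > 0 || f$slope_ci[2] < 0
  if (!excl0(bb_fit) || !excl0(bf_fit)) return("indeterminate")
  if (sign(bb_fit$slope) == sign(bf_fit$slope)) "consistent" else "opposite"
}
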