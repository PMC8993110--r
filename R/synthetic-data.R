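# Synthetic observation generator. The truth model mirrors the fitting model
# — a linear-in-time relative trend plus one annual sinusoid, with optional
# burning-season excess — so parameter-recovery tests are exact. Every
# stochastic operation is driven by the scenario seed and is bit-reproducible.

#' Define a synthetic city scenario
#'
#' The monthly truth curve, in column units, for month at elapsed time `t`
#' years since record start is
#' `baseline * (1 + rel_trend * t) + baseline * seasonal_amplitude *
#' sin(2*pi*t + 2*pi*seasonal_phase/12)`, plus, in burning-season months,
#' `baseline * bb_excess * (1 + bb_trend * t)`. Monthly means of generated
#' pixels equal this curve exactly when `noise_sd = 0`; otherwise a single
#' Gaussian perturbation `N(0, (noise_sd*baseline)^2)` is added per month
#' (additive mode) and pixel values scatter around the monthly mean without
#' changing it.
#'
#' @param baseline_column Column density at record start (arbitrary units, > 0).
#' @param rel_trend Linear trend as fraction of baseline per year.
#' @param seasonal_amplitude Annual-cycle amplitude as fraction of baseline.
#' @param seasonal_phase Phase of the annual cycle, in months.
#' @param bb_months Integer set (1..12) of burning-season months; empty for none.
#' @param bb_excess Burning-season excess as fraction of baseline.
#' @param bb_trend Fractional trend per year applied to the excess.
#' @param noise_sd Monthly noise s.d. as fraction of baseline.
#' @param noise_mode `"additive"` (default) or `"multiplicative"` (noise scales
#'   with the instantaneous truth value instead of the baseline).
#' @param gap_prob Probability that a month is a coverage gap (< 5 pixels).
#' @param qa_fail_prob Probability of an extra quality-flagged (qa_pass = FALSE)
#'   pixel accompanying each good pixel; such pixels never enter means.
#' @param pixel_size_km Instrument footprint size (metadata only).
#' @param years Length-2 integer vector `c(start, end)`, inclusive.
#' @param pixels_per_month Expected number of good pixels in a non-gap month
#'   (minimum 5 always generated).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return An object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(baseline_column = 1, rel_trend = 0,
                               seasonal_amplitude = 0, seasonal_phase = 0,
                               bb_months = integer(), bb_excess = 0, bb_trend = 0,
                               noise_sd = 0, noise_mode = c("additive", "multiplicative"),
                               gap_prob = 0, qa_fail_prob = 0,
                               pixel_size_km = 6.5,
                               years = c(2005L, 2018L),
                               pixels_per_month = 8, seed = 1L) {
  noise_mode <- match.arg(noise_mode)
  stopifnot(baseline_column > 0, gap_prob >= 0, gap_prob < 1,
            noise_sd >= 0, qa_fail_prob >= 0, qa_fail_prob <= 1,
            length(years) == 2, years[2] >= years[1] + 1,
            pixels_per_month >= 5)
  bb_months <- as.integer(bb_months)
  if (length(bb_months) && (any(bb_months < 1) || any(bb_months > 12)))
    stop("bb_months must be month-of-year indices in 1..12")
  structure(list(baseline_column = baseline_column, rel_trend = rel_trend,
                 seasonal_amplitude = seasonal_amplitude,
                 seasonal_phase = seasonal_phase,
                 bb_months = bb_months, bb_excess = bb_excess, bb_trend = bb_trend,
                 noise_sd = noise_sd, noise_mode = noise_mode,
                 gap_prob = gap_prob, qa_fail_prob = qa_fail_prob,
                 pixel_size_km = pixel_size_km,
                 years = as.integer(years),
                 pixels_per_month = pixels_per_month,
                 seed = as.integer(seed)),
            class = "synthetic_scenario")
}

# Deterministic truth curve (no noise) at elapsed time t years; month is the
# calendar month-of-year used for the burning-season term.
scenario_truth <- function(scenario, t, month) {
  b <- scenario$baseline_column
  v <- b * (1 + scenario$rel_trend * t) +
    b * scenario$seasonal_amplitude *
      sin(2 * pi * t + 2 * pi * scenario$seasonal_phase / 12)
  if (length(scenario$bb_months) && scenario$bb_excess != 0) {
    bb <- month %in% scenario$bb_months
    v <- v + bb * b * scenario$bb_excess * (1 + scenario$bb_trend * t)
  }
  v
}

#' Generate pixel-level observations for a scenario over a region
#'
#' Pixels are placed uniformly inside the (unbuffered) region polygon. In a
#' non-gap month the quality-assured pixel values average exactly to the
#' scenario's monthly mean (truth plus that month's noise draw); gap months
#' emit fewer than 5 usable pixels. Quality-flagged pixels (`qa_pass = FALSE`)
#' carry arbitrary values and must never enter downstream means.
#'
#' @param scenario A `synthetic_scenario`.
#' @param region A `region_geometry` to populate.
#' @return Data frame with columns `lon`, `lat`, `time` (Date, mid-month),
#'   `value`, `qa_pass`.
#' @export
generate_pixels <- function(scenario, region) {
  if (!inherits(region, "region_geometry"))
    stop("generate_pixels needs a region_geometry")
  set.seed(scenario$seed)
  yrs <- scenario$years[1]:scenario$years[2]
  rows <- vector("list", length(yrs) * 12L)
  k <- 0L
  for (y in yrs) {
    for (m in 1:12) {
      k <- k + 1L
      t_ym <- ((y - yrs[1]) * 12L + (m - 1L)) / 12
      gap <- runif(1) < scenario$gap_prob
      n_good <- if (gap) sample(0:4, 1) else
        5L + rpois(1, max(scenario$pixels_per_month - 5, 0))
      truth <- scenario_truth(scenario, t_ym, m)
      noise_scale <- if (scenario$noise_mode == "multiplicative")
        scenario$noise_sd * abs(truth) else scenario$noise_sd * scenario$baseline_column
      m_mean <- truth + if (noise_scale > 0) rnorm(1, 0, noise_scale) else 0
      n_bad <- if (scenario$qa_fail_prob > 0)
        rbinom(1, max(n_good, 1L), scenario$qa_fail_prob) else 0L
      n_tot <- n_good + n_bad
      if (n_tot == 0L) next
      pts <- sample_points_in_region(n_tot, region)
      vals <- numeric(n_tot)
      if (n_good > 0L) {
        dev <- if (noise_scale > 0 && n_good > 1L) rnorm(n_good, 0, noise_scale) else
          numeric(n_good)
        vals[seq_len(n_good)] <- m_mean + (dev - mean(dev))  # exact monthly mean
      }
      if (n_bad > 0L)  # contaminated retrievals: wrong by construction
        vals[n_good + seq_len(n_bad)] <-
          truth * runif(n_bad, 0.2, 3) + scenario$baseline_column
      rows[[k]] <- data.frame(
        lon = pts[, 1], lat = pts[, 2],
        time = as.Date(sprintf("%04d-%02d-15", y, m)),
        value = vals,
        qa_pass = rep(c(TRUE, FALSE), c(n_good, n_bad)))
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

# Uniform rejection sampling inside the polygon (bbox proposals).
sample_points_in_region <- function(n, region) {
  bb <- region_bbox(region)
  out <- matrix(numeric(0), ncol = 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 8L)
    lon <- runif(m, bb["lon_min"], bb["lon_max"])
    lat <- runif(m, bb["lat_min"], bb["lat_max"])
    keep <- point_in_ring(lon, lat, region$coords)
    out <- rbind(out, cbind(lon[keep], lat[keep]))
  }
  out[seq_len(n), , drop = FALSE]
}

#' Define a demographic scenario
#'
#' @param pop_start Population in the first year (> 0).
#' @param pop_growth Fractional population growth per year (compounded).
#' @param frac_over14 Fraction of the population older than 14 years.
#' @param y0_by_year Named numeric vector mapping calendar year to the
#'   all-cause baseline mortality rate (deaths per person per year) for the
#'   over-14 stratum; a single unnamed value is recycled to every year.
#' @param anchor_pm25 Annual-mean PM2.5 (ug m^-3) at `anchor_year`, the
#'   chemical-transport-model anchor for the AOD-scaled PM2.5 series.
#' @param anchor_year Calendar year of the anchor (record midpoint by default).
#' @return An object of class `demographic_scenario`.
#' @export
demographic_scenario <- function(pop_start, pop_growth = 0, frac_over14 = 0.7,
                                 y0_by_year = 0.008, anchor_pm25 = 35,
                                 anchor_year = 2012L) {
  stopifnot(pop_start > 0, frac_over14 > 0, frac_over14 <= 1,
            all(y0_by_year >= 0), anchor_pm25 > 0)
  structure(list(pop_start = pop_start, pop_growth = pop_growth,
                 frac_over14 = frac_over14, y0_by_year = y0_by_year,
                 anchor_pm25 = anchor_pm25, anchor_year = as.integer(anchor_year)),
            class = "demographic_scenario")
}

#' Generate a demographic table
#'
#' Population compounds at `pop_growth` from the first requested year.
#'
#' @param scenario A `demographic_scenario`.
#' @param years Integer vector of calendar years.
#' @param region_id Label attached to every row.
#' @return Data frame with columns `region_id`, `year`, `population`,
#'   `frac_over14`, `y0`.
#' @export
generate_demographics <- function(scenario, years, region_id = "city") {
  years <- as.integer(years)
  pop <- scenario$pop_start * (1 + scenario$pop_growth)^(years - years[1])
  y0v <- scenario$y0_by_year
  y0 <- if (is.null(names(y0v))) rep_len(unname(y0v), length(years)) else {
    miss <- setdiff(as.character(years), names(y0v))
    if (length(miss)) stop("y0_by_year missing years: ", paste(miss, collapse = ", "))
    unname(y0v[as.character(years)])
  }
  data.frame(region_id = region_id, year = years, population = pop,
             frac_over14 = scenario$frac_over14, y0 = y0)
}

#' Gridded annual field container
#'
#' @param lon,lat Cell-center coordinate vectors (degrees, regular spacing).
#' @param years Integer vector of years.
#' @param values Array of dim `c(length(lon), length(lat), length(years))`.
#' @param cellsize Cell edge length in degrees.
#' @return An object of class `annual_grid`.
#' @export
annual_grid <- function(lon, lat, years, values, cellsize) {
  values <- array(values, dim = c(length(lon), length(lat), length(years)))
  structure(list(lon = lon, lat = lat, years = as.integer(years),
                 values = values, cellsize = cellsize),
            class = "annual_grid")
}

#' Generate a gridded annual burned-fraction field
#'
#' Burned fraction is nonzero only when the scenario has a burning season
#' (`bb_excess > 0`): each cell carries a fixed spatial modulation times
#' `0.2 * bb_excess * (1 + bb_trend * (year - start))`, clipped to [0, 1],
#' plus (when `noise_sd > 0`) a small seeded perturbation.
#'
#' @param scenario A `synthetic_scenario`.
#' @param grid_spec List with `lon`, `lat` cell-center vectors and `cellsize`
#'   in degrees (default a 0.25-degree 4x4 patch when omitted fields).
#' @return An `annual_grid` of burned fraction (0..1) per cell-year.
#' @export
generate_burned_fraction <- function(scenario, grid_spec) {
  lon <- grid_spec$lon; lat <- grid_spec$lat
  cs <- grid_spec$cellsize %||% 0.25
  yrs <- scenario$years[1]:scenario$years[2]
  set.seed(scenario$seed + 1L)
  nlon <- length(lon); nlat <- length(lat)
  vals <- array(0, dim = c(nlon, nlat, length(yrs)))
  if (scenario$bb_excess > 0) {
    modulation <- matrix(runif(nlon * nlat, 0.8, 1.2), nlon, nlat)
    base <- 0.2 * scenario$bb_excess
    for (k in seq_along(yrs)) {
      f <- base * (1 + scenario$bb_trend * (yrs[k] - yrs[1])) * modulation
      if (scenario$noise_sd > 0)
        f <- f + rnorm(nlon * nlat, 0, 0.02 * scenario$noise_sd)
      vals[, , k] <- pmin(pmax(f, 0), 1)
    }
  }
  annual_grid(lon, lat, yrs, vals, cs)
}

#' Write pixel observations to CSV
#'
#' Columns: lon, lat, time (ISO-8601 date), value, qa_pass.
#'
#' @param pixels Data frame from [generate_pixels()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pixels_csv <- function(pixels, path) {
  df <- pixels
  df$time <- format(as.Date(df$time), "%Y-%m-%d")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read pixel observations from CSV
#'
#' @param path CSV with columns lon, lat, time, value, qa_pass.
#' @return Data frame with `time` parsed to Date and `qa_pass` logical.
#' @export
read_pixels_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("lon", "lat", "time", "value", "qa_pass")
  if (!all(need %in% names(df)))
    stop("pixel CSV must have columns: ", paste(need, collapse = ", "))
  df$time <- as.Date(df$time)
  df$qa_pass <- as.logical(df$qa_pass)
  df
}

#' Write an annual grid to long-format CSV
#'
#' Columns: lon, lat, year, value, cellsize.
#'
#' @param grid An `annual_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annual_grid <- function(grid, path) {
  df <- expand.grid(lon = grid$lon, lat = grid$lat, year = grid$years,
                    KEEP.OUT.ATTRS = FALSE)
  df$value <- as.vector(grid$values)
  df$cellsize <- grid$cellsize
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an annual grid from long-format CSV
#'
#' @param path CSV written by [write_annual_grid()].
#' @return An `annual_grid`.
#' @export
read_annual_grid <- function(path) {
  df <- read.csv(path)
  lon <- sort(unique(df$lon)); lat <- sort(unique(df$lat))
  yrs <- sort(unique(df$year))
  vals <- array(NA_real_, dim = c(length(lon), length(lat), length(yrs)))
  vals[cbind(match(df$lon, lon), match(df$lat, lat), match(df$year, yrs))] <- df$value
  annual_grid(lon, lat, yrs, vals, df$cellsize[1])
}
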