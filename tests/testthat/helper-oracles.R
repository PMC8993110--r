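# Fixtures and independent oracles used across the suite.

# Small city polygon near the equator (~33 km square).
unit_region <- function(buffer_km = 0, id = "test_city", kind = "city") {
  rect_region(id, 0, 0.3, 0, 0.3, buffer_km = buffer_km, kind = kind)
}

# Build a monthly series directly from per-month values (n_pixels = 6 unless
# overridden), spanning whole calendar years from start_year.
series_from_values <- function(values, start_year = 2005L, n_pixels = 6L,
                               region_id = "test_city", species = "NO2") {
  n <- length(values)
  yr <- start_year + (seq_len(n) - 1L) %/% 12L
  mo <- (seq_len(n) - 1L) %% 12L + 1L
  monthly_series(region_id, species,
                 data.frame(year = yr, month = mo, mean = values,
                            n_pixels = rep_len(n_pixels, n)))
}

# Monthly truth curve used by series-level tests: mirrors the generator's
# model but written independently of package internals.
truth_curve <- function(n_months, baseline, rel_trend, amp_frac = 0,
                        phase_months = 0, bb_months = integer(),
                        bb_excess = 0, bb_trend = 0) {
  t <- (seq_len(n_months) - 1L) / 12
  mo <- (seq_len(n_months) - 1L) %% 12L + 1L
  v <- baseline * (1 + rel_trend * t) +
    baseline * amp_frac * sin(2 * pi * t + 2 * pi * phase_months / 12)
  if (length(bb_months) && bb_excess != 0)
    v <- v + (mo %in% bb_months) * baseline * bb_excess * (1 + bb_trend * t)
  v
}

# Independent point-in-polygon oracle: winding-number by signed angle sum.
oracle_pip <- function(lon, lat, ring) {
  vapply(seq_along(lon), function(k) {
    dx <- ring[, 1] - lon[k]; dy <- ring[, 2] - lat[k]
    if (any(dx == 0 & dy == 0)) return(TRUE)  # on a vertex
    ang <- atan2(dy, dx)
    d <- diff(c(ang, ang[1]))
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    abs(sum(d)) > pi  # winding number != 0
  }, logical(1))
}

# Brute-force Theil-Sen slope: explicit double loop over all pairs.
oracle_theil_sen_slope <- function(x, y) {
  n <- length(x)
  slopes <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      slopes <- c(slopes, (y[j] - y[i]) / (x[j] - x[i]))
    }
  }
  median(slopes)
}

# One pixel table per month at fixed in-polygon locations with given values.
pixels_at <- function(year, month, values, lon = NULL, lat = NULL,
                      qa_pass = TRUE) {
  n <- length(values)
  data.frame(lon = lon %||% seq(0.05, 0.25, length.out = n),
             lat = lat %||% rep(0.15, n),
             time = as.Date(sprintf("%04d-%02d-15", year, month)),
             value = values,
             qa_pass = rep_len(qa_pass, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
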