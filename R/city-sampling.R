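# City sampling: pixel-level observations -> city-wide monthly-mean series.
# Retention rules: a pixel contributes to calendar month m iff its QA flag
# passes and its footprint center lies inside the buffered region; a month is
# retained for analysis only when it has at least 5 such pixels.

#' Sample pixels over a region into a monthly city series
#'
#' @param pixels Data frame with columns `lon`, `lat`, `time` (Date or
#'   ISO-8601 string), `value`, `qa_pass`.
#' @param region A `region_geometry`; its `buffer_km` extends the sampling
#'   domain beyond the polygon (used for the 22 smallest cities, matching the
#'   instrument pixel size).
#' @param species Species label stored on the series.
#' @param min_pixels Per-month retention threshold (default 5).
#' @param record_start,record_end Optional `c(year, month)` record bounds;
#'   default to the span of the pixel table (all pixels, so the record is
#'   defined by the instrument, not by QA luck).
#' @return A `monthly_series`. If no months remain a warning is issued and an
#'   empty series returned.
#' @export
sample_region <- function(pixels, region, species = "NO2", min_pixels = 5L,
                          record_start = NULL, record_end = NULL) {
  pixels <- normalize_pixels(pixels)
  if (any(pixels$value < 0 & pixels$qa_pass) && species == "AOD")
    stop("negative AOD values in qa-passing pixels")
  if (nrow(pixels)) {
    ym_all <- pixels$year * 12L + pixels$month
    record_start <- record_start %||% ym_to_c(min(ym_all))
    record_end <- record_end %||% ym_to_c(max(ym_all))
  }
  ok <- pixels$qa_pass & point_in_region(pixels$lon, pixels$lat, region)
  px <- pixels[ok, , drop = FALSE]
  if (!nrow(px)) {
    warning("no qa-passing pixels inside region '", region$region_id,
            "': empty series")
    return(monthly_series(region$region_id, species,
                          data.frame(year = integer(), month = integer(),
                                     mean = numeric(), n_pixels = integer()),
                          record_start = record_start, record_end = record_end,
                          min_pixels = min_pixels))
  }
  key <- px$year * 12L + px$month
  agg <- aggregate(px$value, by = list(key = key),
                   FUN = function(v) c(mean(v), length(v)))
  df <- data.frame(year = (agg$key - 1L) %/% 12L,
                   month = (agg$key - 1L) %% 12L + 1L,
                   mean = agg$x[, 1], n_pixels = as.integer(agg$x[, 2]))
  monthly_series(region$region_id, species, df,
                 record_start = record_start, record_end = record_end,
                 min_pixels = min_pixels)
}

# year*12 + month key back to c(year, month)
ym_to_c <- function(key) c((key - 1L) %/% 12L, (key - 1L) %% 12L + 1L)

normalize_pixels <- function(pixels) {
  need <- c("lon", "lat", "time", "value", "qa_pass")
  if (!all(need %in% names(pixels)))
    stop("pixel table must have columns: ", paste(need, collapse = ", "))
  tm <- as.Date(pixels$time)
  pixels$year <- as.integer(format(tm, "%Y"))
  pixels$month <- as.integer(format(tm, "%m"))
  pixels$qa_pass <- as.logical(pixels$qa_pass)
  pixels
}

#' Monthly background series over a remote ocean domain
#'
#' Same mechanics as [sample_region()], for the ocean domain used to isolate
#' the background (methane-oxidation) component of the HCHO column. The ocean
#' box should extend over the same latitudinal range as its paired city;
#' a mismatch beyond `lat_tol` degrees is reported as a warning.
#'
#' @param pixels Pixel table (see [sample_region()]).
#' @param ocean_region A `region_geometry` with `kind = "ocean_background"`.
#' @param species Species label (HCHO for the background correction).
#' @param paired_city Optional `region_geometry` of the city this background
#'   serves, used for the latitude-range check.
#' @param lat_tol Tolerated latitude-range mismatch in degrees (default 1).
#' @param ... Passed to [sample_region()].
#' @return A `monthly_series`.
#' @export
background_series <- function(pixels, ocean_region, species = "HCHO",
                              paired_city = NULL, lat_tol = 1, ...) {
  if (ocean_region$kind != "ocean_background")
    stop("background_series needs a region of kind 'ocean_background'")
  if (!is.null(paired_city)) {
    bo <- region_bbox(ocean_region); bc <- region_bbox(paired_city)
    d <- max(abs(bo["lat_min"] - bc["lat_min"]), abs(bo["lat_max"] - bc["lat_max"]))
    if (d > lat_tol)
      warning(sprintf(
        "ocean background '%s' latitude range differs from city '%s' by %.2f deg (tol %.2f)",
        ocean_region$region_id, paired_city$region_id, d, lat_tol))
  }
  sample_region(pixels, ocean_region, species = species, ...)
}

#' Subtract a fitted background from a city series
#'
#' Isolates the reactive-NMVOC component of the HCHO column: the seasonal
#' trend fit of the ocean background is evaluated at each retained city month
#' and subtracted from the city monthly mean. Negative residuals (common when
#' columns sit near the instrument detection limit) are kept and flagged.
#'
#' @param city A `monthly_series` over a city.
#' @param background_fit A `seasonal_trend_fit` produced from the paired
#'   ocean-background series.
#' @param species Label for the output series.
#' @return A `monthly_series` of background-corrected values; carries flag
#'   `"negative_residual"` when any retained residual is negative.
#' @export
subtract_background <- function(city, background_fit, species = "HCHO_reactive") {
  if (!inherits(background_fit, "seasonal_trend_fit"))
    stop("background_fit must be a seasonal_trend_fit")
  if (isTRUE(background_fit$insufficient_coverage))
    stop("background fit has insufficient coverage; cannot subtract")
  df <- city$data
  out_of_support <- df$retained &
    (ym_key(df$year, df$month) < ym_key(background_fit$record_start[1], background_fit$record_start[2]) |
     ym_key(df$year, df$month) > ym_key(background_fit$record_end[1], background_fit$record_end[2]))
  if (any(out_of_support))
    stop("city months outside the background fit support: ",
         paste(sprintf("%d-%02d", df$year[out_of_support], df$month[out_of_support])[
           seq_len(min(3, sum(out_of_support)))], collapse = ", "))
  fitted <- predict_seasonal(background_fit, df$year, df$month)
  df$mean <- df$mean - fitted
  flags <- character()
  if (any(df$mean < 0 & df$retained, na.rm = TRUE)) flags <- "negative_residual"
  monthly_series(city$region_id, species, df[c("year", "month", "mean", "n_pixels")],
                 record_start = city$record_start, record_end = city$record_end,
                 min_pixels = city$min_pixels, flags = flags)
}

ym_key <- function(year, month) year * 12L + month

#' Sample HCHO over a rural reference box
#'
#' Builds a `box_size_deg` x `box_size_deg` box whose center lies at a given
#' bearing and distance from the city centroid, and samples it. The distance
#' must fall in the 50-100 km annulus so the box is rural but still shares the
#' city's airshed-scale biogenic environment.
#'
#' @param pixels Pixel table.
#' @param city_center Numeric `c(lon, lat)` (e.g. [region_centroid()]).
#' @param distance_km Distance from the city centroid to the box center;
#'   must lie in `annulus_km`.
#' @param bearing_deg Placement bearing, degrees clockwise from north.
#' @param box_size_deg Box edge in degrees (default 0.2).
#' @param annulus_km Allowed distance range, default `c(50, 100)`.
#' @param species Species label (default HCHO).
#' @param ... Passed to [sample_region()].
#' @return A list with the `region` used and the sampled `series`.
#' @export
rural_reference <- function(pixels, city_center, distance_km = 75,
                            bearing_deg = 90, box_size_deg = 0.2,
                            annulus_km = c(50, 100), species = "HCHO", ...) {
  if (distance_km < annulus_km[1] || distance_km > annulus_km[2])
    stop(sprintf(
      "rural box at %.0f km violates the %.0f-%.0f km annulus constraint",
      distance_km, annulus_km[1], annulus_km[2]))
  ctr <- geosphere::destPoint(c(city_center[1], city_center[2]),
                              b = bearing_deg, d = distance_km * 1000)
  half <- box_size_deg / 2
  region <- rect_region(sprintf("rural_%.0fkm_%03.0fdeg", distance_km, bearing_deg),
                        ctr[1] - half, ctr[1] + half, ctr[2] - half, ctr[2] + half,
                        buffer_km = 0, kind = "rural_reference")
  list(region = region,
       series = sample_region(pixels, region, species = species, ...))
}

#' Sample a gridded annual field over a region
#'
#' Annual value over the buffered region, from cells overlapping the same
#' sampling extent as the satellite observations. `mode = "mean"` gives the
#' overlap-area-weighted mean (burned fraction); `mode = "sum"` the
#' overlap-fraction-weighted sum of cell totals (emissions).
#'
#' Overlap fractions are estimated on a regular `subsamples` x `subsamples`
#' lattice of points inside each cell (exact for cells fully inside or
#' outside the region).
#'
#' @param grid An `annual_grid`.
#' @param region A `region_geometry`.
#' @param mode `"mean"` or `"sum"`.
#' @param subsamples Lattice resolution per cell edge (default 6).
#' @return Data frame with columns `year`, `value`.
#' @export
sample_gridded_annual_field <- function(grid, region, mode = c("mean", "sum"),
                                        subsamples = 6L) {
  mode <- match.arg(mode)
  cs <- grid$cellsize
  cells <- expand.grid(i = seq_along(grid$lon), j = seq_along(grid$lat),
                       KEEP.OUT.ATTRS = FALSE)
  # overlap fraction per cell on a subsample lattice
  offs <- (seq_len(subsamples) - 0.5) / subsamples - 0.5
  frac <- numeric(nrow(cells))
  for (k in seq_len(nrow(cells))) {
    cx <- grid$lon[cells$i[k]]; cy <- grid$lat[cells$j[k]]
    pts <- expand.grid(lon = cx + offs * cs, lat = cy + offs * cs,
                       KEEP.OUT.ATTRS = FALSE)
    frac[k] <- mean(point_in_region(pts$lon, pts$lat, region))
  }
  if (all(frac == 0))
    stop("grid does not overlap region '", region$region_id, "'")
  # cell areas (km^2) for area weighting; only relative weights matter
  area <- (cs * 111.320 * cos(grid$lat[cells$j] * pi / 180)) * (cs * 110.574)
  out <- data.frame(year = grid$years, value = NA_real_)
  for (k in seq_along(grid$years)) {
    v <- grid$values[cbind(cells$i, cells$j, k)]
    out$value[k] <- if (mode == "mean")
      sum(v * frac * area) / sum(frac * area)
    else sum(v * frac)
  }
  out
}
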