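# MonthlyCitySeries: the central container of all trend analysis — one
# city-wide monthly-mean value per calendar month with its pixel count and the
# retention flag (months with fewer than 5 quality-assured pixels are kept in
# the table but never used downstream).

#' Construct a monthly city series
#'
#' @param region_id Region label.
#' @param species One of `"NO2"`, `"HCHO"`, `"NH3"`, `"AOD"`, or a derived
#'   label such as `"HCHO_reactive"`.
#' @param data Data frame with columns `year`, `month`, `mean`, `n_pixels`;
#'   `retained` is recomputed as `n_pixels >= min_pixels`. Empty months (no
#'   pixels at all) must simply be absent — a mean over an empty set is never
#'   represented as zero.
#' @param record_start,record_end Length-2 integer vectors `c(year, month)`
#'   bounding the observing record; default to the first/last month present.
#' @param min_pixels Retention threshold (default 5 pixels per month).
#' @param flags Optional character vector of per-series flags (e.g.
#'   `"negative_residual"` after background subtraction).
#' @return An object of class `monthly_series`.
#' @export
monthly_series <- function(region_id, species, data,
                           record_start = NULL, record_end = NULL,
                           min_pixels = 5L, flags = character()) {
  stopifnot(is.data.frame(data),
            all(c("year", "month", "mean", "n_pixels") %in% names(data)))
  data <- data[order(data$year, data$month),
               c("year", "month", "mean", "n_pixels"), drop = FALSE]
  if (anyDuplicated(data[c("year", "month")]))
    stop("duplicate calendar months in series for ", region_id)
  if (any(data$month < 1 | data$month > 12)) stop("month indices must be in 1..12")
  data$retained <- data$n_pixels >= min_pixels
  rownames(data) <- NULL
  if (nrow(data)) {
    record_start <- record_start %||% c(data$year[1], data$month[1])
    record_end <- record_end %||% c(data$year[nrow(data)], data$month[nrow(data)])
  }
  structure(list(region_id = as.character(region_id), species = species,
                 data = data,
                 record_start = as.integer(record_start),
                 record_end = as.integer(record_end),
                 min_pixels = as.integer(min_pixels),
                 flags = flags),
            class = "monthly_series")
}

#' @export
print.monthly_series <- function(x, ...) {
  cat(sprintf("<monthly_series> %s %s: %d months (%d retained)",
              x$region_id, x$species, nrow(x$data), sum(x$data$retained)))
  if (length(x$record_start))
    cat(sprintf(", record %d-%02d to %d-%02d", x$record_start[1], x$record_start[2],
                x$record_end[1], x$record_end[2]))
  if (length(x$flags)) cat("\n  flags:", paste(x$flags, collapse = ", "))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.monthly_series <- function(x, ...) {
  if (!nrow(x$data)) {
    return(data.frame(region_id = character(), species = character(),
                      year = integer(), month = integer(), mean = numeric(),
                      n_pixels = integer(), retained = logical()))
  }
  cbind(region_id = x$region_id, species = x$species, x$data)
}

# Months in the inclusive record span.
months_in_record <- function(x) {
  if (!length(x$record_start)) return(0L)
  (x$record_end[1] - x$record_start[1]) * 12L +
    (x$record_end[2] - x$record_start[2]) + 1L
}

# Decimal years since record start for each row (month granularity).
series_time <- function(x, year = x$data$year, month = x$data$month) {
  ((year - x$record_start[1]) * 12L + (month - x$record_start[2])) / 12
}

# Rows usable for fitting.
retained_rows <- function(x) x$data[x$data$retained & is.finite(x$data$mean), , drop = FALSE]

#' Write monthly series to tidy CSV
#'
#' Columns: region_id, species, year, month, mean, n_pixels, retained.
#'
#' @param series A `monthly_series` or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_monthly_series <- function(series, path) {
  if (inherits(series, "monthly_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, as.data.frame))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read monthly series from tidy CSV
#'
#' @param path CSV written by [write_monthly_series()].
#' @param min_pixels Retention threshold used to rebuild the series.
#' @return A list of `monthly_series`, one per region/species pair.
#' @export
read_monthly_series <- function(path, min_pixels = 5L) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  keys <- unique(df[c("region_id", "species")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$region_id == keys$region_id[i] & df$species == keys$species[i], ]
    s <- monthly_series(keys$region_id[i], keys$species[i],
                        sub[c("year", "month", "mean", "n_pixels")],
                        min_pixels = min_pixels)
    out[[paste(keys$region_id[i], keys$species[i], sep = ".")]] <- s
  }
  out
}
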