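# Pipeline orchestration: synthesize -> sample -> fit -> partition ->
# exposure -> health -> decompose, each stage reading only the declared files
# of the previous one, with a JSON run manifest recording seed, config hash
# and stage status. Deterministic stages are bit-reproducible for a fixed
# config.

#' Specify one city for a pipeline run
#'
#' @param region A `region_geometry` (kind `"city"`), or NULL when
#'   `region_path` is given.
#' @param scenarios Named list mapping species (`"NO2"`, `"AOD"`, `"HCHO"`,
#'   `"NH3"`) to `synthetic_scenario`s.
#' @param demographic A `demographic_scenario`.
#' @param bb_months Burning-season month set (empty: city not partitioned).
#' @param ocean_region Optional `region_geometry` of kind
#'   `"ocean_background"`, required when an HCHO scenario is present.
#' @param ocean_scenario Optional `synthetic_scenario` for the ocean
#'   background HCHO field.
#' @param region_path Optional GeoJSON path to load the city polygon from.
#' @return An object of class `city_spec`.
#' @export
city_spec <- function(region = NULL, scenarios, demographic,
                      bb_months = integer(), ocean_region = NULL,
                      ocean_scenario = NULL, region_path = NULL) {
  if (is.null(region) && is.null(region_path))
    stop("city_spec needs a region or a region_path")
  if ("HCHO" %in% names(scenarios) &&
      (is.null(ocean_region) || is.null(ocean_scenario)))
    stop("an HCHO scenario requires ocean_region and ocean_scenario for the background correction")
  structure(list(region = region, region_path = region_path,
                 scenarios = scenarios, demographic = demographic,
                 bb_months = as.integer(bb_months),
                 ocean_region = ocean_region, ocean_scenario = ocean_scenario),
            class = "city_spec")
}

#' Build a pipeline run configuration
#'
#' @param cities Named list of `city_spec`s (names are region ids).
#' @param out_dir Output directory (created on run).
#' @param seed Integer master seed, recorded in every output header.
#' @param min_months Coverage gate for [fit_seasonal_trend()].
#' @param harmonics,ci_method Passed to [fit_seasonal_trend()].
#' @param quantile_type Quantile convention for [partition_series()].
#' @param crf A `crf_spec`, or a path to a CRF CSV ([read_crf_csv()]).
#' @param exposure_years `c(start, end)` calendar years for exposure and
#'   mortality endpoints (default 2005 and 2018).
#' @param mortality_n_years Observing-period length for per-year mortality
#'   averages (default 14).
#' @param anchor_year PM2.5 anchor year (default 2012).
#' @return An object of class `run_config`.
#' @export
run_config <- function(cities, out_dir, seed = 1L, min_months = 50L,
                       harmonics = 1L, ci_method = "covariance",
                       quantile_type = 7L, crf = NULL,
                       exposure_years = c(2005L, 2018L),
                       mortality_n_years = 14, anchor_year = 2012L) {
  structure(list(cities = cities, out_dir = out_dir, seed = as.integer(seed),
                 min_months = min_months, harmonics = harmonics,
                 ci_method = ci_method, quantile_type = quantile_type,
                 crf = crf, exposure_years = as.integer(exposure_years),
                 mortality_n_years = mortality_n_years,
                 anchor_year = as.integer(anchor_year)),
            class = "run_config")
}

# Order-sensitive 31-bit polynomial hash over the serialized config.
config_hash <- function(config) {
  bytes <- as.integer(serialize(config, NULL, ascii = TRUE))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Validate a run configuration
#'
#' Checks referenced files exist and resolves path-based members; errors
#' before any stage runs.
#'
#' @param config A `run_config`.
#' @return The resolved config, invisibly usable by [run_pipeline()].
#' @export
validate_config <- function(config) {
  stopifnot(inherits(config, "run_config"), length(config$cities) > 0)
  if (is.null(names(config$cities)) || any(names(config$cities) == ""))
    stop("cities must be a named list")
  for (nm in names(config$cities)) {
    cs <- config$cities[[nm]]
    if (!is.null(cs$region_path)) {
      if (!file.exists(cs$region_path))
        stop("geometry file not found for city '", nm, "': ", cs$region_path)
      regs <- read_geojson_regions(cs$region_path)
      if (!nm %in% names(regs))
        stop("region '", nm, "' absent from ", cs$region_path)
      config$cities[[nm]]$region <- regs[[nm]]
    }
  }
  if (is.character(config$crf)) {
    if (!file.exists(config$crf)) stop("CRF file not found: ", config$crf)
    config$crf <- read_crf_csv(config$crf)
  }
  if (is.null(config$crf)) config$crf <- default_crf()
  config
}

stage_names <- c("synth", "sample", "fit", "partition", "exposure", "health")

#' Run the pipeline (all stages or a subset)
#'
#' Executes the requested stages in canonical order (synth, sample, fit,
#' partition, exposure, health) over the configured cities, writing tidy CSV
#' outputs and a JSON manifest under `config$out_dir`. Stages communicate
#' only through their declared files, so a later stage can be re-run on its
#' own against an existing output directory. A stage failure is recorded in
#' the manifest (with the error message) and later stages are skipped.
#'
#' @param config A `run_config`.
#' @param stages Character subset of the six stage names; default all.
#' @return The run manifest (list), invisibly also written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, stages = stage_names) {
  stopifnot(all(stages %in% stage_names))
  config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = config$seed, config_hash = config_hash(config),
                   out_dir = config$out_dir, stages = list())
  state <- new.env(parent = emptyenv())
  for (st in stage_names[stage_names %in% stages]) {
    res <- tryCatch({
      outputs <- switch(st,
        synth = stage_synth(config, state),
        sample = stage_sample(config, state),
        fit = stage_fit(config, state),
        partition = stage_partition(config, state),
        exposure = stage_exposure(config, state),
        health = stage_health(config, state))
      list(status = "ok", outputs = as.list(outputs))
    }, error = function(e) list(status = "failed", error = conditionMessage(e)))
    manifest$stages[[st]] <- res
    if (res$status == "failed") {
      warning("stage '", st, "' failed: ", res$error)
      break
    }
  }
  manifest$complete <- all(vapply(manifest$stages, function(s)
    identical(s$status, "ok"), logical(1))) &&
    length(manifest$stages) == length(stages)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

out_path <- function(config, ...) file.path(config$out_dir, ...)

write_stamped_csv <- function(df, path, config) {
  con <- file(path, "w")
  writeLines(sprintf("# tropicair seed=%d hash=%s", config$seed,
                     config_hash(config)), con)
  write.csv(df, con, row.names = FALSE)
  close(con)
  path
}

read_stamped_csv <- function(path) read.csv(path, comment.char = "#")

stage_synth <- function(config, state) {
  outputs <- character()
  regions <- list()
  for (nm in names(config$cities)) {
    cs <- config$cities[[nm]]
    regions[[nm]] <- cs$region
    for (sp in names(cs$scenarios)) {
      px <- generate_pixels(cs$scenarios[[sp]], cs$region)
      p <- out_path(config, sprintf("pixels_%s_%s.csv", nm, sp))
      write_pixels_csv(px, p); outputs <- c(outputs, p)
    }
    if (!is.null(cs$ocean_scenario)) {
      regions[[cs$ocean_region$region_id]] <- cs$ocean_region
      px <- generate_pixels(cs$ocean_scenario, cs$ocean_region)
      p <- out_path(config, sprintf("pixels_%s_HCHO_background.csv", nm))
      write_pixels_csv(px, p); outputs <- c(outputs, p)
    }
    if (length(cs$bb_months) && "NO2" %in% names(cs$scenarios)) {
      bb <- region_bbox(cs$region, buffered = TRUE)
      grid <- list(lon = seq(bb["lon_min"], bb["lon_max"], length.out = 4),
                   lat = seq(bb["lat_min"], bb["lat_max"], length.out = 4),
                   cellsize = 0.25)
      bf <- generate_burned_fraction(cs$scenarios[["NO2"]], grid)
      p <- out_path(config, sprintf("burned_fraction_%s.csv", nm))
      write_annual_grid(bf, p); outputs <- c(outputs, p)
    }
  }
  demo <- do.call(rbind, lapply(names(config$cities), function(nm) {
    cs <- config$cities[[nm]]
    yrs <- cs$scenarios[[1]]$years
    generate_demographics(cs$demographic, yrs[1]:yrs[2], region_id = nm)
  }))
  p <- out_path(config, "demographics.csv")
  write_stamped_csv(demo, p, config); outputs <- c(outputs, p)
  g <- out_path(config, "regions.geojson")
  write_geojson_regions(regions, g); outputs <- c(outputs, g)
  outputs
}

stage_sample <- function(config, state) {
  all_series <- list()
  for (nm in names(config$cities)) {
    cs <- config$cities[[nm]]
    for (sp in names(cs$scenarios)) {
      px <- read_pixels_csv(out_path(config, sprintf("pixels_%s_%s.csv", nm, sp)))
      ser <- sample_region(px, cs$region, species = sp)
      all_series[[paste(nm, sp, sep = ".")]] <- ser
      if (sp == "HCHO") {
        bpx <- read_pixels_csv(out_path(config,
                                        sprintf("pixels_%s_HCHO_background.csv", nm)))
        bg <- background_series(bpx, cs$ocean_region, paired_city = cs$region)
        all_series[[paste(nm, "HCHO_background", sep = ".")]] <- bg
        bg_fit <- fit_seasonal_trend(bg, harmonics = config$harmonics,
                                     ci_method = config$ci_method,
                                     min_months = config$min_months)
        if (!isTRUE(bg_fit$insufficient_coverage)) {
          corr <- subtract_background(ser, bg_fit)
          all_series[[paste(nm, "HCHO_reactive", sep = ".")]] <- corr
        }
      }
    }
  }
  state$series <- all_series
  p <- out_path(config, "series.csv")
  write_monthly_series(all_series, p)
  p
}

# Stages re-run in a fresh session rebuild their inputs from declared files.
ensure_series <- function(config, state) {
  if (!is.null(state$series)) return(invisible())
  p <- out_path(config, "series.csv")
  if (!file.exists(p)) stop("no series.csv in ", config$out_dir,
                            "; run the sample stage first")
  state$series <- read_monthly_series(p)
  invisible()
}

ensure_fits <- function(config, state) {
  if (!is.null(state$fits)) return(invisible())
  ensure_series(config, state)
  state$fits <- setNames(
    lapply(state$series, fit_seasonal_trend, harmonics = config$harmonics,
           ci_method = config$ci_method, min_months = config$min_months),
    names(state$series))
  invisible()
}

stage_fit <- function(config, state) {
  ensure_series(config, state)
  state$fits <- setNames(
    lapply(state$series, fit_seasonal_trend, harmonics = config$harmonics,
           ci_method = config$ci_method, min_months = config$min_months),
    names(state$series))
  rows <- lapply(state$fits, function(f)
    data.frame(region_id = f$region_id, species = f$species,
               status = if (isTRUE(f$insufficient_coverage))
                 "insufficient coverage" else "ok",
               baseline = f$mu0, trend = f$beta,
               rel_trend_pct = f$rel_trend,
               ci_low = f$beta_ci[1], ci_high = f$beta_ci[2],
               significant = f$significant,
               amp = f$amp, phase_months = f$phase,
               n_months = f$n_months_used,
               coverage = round(f$coverage_fraction, 4)))
  p <- out_path(config, "trends.csv")
  write_stamped_csv(do.call(rbind, unname(rows)), p, config)
  p
}

stage_partition <- function(config, state) {
  ensure_series(config, state)
  rows <- list()
  for (nm in names(config$cities)) {
    cs <- config$cities[[nm]]
    if (!length(cs$bb_months)) next
    for (sp in intersect(c("NO2", "NH3", "HCHO_reactive"),
                         sub("^.*\\.", "", grep(paste0("^", nm, "\\."),
                                                names(state$series), value = TRUE)))) {
      ser <- state$series[[paste(nm, sp, sep = ".")]]
      part <- partition_series(ser, cs$bb_months,
                               quantile_type = config$quantile_type)
      tr <- tryCatch(partition_trends(part), error = function(e) NULL)
      if (is.null(tr)) next
      bf_path <- out_path(config, sprintf("burned_fraction_%s.csv", nm))
      label <- NA_character_
      if (file.exists(bf_path)) {
        bf <- sample_gridded_annual_field(read_annual_grid(bf_path),
                                          cs$region, mode = "mean")
        bf_fit <- theil_sen(bf$year, bf$value)
        label <- consistency_with_burned_fraction(tr$bb, bf_fit)
      }
      rows[[paste(nm, sp)]] <- data.frame(
        region_id = nm, species = sp,
        bb_influenced = bb_influenced(part),
        bb_slope = tr$bb$slope, bb_ci_low = tr$bb$slope_ci[1],
        bb_ci_high = tr$bb$slope_ci[2], bb_rel_pct = tr$bb_rel,
        anth_slope = tr$anth$slope, anth_ci_low = tr$anth$slope_ci[1],
        anth_ci_high = tr$anth$slope_ci[2], anth_rel_pct = tr$anth_rel,
        burned_fraction_consistency = label)
    }
  }
  df <- if (length(rows)) do.call(rbind, unname(rows)) else
    data.frame(region_id = character(), species = character())
  p <- out_path(config, "partitions.csv")
  write_stamped_csv(df, p, config)
  p
}

stage_exposure <- function(config, state) {
  ensure_fits(config, state)
  demo <- read_stamped_csv(out_path(config, "demographics.csv"))
  ys <- config$exposure_years
  rows <- list()
  for (nm in names(config$cities)) {
    dd <- demo[demo$region_id == nm, ]
    for (sp in c("AOD", "NO2")) {
      f <- state$fits[[paste(nm, sp, sep = ".")]]
      if (is.null(f) || isTRUE(f$insufficient_coverage)) next
      N1 <- dd$population[dd$year == ys[1]]; N2 <- dd$population[dd$year == ys[2]]
      if (!length(N1) || !length(N2))
        stop("demographics for city '", nm, "' lack exposure years ",
             ys[1], "/", ys[2])
      E1 <- population_exposure(N1, f, ys[1])
      E2 <- population_exposure(N2, f, ys[2])
      nyr <- ys[2] - ys[1]
      pop_pct <- exposure_trend(N1, N2, nyr)
      conc_pct <- exposure_trend(annual_fit_mean(f, ys[1]),
                                 annual_fit_mean(f, ys[2]), nyr)
      rows[[paste(nm, sp)]] <- data.frame(
        region_id = nm, species = sp, E_start = E1, E_end = E2,
        rel_exposure_trend_pct = exposure_trend(E1, E2, nyr),
        pop_trend_pct = pop_pct, conc_trend_pct = conc_pct,
        additive_pct = compose_trends(pop_pct, conc_pct)$additive)
    }
  }
  df <- if (length(rows)) do.call(rbind, unname(rows)) else
    data.frame(region_id = character())
  p <- out_path(config, "exposure.csv")
  write_stamped_csv(df, p, config)
  p
}

stage_health <- function(config, state) {
  ensure_fits(config, state)
  demo <- read_stamped_csv(out_path(config, "demographics.csv"))
  ys <- config$exposure_years
  mort <- list(); deco <- list()
  for (nm in names(config$cities)) {
    cs <- config$cities[[nm]]
    f <- state$fits[[paste(nm, "AOD", sep = ".")]]
    if (is.null(f) || isTRUE(f$insufficient_coverage)) next  # no discernible AOD trend
    dd <- demo[demo$region_id == nm, ]
    pm <- pm25_timeseries(cs$demographic$anchor_pm25, f, ys,
                          anchor_year = config$anchor_year)
    est <- lapply(seq_along(ys), function(i) {
      drow <- dd[dd$year == ys[i], ]
      premature_deaths(drow$population, drow$frac_over14, drow$y0,
                       attributable_fraction(pm$pm25[i], config$crf),
                       region_id = nm, year = ys[i])
    })
    ch <- mortality_change(est[[1]], est[[2]], n_years = config$mortality_n_years)
    mort[[nm]] <- data.frame(
      region_id = nm, pm25_start = pm$pm25[1], pm25_end = pm$pm25[2],
      deaths_start = est[[1]]$deaths, deaths_start_low = est[[1]]$deaths_low,
      deaths_start_high = est[[1]]$deaths_high,
      deaths_end = est[[2]]$deaths, deaths_end_low = est[[2]]$deaths_low,
      deaths_end_high = est[[2]]$deaths_high,
      change = ch$change, relative_pct = ch$relative_pct,
      per_year = ch$per_year)
    d1 <- dd[dd$year == ys[1], ]; d2 <- dd[dd$year == ys[2], ]
    dec <- decompose_factors(
      list(pop = d1$population, frac_over14 = d1$frac_over14, y0 = d1$y0,
           pm25 = pm$pm25[1]),
      list(pop = d2$population, frac_over14 = d2$frac_over14, y0 = d2$y0,
           pm25 = pm$pm25[2]),
      config$crf)
    deco[[nm]] <- data.frame(region_id = nm, t(dec$log_ratio),
                             total_log_ratio = dec$total_log_ratio)
  }
  p1 <- out_path(config, "mortality.csv")
  write_stamped_csv(if (length(mort)) do.call(rbind, unname(mort)) else
    data.frame(region_id = character()), p1, config)
  p2 <- out_path(config, "decomposition.csv")
  write_stamped_csv(if (length(deco)) do.call(rbind, unname(deco)) else
    data.frame(region_id = character()), p2, config)
  c(p1, p2)
}

#' Summarize a completed run
#'
#' Reads the stage outputs referenced by a manifest into per-city summary
#' tables; cities failing the coverage gate remain present, flagged
#' "insufficient coverage".
#'
#' @param manifest A run manifest from [run_pipeline()], or the path to a
#'   `manifest.json`.
#' @return List of data frames: `trends`, `partitions`, `exposure`,
#'   `mortality`, `decomposition`.
#' @export
summarize_run <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  out_dir <- manifest$out_dir
  rd <- function(f) {
    p <- file.path(out_dir, f)
    if (file.exists(p)) read_stamped_csv(p) else data.frame()
  }
  list(trends = rd("trends.csv"), partitions = rd("partitions.csv"),
       exposure = rd("exposure.csv"), mortality = rd("mortality.csv"),
       decomposition = rd("decomposition.csv"))
}
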