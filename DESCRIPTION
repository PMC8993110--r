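Package: tropicair
Title: Satellite-Derived Air-Quality Trends, Sources, and Health Burden in
    Fast-Growing Cities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for city-scale analysis of satellite column observations of
    short-lived air pollutants (NO2, HCHO, NH3) and aerosol optical depth.
    Samples pixel-level observations over buffered city polygons into monthly
    mean series, isolates the reactive NMVOC component of HCHO by subtracting a
    fitted ocean background, fits a seasonal harmonic plus linear trend model
    with 95% confidence intervals, estimates robust annual trends with the
    Theil-Sen median estimator, partitions series into biomass-burning and
    anthropogenic components with a per-year 75th-percentile rule, diagnoses
    ozone-production regimes from HCHO/NO2 ratios, and propagates trends into
    population exposure, PM2.5-attributable premature mortality, and a
    log-ratio decomposition of mortality drivers. Includes a synthetic-data
    generator with known ground truth so every stage is testable by parameter
    recovery without any satellite download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
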