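# tropicair

Trends in air pollution over fast-growing tropical cities, from satellite
column observations to health burden — as a tested, reusable R pipeline.

Many tropical cities that will be megacities by 2100 have no routine surface
air-quality monitoring. Multi-year satellite records of tropospheric NO2
columns, total-column HCHO and NH3, and aerosol optical depth (AOD) are the
only consistent observations available. `tropicair` implements the analysis
chain that turns pixel-level column observations into city-scale findings,
for atmospheric scientists and exposure/health modellers:

1. **City sampling** — monthly means of QA-passing pixel centers inside the
   city polygon, metrically buffered by the instrument pixel size for small
   cities; months with fewer than 5 pixels are flagged and excluded.
2. **Reactive-NMVOC proxy** — the HCHO background (methane oxidation) is
   fitted over a paired remote-ocean box and subtracted, leaving the
   reactive component attributable to local VOC sources.
3. **Seasonal trend fits** — `f(t) = mu0 + beta*t + A*sin(2*pi*t + phi)` by
   least squares on retained months, with 95% CIs, a coverage gate (>50
   months for 2005-2018 records), and relative trends in % of the
   record-start baseline per year. Annual series use the Theil-Sen median
   estimator with rank-based CIs.
4. **Source partitioning** — per-year 75th-percentile split of monthly means
   into biomass-burning excess and anthropogenic (below-percentile)
   components, trended separately and checked against satellite burned
   fraction.
5. **Ozone regime** — annual HCHO/NO2 column ratios against the
   NOx-/VOC-sensitivity threshold of 2, with a Theil-Sen projected crossing
   year.
6. **Exposure and mortality** — population exposure E = N * C (annual mean of
   the fitted proxy), anchor-scaled absolute PM2.5, attributable fraction
   AF = 1 - 1/RR(c) with a pluggable concentration-response table, premature
   deaths with CIs, and an exact log-ratio decomposition of the mortality
   change into PM2.5, population and baseline-mortality drivers.

A synthetic-data generator with known ground truth stands in for the
satellite records, so the whole chain is testable by parameter recovery
without downloading anything; real pixel tables in the same CSV layout
(`lon, lat, time, value, qa_pass`) use the same functions unchanged.

## Worked example

```r
library(tropicair)

reg <- rect_region("lagosish", 0, 0.3, 0, 0.3, buffer_km = 6.5)
sc  <- synthetic_scenario(baseline_column = 2e15, rel_trend = 0.044,
                          seasonal_amplitude = 0.2, seasonal_phase = 2,
                          noise_sd = 0.08, gap_prob = 0.1,
                          years = c(2005, 2018), seed = 7)
ser <- sample_region(generate_pixels(sc, reg), reg, species = "NO2")
fit_seasonal_trend(ser)
#> <seasonal_trend_fit> lagosish NO2: baseline 2.012e+15, trend +8.722e+13 / yr (4.33% / yr), significant at 95% CI
```

The fitted relative trend (4.33 % a^-1, 95% CI excluding zero) recovers the
simulated 4.4 % a^-1 growth within its uncertainty from a record with 8%
noise and 10% gap months. The full workflow — simulation, sampling, fits,
partitioning, exposure, mortality, summary — is organised as numbered
drivers:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_sample_series.R
Rscript analysis/03_trends.R
Rscript analysis/04_sources.R
Rscript analysis/05_exposure_health.R
Rscript analysis/06_summary.R
```

Each prints what it found and writes tidy CSVs under `results/run/`; the
last writes `results/summary_*.csv`. On the bundled three-city scenario the
run reports, e.g., a significant +3.2 % a^-1 all-data NO2 trend for the
burning-influenced city driven by a +4.2 % a^-1 anthropogenic component
against a declining burning excess (consistent with its declining burned
fraction), a -1.9 % a^-1 NO2 decline in the policy-controlled city, an
"insufficient coverage" flag for the cloud-gapped city, and a +49% rise in
PM2.5-attributable premature deaths (11,332 in 2005 to 16,881 in 2018)
decomposed into PM2.5, population and baseline-mortality log-ratios.

Note the bundled concentration-response table is synthetic (see
`vignettes/tropicair-methods.Rmd`); supply real coefficients via
`read_crf_csv()` for quantitative mortality work.

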