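---
title: "Methods: city-scale satellite air-quality trends, sources and health burden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: city-scale satellite air-quality trends, sources and health burden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tropicair)
```

## The problem

Fast-growing tropical cities mostly lack routine surface monitoring of air
pollution, but space-based spectrometers and radiometers provide consistent
multi-year records of tropospheric NO~2~ columns, total-column HCHO and
NH~3~ (molecules cm^-2^), and aerosol optical depth (AOD, unitless). This
package implements the full chain from pixel-level column observations to
city-scale conclusions: monthly-mean sampling over city polygons, isolation
of the reactive-NMVOC component of HCHO, seasonal-trend fitting with
significance, partitioning of trends into biomass-burning and anthropogenic
components, ozone-regime diagnostics, population-exposure trends, and
PM~2.5~-attributable premature mortality with a factor decomposition.

Because the full satellite records are bulky and external, the package ships
a synthetic-data generator with known ground truth. Every stage is exercised
and validated by parameter recovery on synthetic cities; real pixel tables in
the same CSV layout (`lon, lat, time, value, qa_pass`) drop into the same
functions unchanged.

## City sampling

A pixel contributes to the monthly mean of a region when its QA flag passes
and its footprint center lies in the buffered polygon. Conventions:

* **Buffered membership.** The sampling domain is the polygon union all
  points within `buffer_km` of its boundary, with geodesic (WGS-84)
  distances via `geosphere::dist2Line()`. Degree-based dilation would
  shrink with latitude; a metric buffer does not. The boundary is
  *inclusive*: at `buffer_km = 0` a pixel center exactly on the edge
  counts as inside (within a 1 m numerical tolerance). Small-city domains
  use buffers equal to the instrument pixel size: 6.5 km (OMI, MODIS) or
  10 km (IASI).
* **Retention.** A month is retained only with >= 5 QA-passing pixels;
  sparser months stay in the table, flagged, and never enter a fit. A mean
  over zero pixels is absent, never zero. Months are calendar months in
  UTC; a pixel belongs to the month of its timestamp.
* **Background correction (HCHO).** The methane-oxidation background is
  estimated over a remote ocean box spanning the same latitude range as the
  city (a mismatch beyond 1 degree is warned about). The seasonal-trend model is
  fit to the ocean series — with the same retained-month rules as cities —
  and its *fitted* values are subtracted from the city means month by
  month. Negative residuals are expected near the detection limit; they are
  kept and flagged, never clipped.
* **Rural reference (biogenic check).** A 0.2 degree x 0.2 degree box whose center
  is placed 50-100 km from the city centroid at an explicit bearing; the
  annulus bound is enforced, the bearing is the caller's choice since any
  azimuth is a priori acceptable.
* **Gridded annual fields.** Burned fraction uses the overlap-area-weighted
  mean of cells intersecting the buffered domain; emission totals use the
  overlap-fraction-weighted sum. Overlap fractions are evaluated on a 6x6
  lattice of points per cell — exact for fully inside/outside cells, and at
  0.25 degree cells a <=3% area granularity otherwise, negligible against the
  fields' own uncertainty.

## Trend models

Monthly series are fit with

$$f(t) = \mu_0 + \beta t + A\sin(2\pi t + \phi), \qquad t = \text{years since record start},$$

which accounts for the pronounced tropical seasonality (photochemistry,
monsoon dynamics, burning seasons) before reading off a linear trend.
Rewriting the sinusoid as $a\sin 2\pi t + b\cos 2\pi t$ makes the model
linear in $(\mu_0, \beta, a, b)$, so it is estimated by ordinary least
squares on retained months — no iterative optimiser, hence no
initialisation or convergence tie-breaks. An optional semi-annual harmonic
(`harmonics = 2`) is available where one annual sinusoid is too rigid; the
default is the smallest model that captures the seasonality.

* **Confidence intervals.** Default is the t-based interval from the OLS
  parameter covariance; a year-block bootstrap (`ci_method = "bootstrap"`,
  200 resamples) is available for series with autocorrelated residuals. A
  trend is *significant* when the 95% interval excludes zero.
* **Coverage gate.** Fits are refused (an explicit "insufficient coverage"
  result, not an error) unless retained months exceed the gate: > 50 months
  for a 2005-2018 monthly record (OMI/MODIS), > 40 for 2008-2018 (IASI),
  both about 30% coverage. Refused cities stay in all tables, flagged.
* **Relative trends** are `100 * beta / mu0`, percent of the *fitted* value at
  record start per year. The fitted baseline is robust to missing early
  months, unlike the first observed value.
* **Annual series** (partition components, burned fraction, emissions,
  regime ratios) are trended with the Theil-Sen estimator — the median of
  all pairwise slopes, with the classical rank-based 95% interval on the
  ordered slopes — which damps the influence of interannual variability.
  Monthly all-data trends use the seasonal-fit CI; annualised partitions
  use Theil-Sen CIs.
* **Ozone regime.** Annual HCHO/NO~2~ ratios over months retained in both
  series; years with non-positive NO~2~ means are omitted with a warning.
  Ratios above 2 indicate NO~x~-sensitive ozone formation. The
  threshold-crossing year is where the Theil-Sen line through the annual
  ratios meets the threshold, reported only within a 30-year extrapolation
  horizon; a line flat at exactly the threshold reports the first year and
  a degeneracy flag.

## Source partitioning

Within each calendar year with >= 8 retained months, the 75th percentile of
the monthly means is computed with the linear-interpolation quantile
(type 7, R's default). Months **strictly above** the percentile are
biomass-burning candidates; months at or below it (ties classify as
anthropogenic) form the nonbiomass-burning data, summarised by their annual
mean. The burning excess of an above-percentile, burning-season month is its
value minus that year's anthropogenic mean, so excess + anthropogenic mean
reconstructs the original value (exactly, up to one floating-point rounding
of the stored difference). With 12 distinct values, exactly 3 months lie
strictly above the type-7 percentile.

Burning seasons default to the four regional calendars (December-March in
Northern Africa, July-November in Southern Africa, January-April in South and
continental Southeast Asia, August-October in equatorial Southeast Asia) and
are user-editable. A city counts as substantially burning-influenced when all
above-percentile months fall inside the season in at least half of the
partitioned years. Above-percentile spikes *outside* the season fail that
check and are excluded from the burning series.

Annual burning values are per-year means of the monthly excesses (the
season-aggregated alternative weights months unequally across years with
different gap patterns). Directional consistency with burned fraction is
`consistent`/`opposite` only when both Theil-Sen intervals exclude zero, else
`indeterminate`.

## Exposure and health burden

* **Exposure** is $E = N \cdot C$: population times the annual mean of the
  fitted proxy curve (AOD for PM~2.5~, NO~2~ column for NO~2~). Relative
  exposure trends are linear in the start value over the 13-year 2005-2018
  interval; to first order they are the *sum* of the population and
  concentration trends, and the multiplicative cross-term (about 0.007
  percentage points per year at 1.3 + 0.5) is reported separately.
* **Absolute PM~2.5~** is anchored: `PM2.5(y) = anchor * C(y)/C(anchor_year)`
  with the anchor a modelled annual-mean concentration (ug m^-3) at the
  record midpoint (2012). Scaling is exact: a 10% smaller anchor gives
  exactly 10% smaller concentrations everywhere.
* **Mortality.** Attributable fraction AF = 1 - 1/RR(c) with log-linear
  RR(c) = exp(beta(c) (c - c0)) above the counterfactual c0 and 1 below it;
  beta(c) is interpolated from a concentration-indexed table with central,
  low and high rows that drive the CI. Deaths = population x over-14
  fraction x baseline all-cause rate x AF, summed over strata when several
  are supplied; the default synthetic demographics use a single >= 14
  stratum. **The bundled CRF table is synthetic** (an attenuating slope,
  flattening above 50 ug m^-3 where published risk models are most
  uncertain): the coefficients of the published meta-analytic model are not
  reproduced here, so absolute death counts with the default are
  illustrative. Supply a real coefficient table via `read_crf_csv()` for
  quantitative use.
* **Per-year averages** of mortality changes use the 14-year observing-period
  convention for 2005-2018 (180,000/14 = 12,857, quoted as 13,000 a^-1^),
  while interval trends divide by the 13 elapsed years; both lengths are
  explicit arguments, never inferred.
* **Decomposition.** For each factor (PM~2.5~ via AF, population including
  the over-14 share, baseline rate), the log-ratio of deaths with that
  factor held at start-year values (others at end-year) to all-end-year
  deaths. For the multiplicative single-stratum model the three log-ratios
  sum to ln(M_start/M_end) exactly; the suite checks this to 1e-12.
* City totals sum only cities whose AOD series passed the coverage gate.

## The synthetic generator: what it does and does not emulate

The generator's truth model is deliberately the fitting model — linear
relative trend plus one annual sinusoid, plus a burning-season excess with
its own trend — so recovery tests are exact: with no noise and no gaps the
fit recovers the relative trend and seasonal amplitude to better than 1e-6
relative error. Monthly noise is a single Gaussian perturbation of the
monthly mean (additive, as a fraction of baseline; a multiplicative mode
exists but is off by default), and pixel values scatter around the monthly
mean without changing it, so the series-level error model is exactly i.i.d.
normal and the nominal 95% CI calibration can be checked honestly: over 200
noisy replicates (10% noise, 20% gap months) coverage lands in the 93-97%
binomial band. Cloud gaps are months that emit fewer than 5 pixels;
quality-flagged pixels carry deliberately wrong values so any leakage into
means is caught.

It does **not** emulate: autocorrelated or heteroscedastic retrieval noise,
drifting instrument sensitivity, spatial gradients within the city, realistic
swath/orbit geometry, semi-annual or interannual (ENSO-type) variability, or
trend breakpoints. Passing recovery tests therefore demonstrates the
correctness of the estimators under their stated assumptions, not robustness
to every pathology of real retrievals; the bootstrap CI option and the
semi-annual harmonic are the first knobs to reach for with real data.

## Numerical and design choices

* Quantile convention type 7 and the tie rule (at-percentile months are
  anthropogenic) are explicit, documented and configurable, since the
  percentile rule is sensitive to both.
* Theil-Sen slope ties take the median convention (midpoint of central
  order statistics); duplicate years are an error, not averaged away.
* Point-in-polygon uses even-odd ray casting with the boundary resolved by
  geodesic distance, making membership monotone in `buffer_km`.
* Exposure years, anchor year, gates, burning calendars, CRF and quantile
  type all live in the run configuration; every stochastic operation takes
  an explicit integer seed recorded in output headers, and reruns are
  bit-identical.
* Problem sizes in the test suite (200 trend replicates, 1,000 Theil-Sen
  oracle instances, 100 partition/decomposition cases, a 3-city 14-year
  demo) were chosen so the whole suite exercises every guarantee in about a
  minute on a single core.

## Known limitations

Column-to-surface translation is a proxy (no NO~x~-lifetime or
free-tropospheric background corrections); emission comparisons accept any
georeferenced annual grid but no native inventory dialects; the NetCDF
variants of the interfaces are not provided (CSV and GeoJSON only); and the
health module estimates PM~2.5~-attributable all-cause mortality for a
single pollutant — NO~2~ mortality and morbidity endpoints are out of scope.
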