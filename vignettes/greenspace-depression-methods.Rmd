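---
title: "Methods: greenspace exposure metrics and their association with depressive symptoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: greenspace exposure metrics and their association with depressive symptoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(greenexp)
```

## The scientific question

Residential exposure to vegetation ("greenspace") and to combined water and
vegetated land cover ("blue-greenspace") has been linked to better mental
health, but the association in older adults is sensitive to *how* exposure is
measured: at what distance from the home, and in which season. `greenexp`
implements a complete measurement-and-analysis pipeline for this question:

1. **Exposure assessment.** Greenspace exposure is the arithmetic mean of
   rescaled NDVI over a circular buffer (radii 250, 500, 1,000, 2,000 m)
   centered at the residence, computed from a year of 16-day satellite
   composites (nominally 23 layers at 250 m resolution) and aggregated to
   monthly and annual windows. Blue-greenspace exposure is the proportion of
   buffer cells in a fine-resolution land-use/land-cover (LULC) raster whose
   class is water, public park, forest, or agriculture; it is time-invariant.
2. **Association analysis.** Depressive symptoms are defined by the 10-item
   CES-D screening scale binarized at a cutoff (score >= 4). Logistic
   regression relates the binary outcome to each exposure, unadjusted and
   adjusted for demographic, behavioral, medical and area-level covariates.
   Effects are reported as odds ratios per interquartile-range (IQR)
   increment of the exposure with 95% Wald intervals, overall, stratified by
   household income at the 2M KRW/month line, and month by month.
3. **Synthetic studies.** Because cohort data of this kind are private, the
   package generates complete synthetic studies — rasters, cohort, outcomes —
   with *known* true effects, so every stage can be validated end to end.

## The exposure model

### Raster geometry

Rasters are planar, meter-unit grids with square cells; row 1 is
northernmost and cell extents are half-open (left/top edges included). The
package performs no reprojection or datum transforms: inputs must already be
in a projected CRS so that buffer radii are Euclidean distances in meters.
This is deliberate — the study area determines the right projection, and
silently reprojecting would hide errors worse than the ones it fixes.

### NDVI rescaling

Raw NDVI lies in [-1, 1], with negative values over water, bare soil, built
surfaces and snow. Exposure uses `rescale_ndvi(v) = max(0, v)`: all
non-vegetated surfaces map to exactly zero and vegetated values keep their
scale. We rejected the affine alternative `(v + 1) / 2` because it assigns
water a "greenness" of 0.5, which contradicts the intended semantics of
zero meaning no vegetation. Rescaling is applied **per cell before
averaging**; the order matters only through the clamp, and clamping first
means a buffer containing a lake is not credited for the lake. Files store
NDVI at its native scale; rescaling is an analysis step, never an I/O step.

### Buffer membership

A cell belongs to a buffer when its **center** lies within the radius
(closed boundary). At the native 250 m resolution this gives the expected
discrete neighborhoods: a 250 m buffer at a cell center selects the focal
cell plus its four rook neighbors (5 cells), a 500 m buffer the 13-cell
disc with offset norm `i^2 + j^2 <= 4`. Exact-area fractional weighting is
out of scope; at these radii the center rule differs from area weighting by
less than the NDVI measurement noise. A degenerate buffer smaller than half
a cell falls back to the single containing cell so that every on-raster
residence receives an exposure. Buffer centers falling off the raster are an
error for the single-point operations, but the batch table-builder degrades
them to missing values with a warning, so one bad address does not abort a
cohort run.

### Temporal aggregation

A 16-day composite belongs to the calendar month containing its start date
(the labeling convention of 16-day vegetation-index products). Monthly
exposure is the mean of that month's composite buffer-means (typically two);
the annual exposure is by default the unweighted mean over *all* composites,
so months contributing three composites weigh slightly more. The
equal-weight-per-month alternative is available (`annual_weighting =
"month"`); when every month has the same number of composites the two
definitions coincide exactly, which the tests exploit as an invariant.

## The association model

For exposure \(x\) with analysis-sample interquartile range \(q\), the fitted
logistic model
\[
\operatorname{logit} P(\text{CES-D} \ge 4) = \beta_0 + \beta x + \gamma'z
\]
is reported as \(\mathrm{OR} = e^{\beta q}\) with 95% CI
\(e^{(\beta \pm 1.959964\,\mathrm{SE})\,q}\) and a two-sided Wald p-value.
Wald inference is used for both the interval and the test so the two can
never disagree about significance. The IQR uses linear interpolation between
order statistics at position \(1 + (n-1)p\) (quantile type 7); a SAS-style
empirical-distribution rule is available via `quantile_type = 2` and
perturbs ORs only through the scaling constant \(q\). The IQR is always
computed on the analysis sample of the model at hand, so income-stratum and
monthly models are scaled by their own exposure spread.

The adjusted covariate set comprises age group, sex, household income,
education, marital status, current smoking, alcohol use, physical activity,
chronic medical conditions (hypertension and dyslipidemia; diabetes can be
added with `include_diabetes`), and four continuous area-level covariates
(mean annual temperature, crime rate, population density, per capita park
area). Categorical covariates enter as treatment contrasts against fixed
reference levels (age 70-74, male, income <1M, at-most-high-school, married,
and "no" for the behaviors) — the modal or first category where the choice
was open; the chosen references are recorded in each result object.
Complete-case analysis is used: rows missing the outcome or any modeled
field are dropped, with counts reported. Physical activity is included in
the stratified models as well; a flag removes it for sensitivity checks.

### Numerical details

The likelihood is maximized by Newton/IRLS from a zero start. Newton steps
are solved by Cholesky factorization on a column-rescaled design (unit
column norms), which keeps the information matrix well conditioned when
covariates live on wildly different scales (population density is four
orders of magnitude larger than an exposure in [0, 1]). Convergence is
declared when the largest score component falls below 1e-8, the largest
coefficient update falls below 1e-10, or the log-likelihood plateaus
(relative change below 1e-11) — the last criterion is what terminates
quasi-separated fits, where an indicator covariate perfectly predicts a
small cell and its coefficient drifts toward infinity while the likelihood
stops moving. Such fits return a diagnostic count of fitted probabilities
pinned at 0/1; *complete* separation (every observation perfectly
predicted, no finite MLE) is an error, as are rank-deficient designs and
constant outcomes. Fewer than 10 cases in an analysis sample triggers a
small-sample warning rather than an error.

## The synthetic-data generator

The generator's purpose is statistical, not cartographic: it reproduces the
*structure* the analysis relies on — spatial autocorrelation at buffer
scale, seasonality, realistic covariate marginals, a logistic outcome with
a known effect — without attempting realistic geography.

**NDVI fields.** Spatial structure comes from box-smoothed white noise
(smoothing radius 2 cells = 500 m by default), min-max normalized to a
greenness propensity in [0, 1]. Seasonality has two components sharing one
sinusoid \(s(t) = 0.45 + 0.25 \sin(2\pi(\mathrm{doy} - 118)/365)\) (peak in
late July): the *level* \(s(t)\) scales all cells, and the *pattern* blends
two correlated propensity fields — a winter (evergreen) and a summer
(deciduous-augmented) pattern, correlation 0.6 by default — using the same
sinusoid as mixing weight. The two-pattern construction mirrors a mixed
evergreen/deciduous landscape, where winter greenness is concentrated in
coniferous areas: it makes winter and summer exposures *correlated but not
proportional*. That distinction is essential for the monthly analysis: if
every month's exposure were a scalar multiple of one spatial field (as a
single-pattern generator produces), all twelve monthly models would estimate
the same per-IQR OR in expectation and no month-specific signal could exist
at all, let alone be recovered. Per-cell, per-composite Gaussian noise
(SD 0.05) represents retrieval error; values are clipped to [-1, 1]. With
the amplitude set to zero the pattern mixture is frozen, so a zero-noise,
zero-amplitude series is exactly constant across composites.

**Land cover.** An independent smoothed-noise field is thresholded at the
quantiles implied by the requested class proportions (defaults: water 5%,
park 8%, forest 18%, agriculture 9%, urban 55%, bare 5% — 40% blue-green,
an urban-dominated landscape), which yields contiguous patches and hits the
requested shares to within a cell. The synthetic LULC grid uses 20 m cells
rather than the 1 m of real national products: blue-green *proportions* over
250-2,000 m buffers are already stable at 20 m, and a 1 m grid over a
15 km x 15 km region would be three orders of magnitude larger for no
statistical gain.

**Cohort.** The default cohort has n = 617 members aged 60-84 with
covariates drawn independently from marginals typical of an urban Korean
outpatient cohort of that size (46.2% female; 83.5% married; income
distributed 22.7/25.9/20.8/20.9/9.7% across the five bands; 54.9%
hypertensive; area covariates Normal with population density
8711 ± 7169 /km², crime 26.9 ± 1.7 /1000, park area 8.3 ± 0.6 m²/person,
temperature 13.1 ± 0.7 °C, the first three truncated at zero by
resampling). Coordinates are uniform over the raster interior with a margin
of the largest radius, so every buffer is fully on-raster. Covariates are
independent of location and of each other by default — the generator
emulates *no confounding* unless asked (`income_confounding` adds a
low-income log-odds shift), which is what makes unadjusted and adjusted
estimates comparable in calibration runs.

**Outcomes.** The designated causal exposure (default: annual NDVI at
250 m) enters a logistic model with slope \(\log(\mathrm{OR}^\*)/q\), where
\(\mathrm{OR}^\*\) is the configured true odds ratio per IQR (default 0.67,
a plausible adjusted effect size for this literature) and \(q\) the realized
cohort IQR; the intercept is calibrated by root-finding so the mean outcome
probability equals the target prevalence. The default baseline prevalence is
0.25 — a typical positive-screen rate for elderly CES-D samples; the
specific cohort this design emulates did not publish its case count, so
this is a design choice of the generator. A per-stratum effect
(`true_or_per_iqr = c(low = , high = )`) injects different ORs in the two
income strata. CES-D scores are drawn uniformly within the depressed
(cutoff..10) or non-depressed (0..cutoff-1) range, so binarization at the
cutoff inverts generation exactly; score-level realism is deliberately out
of scope since only the binary outcome is analyzed.

**What passing tests do and do not show.** The generator's cohorts have
independent covariates, stationary smooth fields, no cloud/QA artifacts, no
spatially clustered settlement patterns, and exposure-outcome links that are
exactly logistic. Validation against it therefore demonstrates correctness
of the *computations* (zonal statistics, aggregation, model fitting,
scaling) and calibration of the *inference under the assumed model* — not
robustness to confounding, exposure misclassification, or model
misspecification in real data.

## Validation design

The test suite validates the pipeline at these problem sizes, chosen to give
tight Monte-Carlo bounds while keeping a full run in minutes:

- **Zonal oracle.** 200 random grids (up to 50 x 50 cells, cell sizes
  50-500 m) with random centers, radii and nodata patterns: buffer
  membership, buffer means and blue-green proportions must match an
  exhaustive every-cell oracle exactly, alongside the hand-derived 5-cell /
  13-cell neighborhoods and worked means.
- **Closed forms.** 50 random 2 x 2 tables: fitted slope within 1e-6 of
  `log(ad/bc)` and Wald SE within 1e-4 of `sqrt(1/a + 1/b + 1/c + 1/d)`.
- **Recovery.** 200 replicate studies, n = 2000, true OR 0.67: mean
  recovered adjusted OR within [0.64, 0.70] and CI coverage within
  [0.92, 0.98].
- **Null calibration.** 500 replicates at the default study size (n = 617),
  true OR 1: rejection rate at the 0.05 level within [0.03, 0.07].
- **Effect modification.** 100 replicates, n = 2000, true OR 0.5 in the
  low-income stratum and 1.0 in the high: significance in >= 80% of
  low-stratum fits and <= 10% of high-stratum fits.
- **Seasonal pattern.** 100 replicates with a January-NDVI causal exposure
  (true OR 0.6): the month with the minimum estimated OR falls in
  December-March in >= 70% of replicates.
- **Determinism.** Fixed seeds give byte-identical files end to end; the
  algebraic invariants (clamp idempotence and monotonicity, buffer nesting,
  per-IQR scale invariance, stratum partition, annual/monthly commutation)
  hold over randomized cases.

## Known limitations

- Esri ASCII grids are the supported raster format; GeoTIFF inputs must be
  converted upstream.
- Cell membership is by center, not fractional area; at radii below half a
  cell the buffer degenerates to the containing cell.
- No spatial autocorrelation adjustment in the regression: residential
  clustering would understate standard errors in real data.
- No multiple-testing correction across buffers or months, matching common
  practice in this literature; the monthly series should be read as a
  pattern, not twelve independent hypotheses.
- Monthly models reuse the annual adjustment set, including annual mean
  temperature; month-specific temperature adjustment is not implemented.
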