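# greenexp

Residential greenspace exposure metrics and their association with
depressive symptoms in older adults.

## What it does and for whom

`greenexp` is an R package for environmental-epidemiology analyses that ask
whether living near greenery is associated with lower depression risk — and
how the answer depends on the *spatial* scale (buffer radius) and *temporal*
window (month vs. year) at which exposure is measured. It is aimed at
researchers who have (or want to simulate) three ingredients:

- a year of satellite NDVI composites (16-day cadence, ~250 m cells),
- a categorical land-use/land-cover raster with a declared set of
  blue-green classes (water, public parks, forests, agriculture),
- a cohort table with residential coordinates, CES-D-10 depression scores
  and covariates.

The package computes, for each participant and each circular buffer of
radius *r* ∈ {250, 500, 1000, 2000} m around the residence:

- **greenspace exposure**: the arithmetic buffer mean of rescaled NDVI,
  `max(0, NDVI)` per cell, aggregated to monthly and annual windows;
- **blue-greenspace exposure**: the proportion of buffer cells whose
  land-cover class is blue-green (a number in [0, 1]).

It then fits simple and multiple logistic regressions of the binary outcome
CES-D ≥ 4 on each exposure and reports the **odds ratio per
interquartile-range (IQR) increment**,

OR = exp(β·IQR),  95% CI = exp((β ± 1.959964·SE)·IQR),

with two-sided Wald p-values — overall, stratified by household income at
the 2M KRW/month line, and month by month. A fully seeded synthetic-data
module generates complete studies (seasonal autocorrelated NDVI fields,
patchy land cover, a realistic cohort, logistic outcomes with known true
ORs) so the entire pipeline is testable without any private data. The
methods vignette (`vignettes/greenspace-depression-methods.Rmd`) documents
the models, defaults and design decisions.

## Worked example

Simulate a default study (n = 617, 23 composites, a true adjusted OR of
0.67 per IQR injected on annual NDVI at 250 m) and analyze it:

```r
library(greenexp)

cfg   <- sim_config(seed = 7)
study <- gen_study(cfg)
spec  <- model_spec()          # CES-D cutoff 4, full adjustment set

run_association(study$participants, study$exposures, spec,
                metric = "ndvi", buffer_m = 250, window = "annual",
                adjusted = FALSE)
#> ndvi 250m [annual, all, unadjusted]: OR/IQR 0.683 (0.543-0.861), p=0.001224, n=617 (173 cases)

run_association(study$participants, study$exposures, spec,
                metric = "ndvi", buffer_m = 250, window = "annual",
                adjusted = TRUE)
#> ndvi 250m [annual, all, adjusted]: OR/IQR 0.672 (0.530-0.852), p=0.001015, n=617 (173 cases)

run_association(study$participants, study$exposures, spec,
                metric = "bluegreen", buffer_m = 250, window = "static",
                adjusted = TRUE)
#> bluegreen 250m [static, all, adjusted]: OR/IQR 1.075 (0.787-1.467), p=0.6489, n=617 (173 cases)
```

Reading the output: an IQR increase in annual 250 m greenspace is
associated with 33% lower odds of depressive symptoms (adjusted OR 0.672,
CI excluding 1 — and close to the injected truth of 0.67). The
blue-greenspace OR is near 1 because this simulation injected no effect on
land-cover exposure; it tracks NDVI only through shared geography.

Income stratification uses each stratum's own IQR:

```r
strata <- stratify_income(study$participants)
run_association(strata$low, study$exposures, spec, "ndvi", 250, "annual",
                stratum = "low_income")
#> ndvi 250m [annual, low_income, adjusted]: OR/IQR 0.766 (0.537-1.091), p=0.139, n=290 (76 cases)
```

The same analyses run as a file-based pipeline (`cmd_simulate` →
`cmd_exposure` → `cmd_associate` → `cmd_report`), driven by a
`pipeline_config()` or the thin CLI wrapper in `inst/cli/greenexp.R`; the
stages communicate only through documented CSV/ASC/JSON files and rerunning
them with the same seed reproduces every output byte for byte.

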