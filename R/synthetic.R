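# Seed offsets keep the generators' RNG streams independent of call order,
# so each component is reproducible on its own under one study seed.
SEED_NDVI <- 101L
SEED_LULC <- 202L
SEED_COHORT <- 303L
SEED_OUTCOME <- 404L

#' Configuration for a synthetic study
#'
#' Bundles every knob of the synthetic-data generators: raster geometry, the
#' seasonal NDVI model, the land-cover mosaic, the cohort size and covariate
#' marginals, and the outcome model (true odds ratio per IQR of a designated
#' causal exposure, baseline prevalence, optional income confounding).
#'
#' The NDVI model combines a seasonal level
#' `s(t) = ndvi_mid + seasonal_amplitude * sin(2*pi*(doy - seasonal_phase)/365)`
#' with a spatial greenness pattern that itself shifts with season: two
#' correlated smoothed-noise fields represent the winter (evergreen) and
#' summer (deciduous-augmented) greenness patterns and are blended by the same
#' sinusoid, so winter and summer composites share structure (correlation
#' about `season_pattern_cor`) without being proportional. Cell values are
#' `clip(s(t) * pattern + noise, -1, 1)`.
#'
#' @param seed integer master seed; fixed seed gives bit-identical studies.
#' @param origin_x,origin_y,cell_size,n_rows,n_cols NDVI grid geometry
#'   (meters; 250 m cells by default, 60 x 60 cells = 15 km x 15 km).
#' @param n_composites number of 16-day composites (default 23, a full year).
#' @param start_date date of the first composite.
#' @param ndvi_mid annual mean level of the seasonal sinusoid (NDVI units).
#' @param seasonal_amplitude amplitude of the sinusoid (NDVI units); 0 removes
#'   all seasonality (composites identical when `noise_sd = 0`).
#' @param seasonal_phase phase in day-of-year units (default 118: seasonal
#'   peak in late July).
#' @param season_pattern_cor correlation between the winter and summer spatial
#'   greenness patterns (default 0.6, a mixed evergreen/deciduous landscape).
#' @param spatial_smoothing_radius box-smoothing radius in NDVI cells.
#' @param noise_sd per-cell, per-composite noise SD (NDVI units).
#' @param lulc_cell_size land-cover cell size in meters (default 20 m).
#' @param lulc_smoothing_radius box-smoothing radius in LULC cells for the
#'   patch field.
#' @param class_props named class proportions summing to 1 over
#'   water/park/forest/agriculture/urban/bare (defaults give 40% blue-green).
#' @param n_participants cohort size (default 617).
#' @param missing_cesd_rate fraction of subjects with missing CES-D scores.
#' @param cesd_cutoff cutoff consistent with the analysis (default 4).
#' @param true_or_per_iqr target odds ratio per population-IQR of the causal
#'   exposure; either a scalar or `c(low = , high = )` for income-stratum-
#'   specific effects.
#' @param baseline_prevalence marginal outcome prevalence the intercept is
#'   calibrated to (default 0.25).
#' @param causal_metric,causal_buffer,causal_window the designated causal
#'   exposure (default annual NDVI at 250 m).
#' @param income_confounding additive log-odds shift for low-income subjects
#'   (default 0 = no confounding).
#' @param radii,windows,metrics which exposures [gen_study] computes.
#' @param annual_weighting `"composite"` or `"month"`.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       origin_x = 0, origin_y = 15000, cell_size = 250,
                       n_rows = 60, n_cols = 60,
                       n_composites = 23L, start_date = as.Date("2021-01-01"),
                       ndvi_mid = 0.45, seasonal_amplitude = 0.25,
                       seasonal_phase = 118, season_pattern_cor = 0.6,
                       spatial_smoothing_radius = 2L, noise_sd = 0.05,
                       lulc_cell_size = 20, lulc_smoothing_radius = 15L,
                       class_props = c(water = 0.05, park = 0.08, forest = 0.18,
                                       agriculture = 0.09, urban = 0.55,
                                       bare = 0.05),
                       n_participants = 617L, missing_cesd_rate = 0,
                       cesd_cutoff = 4L,
                       true_or_per_iqr = 0.67, baseline_prevalence = 0.25,
                       causal_metric = "ndvi", causal_buffer = 250,
                       causal_window = "annual",
                       income_confounding = 0,
                       radii = c(250, 500, 1000, 2000),
                       windows = c("annual", "monthly"),
                       metrics = c("ndvi", "bluegreen"),
                       annual_weighting = "composite") {
  stopifnot(abs(sum(class_props) - 1) < 1e-8,
            baseline_prevalence > 0, baseline_prevalence < 1,
            all(true_or_per_iqr > 0), n_participants >= 1,
            missing_cesd_rate >= 0, missing_cesd_rate < 1,
            season_pattern_cor >= -1, season_pattern_cor <= 1)
  if (length(true_or_per_iqr) > 1L &&
      !setequal(names(true_or_per_iqr), c("low", "high"))) {
    stop("per-stratum true_or_per_iqr must be named c(low = , high = )",
         call. = FALSE)
  }
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "sim_config")
}

# Table-1-style covariate marginals for the synthetic cohort (counts / 617)
cohort_marginals <- list(
  age_group = c("60-64" = 34, "65-69" = 77, "70-74" = 249, "75-79" = 202,
                "80-84" = 55) / 617,
  sex = c(male = 332, female = 285) / 617,
  income = c("<1M" = 140, "1-2M" = 160, "2-3M" = 128, "3-5M" = 129,
             ">=5M" = 60) / 617,
  education = c("<=high-school" = 296, ">high-school" = 321) / 617,
  marital = c(married = 515, widowed = 89, divorced = 12, never = 1) / 617,
  smoking = c(no = 381, yes = 236) / 617,
  alcohol = c(no = 400, yes = 217) / 617,
  physical_activity = c(no = 370, yes = 247) / 617,
  hypertension = 339 / 617,
  dyslipidemia = 338 / 617,
  diabetes = 142 / 617,
  population_density = c(mean = 8711.38, sd = 7169.0),
  crime_rate = c(mean = 26.93, sd = 1.7),
  park_area_pc = c(mean = 8.27, sd = 0.6),
  mean_temp = c(mean = 13.14, sd = 0.7)
)

# exact box (moving-average) smoothing via a summed-area table;
# window truncated at the edges, normalized by the actual cell count
box_smooth <- function(m, radius) {
  if (radius <= 0) return(m)
  nr <- nrow(m); nc <- ncol(m)
  S <- apply(apply(m, 2L, cumsum), 1L, cumsum)  # S is nc x nr after t
  S <- t(S)
  S <- rbind(0, cbind(0, S))
  r1 <- pmax(seq_len(nr) - radius, 1L); r2 <- pmin(seq_len(nr) + radius, nr)
  c1 <- pmax(seq_len(nc) - radius, 1L); c2 <- pmin(seq_len(nc) + radius, nc)
  sums <- S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  counts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sums / counts
}

norm01 <- function(m) {
  rng <- range(m)
  if (rng[2] == rng[1]) return(m * 0 + 0.5)
  (m - rng[1]) / (rng[2] - rng[1])
}

day_of_year <- function(dates) as.integer(format(dates, "%j"))

#' Generate a seasonal NDVI composite series
#'
#' Builds two correlated spatially smoothed greenness patterns (winter and
#' summer), blends them with a seasonal sinusoid, scales by the seasonal
#' level, adds per-composite noise, and clips to `[-1, 1]`. Deterministic
#' given `config$seed`. Spatial means are lowest in winter and highest in
#' midsummer.
#'
#' @param config a [sim_config].
#' @return a [composite_series].
#' @export
gen_ndvi_series <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + SEED_NDVI)
  nr <- config$n_rows; nc <- config$n_cols
  z_w <- matrix(stats::rnorm(nr * nc), nr, nc)
  z_i <- matrix(stats::rnorm(nr * nc), nr, nc)
  rho <- config$season_pattern_cor
  z_s <- rho * z_w + sqrt(1 - rho^2) * z_i
  g_w <- norm01(box_smooth(z_w, config$spatial_smoothing_radius))
  g_s <- norm01(box_smooth(z_s, config$spatial_smoothing_radius))
  dates <- config$start_date + 16L * (seq_len(config$n_composites) - 1L)
  doy <- day_of_year(dates)
  sinv <- sin(2 * pi * (doy - config$seasonal_phase) / 365)
  s_level <- config$ndvi_mid + config$seasonal_amplitude * sinv
  # pattern blend follows the same sinusoid; frozen when amplitude is 0 so
  # zero-amplitude series are truly season-free
  w_mix <- if (config$seasonal_amplitude > 0) 0.5 + 0.5 * sinv else rep(0.5, length(doy))
  grids <- vector("list", length(dates))
  for (k in seq_along(dates)) {
    pattern <- (1 - w_mix[k]) * g_w + w_mix[k] * g_s
    vals <- s_level[k] * pattern
    if (config$noise_sd > 0) {
      vals <- vals + matrix(stats::rnorm(nr * nc, sd = config$noise_sd), nr, nc)
    }
    vals <- pmin(pmax(vals, -1), 1)
    grids[[k]] <- raster_grid(vals, config$origin_x, config$origin_y,
                              config$cell_size)
  }
  composite_series(dates, grids)
}

#' Generate a patchy land-cover raster and its legend
#'
#' Thresholds an independent smoothed-noise field at the quantiles implied by
#' the requested class proportions, producing contiguous patches whose global
#' shares match the request to within a cell. The land-cover grid covers the
#' NDVI grid extent at `lulc_cell_size` resolution. Water, park, forest and
#' agriculture are marked blue-green in the legend.
#'
#' @param config a [sim_config].
#' @return list with elements `grid` ([raster_grid]) and `legend`
#'   ([lulc_legend]).
#' @export
gen_lulc <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + SEED_LULC)
  width <- config$n_cols * config$cell_size
  height <- config$n_rows * config$cell_size
  nr <- as.integer(ceiling(height / config$lulc_cell_size))
  nc <- as.integer(ceiling(width / config$lulc_cell_size))
  field <- box_smooth(matrix(stats::rnorm(nr * nc), nr, nc),
                      config$lulc_smoothing_radius)
  props <- config$class_props
  codes <- stats::setNames(10L * seq_along(props), names(props))
  # quantile thresholding: rank cells, cut at cumulative proportions
  rk <- rank(field, ties.method = "first")
  cuts <- cumsum(props) * length(rk)
  cls <- findInterval(rk - 0.5, c(0, cuts), rightmost.closed = TRUE)
  vals <- matrix(codes[cls], nr, nc)
  legend <- lulc_legend(codes,
                        intersect(c("water", "park", "forest", "agriculture"),
                                  names(props)[props > 0]))
  list(grid = raster_grid(vals, config$origin_x, config$origin_y,
                          config$lulc_cell_size),
       legend = legend)
}

sample_level <- function(n, probs) {
  factor(sample(names(probs), n, replace = TRUE, prob = probs),
         levels = names(probs))
}

rnorm_trunc0 <- function(n, mean, sd) {
  out <- stats::rnorm(n, mean, sd)
  while (any(out < 0)) {
    bad <- out < 0
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  out
}

#' Generate a synthetic cohort
#'
#' Draws residential coordinates uniformly over the NDVI grid interior (with a
#' margin of the largest buffer radius, so every buffer stays on-raster) and
#' covariates independently from realistic marginals for an urban Korean
#' cohort of adults aged 60-84: age-group, sex, household income, education,
#' marital status, smoking, alcohol, physical activity, chronic conditions,
#' and area-level covariates (population density, crime rate, per capita park
#' area, mean annual temperature; truncated at zero where relevant). CES-D is
#' left missing; [gen_outcomes] fills it.
#'
#' @param config a [sim_config].
#' @return participant data.frame.
#' @export
gen_participants <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + SEED_COHORT)
  n <- config$n_participants
  margin <- max(config$radii, config$causal_buffer)
  xmin <- config$origin_x + margin
  xmax <- config$origin_x + config$n_cols * config$cell_size - margin
  ymax <- config$origin_y - margin
  ymin <- config$origin_y - config$n_rows * config$cell_size + margin
  if (xmax <= xmin || ymax <= ymin) {
    stop("grid too small for the largest buffer radius: no interior remains",
         call. = FALSE)
  }
  mg <- cohort_marginals
  df <- data.frame(
    id = sprintf("P%04d", seq_len(n)),
    x = stats::runif(n, xmin, xmax),
    y = stats::runif(n, ymin, ymax),
    cesd = NA_integer_,
    age_group = sample_level(n, mg$age_group),
    sex = sample_level(n, mg$sex),
    income = sample_level(n, mg$income),
    education = sample_level(n, mg$education),
    marital = sample_level(n, mg$marital),
    smoking = sample_level(n, mg$smoking),
    alcohol = sample_level(n, mg$alcohol),
    physical_activity = sample_level(n, mg$physical_activity),
    hypertension = stats::runif(n) < mg$hypertension,
    dyslipidemia = stats::runif(n) < mg$dyslipidemia,
    diabetes = stats::runif(n) < mg$diabetes,
    population_density = rnorm_trunc0(n, mg$population_density["mean"],
                                      mg$population_density["sd"]),
    crime_rate = rnorm_trunc0(n, mg$crime_rate["mean"], mg$crime_rate["sd"]),
    park_area_pc = rnorm_trunc0(n, mg$park_area_pc["mean"],
                                mg$park_area_pc["sd"]),
    mean_temp = stats::rnorm(n, mg$mean_temp["mean"], mg$mean_temp["sd"]),
    stringsAsFactors = FALSE
  )
  df
}

#' Simulate depressive-symptom outcomes from a logistic model
#'
#' Draws a binary depression indicator from
#' `logit P(depressed) = beta0 + beta_e * x (+ confounding terms)` where `x`
#' is the designated causal exposure, `beta_e = log(true OR per IQR) / IQR`
#' with the IQR computed on the generated cohort, and `beta0` is calibrated by
#' root-finding so the mean probability equals `baseline_prevalence`. With a
#' per-stratum `true_or_per_iqr`, the effect and IQR are stratum-specific
#' (income below / at-or-above 2M KRW). CES-D scores are then drawn uniformly
#' from `{cutoff..10}` for depressed subjects and `{0..cutoff-1}` otherwise,
#' so binarizing at the cutoff inverts the generation exactly.
#'
#' @param participants cohort from [gen_participants].
#' @param exposures an `exposure_table` containing the causal exposure.
#' @param config a [sim_config].
#' @return list with `participants` (CES-D filled; `NA` for the configured
#'   missing fraction) and `truth` (a record of `beta0`, the per-stratum
#'   exposure coefficients, population IQRs, and implied odds ratios).
#' @export
gen_outcomes <- function(participants, exposures, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + SEED_OUTCOME)
  sel <- exposures$metric == config$causal_metric &
    exposures$buffer_m == config$causal_buffer &
    exposures$window == config$causal_window
  if (!any(sel)) {
    stop(sprintf("causal exposure %s/%g/%s not present in the exposure table",
                 config$causal_metric, config$causal_buffer,
                 config$causal_window), call. = FALSE)
  }
  exp_sub <- exposures[sel, ]
  x <- exp_sub$value[match(as.character(participants$id),
                           exp_sub$participant_id)]
  if (anyNA(x)) {
    stop("causal exposure missing for some participants; cannot simulate outcomes",
         call. = FALSE)
  }
  or_cfg <- config$true_or_per_iqr
  low <- as.character(participants$income) %in% c("<1M", "1-2M")
  if (length(or_cfg) == 1L) {
    iqr_pop <- iqr(x)
    if (iqr_pop == 0 && or_cfg != 1) {
      stop("causal exposure is degenerate (IQR = 0) with a nonzero effect",
           call. = FALSE)
    }
    beta_e <- if (or_cfg == 1) 0 else log(or_cfg) / iqr_pop
    eta_x <- beta_e * x
    truth_beta <- c(all = beta_e)
    truth_iqr <- c(all = iqr_pop)
    truth_or <- c(all = unname(or_cfg))
  } else {
    iqr_low <- iqr(x[low]); iqr_high <- iqr(x[!low])
    if ((iqr_low == 0 && or_cfg[["low"]] != 1) ||
        (iqr_high == 0 && or_cfg[["high"]] != 1)) {
      stop("causal exposure is degenerate (IQR = 0) in a stratum with a nonzero effect",
           call. = FALSE)
    }
    b_low <- if (or_cfg[["low"]] == 1) 0 else log(or_cfg[["low"]]) / iqr_low
    b_high <- if (or_cfg[["high"]] == 1) 0 else log(or_cfg[["high"]]) / iqr_high
    eta_x <- ifelse(low, b_low * x, b_high * x)
    truth_beta <- c(low = b_low, high = b_high)
    truth_iqr <- c(low = iqr_low, high = iqr_high)
    truth_or <- c(low = unname(or_cfg[["low"]]), high = unname(or_cfg[["high"]]))
  }
  eta_rest <- eta_x + config$income_confounding * as.numeric(low)
  f <- function(b0) mean(stats::plogis(b0 + eta_rest)) - config$baseline_prevalence
  beta0 <- stats::uniroot(f, c(-30, 30), tol = 1e-12)$root
  p_i <- stats::plogis(beta0 + eta_rest)
  depressed <- stats::rbinom(length(p_i), 1L, p_i)
  cutoff <- config$cesd_cutoff
  cesd <- ifelse(depressed == 1L,
                 sample(cutoff:10, length(p_i), replace = TRUE),
                 sample(0:(cutoff - 1L), length(p_i), replace = TRUE))
  if (config$missing_cesd_rate > 0) {
    miss <- stats::runif(length(cesd)) < config$missing_cesd_rate
    cesd[miss] <- NA_integer_
  }
  participants$cesd <- as.integer(cesd)
  truth <- list(
    true_or_per_iqr = truth_or,
    beta_exposure = truth_beta,
    iqr_pop = truth_iqr,
    implied_or = exp(truth_beta * truth_iqr),
    beta0 = beta0,
    baseline_prevalence = config$baseline_prevalence,
    causal_metric = config$causal_metric,
    causal_buffer = config$causal_buffer,
    causal_window = config$causal_window,
    income_confounding = config$income_confounding,
    n_depressed = sum(depressed)
  )
  list(participants = participants, truth = truth)
}

#' Generate a complete synthetic study
#'
#' Composes the raster, cohort and outcome generators and the exposure module
#' into one bundle: NDVI series and/or land-cover raster (per
#' `config$metrics`), the cohort with simulated CES-D scores, the full
#' exposure table, and a truth record of the injected effect.
#'
#' @param config a [sim_config].
#' @return list with `config`, `series`, `lulc`, `legend`, `participants`,
#'   `exposures`, `truth`.
#' @export
gen_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  need_ndvi <- "ndvi" %in% config$metrics || config$causal_metric == "ndvi"
  need_lulc <- "bluegreen" %in% config$metrics || config$causal_metric == "bluegreen"
  series <- if (need_ndvi) gen_ndvi_series(config) else NULL
  lulc <- legend <- NULL
  if (need_lulc) {
    lg <- gen_lulc(config)
    lulc <- lg$grid
    legend <- lg$legend
  }
  participants <- gen_participants(config)
  windows <- config$windows
  if (config$causal_metric == "ndvi" &&
      !(config$causal_window %in% exposure_windows(windows))) {
    windows <- c(windows, config$causal_window)
  }
  radii <- sort(unique(c(config$radii, config$causal_buffer)))
  exposures <- build_exposure_table(participants, series = series, lulc = lulc,
                                    legend = legend, radii = radii,
                                    windows = windows,
                                    annual_weighting = config$annual_weighting)
  out <- gen_outcomes(participants, exposures, config)
  list(config = config, series = series, lulc = lulc, legend = legend,
       participants = out$participants, exposures = exposures,
       truth = out$truth)
}
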