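#' Pipeline configuration
#'
#' Collects the file paths and analysis switches the pipeline stages share.
#' Can be built from a YAML file (`pipeline_config("config.yml")`) or from
#' arguments. Unknown keys are rejected.
#'
#' @param path optional YAML file; its keys are merged under the defaults.
#' @param ... individual settings overriding the defaults: `manifest`,
#'   `lulc`, `participants` (input paths), `out_dir`, `radii`, `cutoff`,
#'   `include_physical_activity`, `include_diabetes`, `stratify`, `monthly`,
#'   `monthly_buffer`, `annual_weighting`, `quantile_type`, `seed`,
#'   `sim` (a [sim_config] or list of its arguments, for [cmd_simulate]).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  defaults <- list(
    manifest = NULL, lulc = NULL, participants = NULL,
    out_dir = ".", radii = c(250, 500, 1000, 2000),
    cutoff = 4L, include_physical_activity = TRUE, include_diabetes = FALSE,
    stratify = TRUE, monthly = TRUE, monthly_buffer = NULL,
    annual_weighting = "composite", quantile_type = 7L, seed = 1L,
    sim = NULL
  )
  overrides <- list(...)
  if (!is.null(path)) {
    from_file <- yaml::read_yaml(path)
    overrides <- utils::modifyList(from_file, overrides)
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    stop(sprintf("unknown pipeline setting(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, overrides)
  structure(cfg, class = "pipeline_config")
}

as_model_spec <- function(cfg) {
  model_spec(cutoff = cfg$cutoff,
             include_physical_activity = cfg$include_physical_activity,
             include_diabetes = cfg$include_diabetes,
             quantile_type = cfg$quantile_type)
}

#' Simulate a study and write its input files
#'
#' Runs [gen_study] and writes the standard input bundle to `out_dir`:
#' the NDVI composite rasters plus `ndvi_manifest.csv`, `lulc.asc`,
#' `legend.json`, `participants.csv`, and `truth.json` (the injected effect,
#' for scoring recovery).
#'
#' @param config a [pipeline_config]; its `sim` entry (a [sim_config] or a
#'   list of [sim_config] arguments) defines the study, with `seed` falling
#'   back to the pipeline seed.
#' @return list of written paths, invisibly; the study bundle as attribute
#'   `"study"`.
#' @export
cmd_simulate <- function(config) {
  sim <- config$sim
  if (is.null(sim)) sim <- list()
  if (!inherits(sim, "sim_config")) {
    if (is.null(sim$seed)) sim$seed <- config$seed
    sim <- do.call(sim_config, sim)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- gen_study(sim)
  paths <- list()
  if (!is.null(study$series)) {
    paths$manifest <- write_manifest(study$series, config$out_dir)
  }
  if (!is.null(study$lulc)) {
    paths$lulc <- file.path(config$out_dir, "lulc.asc")
    write_grid(study$lulc, paths$lulc)
    paths$legend <- file.path(config$out_dir, "legend.json")
    jsonlite::write_json(list(classes = as.list(study$legend$classes),
                              blue_green = study$legend$blue_green),
                         paths$legend, auto_unbox = TRUE)
  }
  paths$participants <- file.path(config$out_dir, "participants.csv")
  write_participants(study$participants, paths$participants)
  paths$truth <- file.path(config$out_dir, "truth.json")
  jsonlite::write_json(study$truth, paths$truth, auto_unbox = TRUE,
                       digits = I(17))
  message(sprintf("simulated study: %d participants, %d composites, seed %d",
                  nrow(study$participants),
                  if (is.null(study$series)) 0L else length(study$series),
                  sim$seed))
  out <- paths
  attr(out, "study") <- study
  invisible(out)
}

read_legend_json <- function(path) {
  lg <- jsonlite::read_json(path, simplifyVector = TRUE)
  lulc_legend(unlist(lg$classes), lg$blue_green)
}

#' Compute and write the exposure table
#'
#' Reads the composite manifest, land-cover raster and participant table
#' named in the config, builds the exposure table at the configured radii
#' (annual + monthly NDVI windows, static blue-greenspace), and writes
#' `exposure.csv` to `out_dir`. Logs timing and missing-value counts per
#' metric.
#'
#' @param config a [pipeline_config] with `participants` and at least one of
#'   `manifest` (NDVI) or `lulc` (+ `legend` JSON next to it) set.
#' @return the exposure CSV path, invisibly.
#' @export
cmd_exposure <- function(config) {
  if (is.null(config$participants)) {
    stop("config$participants is required", call. = FALSE)
  }
  participants <- read_participants(config$participants)
  series <- NULL
  if (!is.null(config$manifest)) {
    t0 <- proc.time()[["elapsed"]]
    series <- read_manifest(config$manifest)
    message(sprintf("read %d composites in %.1fs", length(series),
                    proc.time()[["elapsed"]] - t0))
  }
  lulc <- legend <- NULL
  if (!is.null(config$lulc)) {
    lulc <- read_grid(config$lulc, kind = "lulc")
    legend_path <- file.path(dirname(config$lulc), "legend.json")
    if (!file.exists(legend_path)) {
      stop(sprintf("legend file not found next to the LULC raster: %s",
                   legend_path), call. = FALSE)
    }
    legend <- read_legend_json(legend_path)
  }
  t0 <- proc.time()[["elapsed"]]
  exposures <- build_exposure_table(
    participants, series = series, lulc = lulc, legend = legend,
    radii = config$radii,
    windows = c("annual", "monthly"),
    annual_weighting = config$annual_weighting)
  for (m in unique(exposures$metric)) {
    n_miss <- sum(is.na(exposures$value[exposures$metric == m]))
    message(sprintf("%s exposures: %d rows, %d missing (%.1fs)", m,
                    sum(exposures$metric == m), n_miss,
                    proc.time()[["elapsed"]] - t0))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(config$out_dir, "exposure.csv")
  write_exposure_table(exposures, path)
  invisible(path)
}

#' Fit the association models and write results + report
#'
#' Reads the exposure table and participants, then fits, per radius:
#' unadjusted and adjusted models for annual NDVI and blue-greenspace
#' exposure; if `stratify` is on, adjusted models per income stratum; if
#' `monthly` is on, the 12-month adjusted NDVI series (at `monthly_buffer`,
#' default: every configured radius). Writes `results.csv` and a plain-text
#' `report.txt` to `out_dir` and logs exclusion counts.
#'
#' @param config a [pipeline_config]; `participants` and the exposure CSV
#'   (at `out_dir/exposure.csv` or `config$manifest`-independent) must exist.
#' @param exposure_path optional explicit exposure CSV path.
#' @return the results CSV path, invisibly.
#' @export
cmd_associate <- function(config, exposure_path = NULL) {
  if (is.null(exposure_path)) {
    exposure_path <- file.path(config$out_dir, "exposure.csv")
  }
  exposures <- read_exposure_table(exposure_path)
  participants <- read_participants(config$participants)
  spec <- as_model_spec(config)
  n_missing_cesd <- sum(is.na(participants$cesd))
  message(sprintf("%d participants read; %d excluded for missing CES-D",
                  nrow(participants), n_missing_cesd))
  metrics_present <- intersect(c("ndvi", "bluegreen"), unique(exposures$metric))
  results <- list()
  add <- function(r) results[[length(results) + 1L]] <<- r
  for (metric in metrics_present) {
    window <- if (metric == "ndvi") "annual" else "static"
    for (r in config$radii) {
      for (adj in c(FALSE, TRUE)) {
        add(run_association(participants, exposures, spec, metric = metric,
                            buffer_m = r, window = window, adjusted = adj))
      }
    }
  }
  if (isTRUE(config$stratify)) {
    strata <- stratify_income(participants)
    for (metric in metrics_present) {
      window <- if (metric == "ndvi") "annual" else "static"
      for (r in config$radii) {
        add(run_association(strata$low, exposures, spec, metric = metric,
                            buffer_m = r, window = window, adjusted = TRUE,
                            stratum = "low_income"))
        add(run_association(strata$high, exposures, spec, metric = metric,
                            buffer_m = r, window = window, adjusted = TRUE,
                            stratum = "high_income"))
      }
    }
  }
  if (isTRUE(config$monthly) && "ndvi" %in% metrics_present) {
    buffers <- if (is.null(config$monthly_buffer)) config$radii
               else config$monthly_buffer
    for (b in buffers) {
      for (r in monthly_series(participants, exposures, spec, buffer_m = b)) {
        add(r)
      }
    }
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res_path <- file.path(config$out_dir, "results.csv")
  write_results(results, res_path)
  rep_path <- file.path(config$out_dir, "report.txt")
  writeLines(cmd_report(res_path), rep_path)
  message(sprintf("wrote %d model results to %s", length(results), res_path))
  invisible(res_path)
}

#' Render a plain-text association report
#'
#' Formats the results CSV as forest-style tables: overall models (metric x
#' buffer rows, unadjusted/adjusted columns), income-stratified models, and
#' the monthly series. Significance at the 0.05 level is starred. The report
#' is derived from the results file, so the two can never disagree.
#'
#' @param results_path path to a results CSV/JSON written by [write_results].
#' @return character vector of report lines.
#' @export
cmd_report <- function(results_path) {
  df <- read_results(results_path)
  fmt1 <- function(r) {
    sprintf("%.2f (%.2f-%.2f)%s", r$or_, r$ci_low, r$ci_high,
            ifelse(!is.na(r$p) & r$p < 0.05, "*", " "))
  }
  lines <- c("Odds ratios of depressive symptoms per IQR increase in exposure",
             "(* p < 0.05, Wald)", "")
  overall <- df[df$stratum == "all" & !grepl("^month-", df$window), ]
  if (nrow(overall)) {
    lines <- c(lines, "== Overall ==",
               sprintf("%-10s %8s  %-22s %-22s", "metric", "buffer_m",
                       "unadjusted OR (95% CI)", "adjusted OR (95% CI)"))
    for (metric in unique(overall$metric)) {
      for (b in sort(unique(overall$buffer_m[overall$metric == metric]))) {
        un <- overall[overall$metric == metric & overall$buffer_m == b &
                        !overall$adjusted, ]
        ad <- overall[overall$metric == metric & overall$buffer_m == b &
                        overall$adjusted, ]
        lines <- c(lines, sprintf("%-10s %8g  %-22s %-22s", metric, b,
                                  if (nrow(un)) fmt1(un[1, ]) else "-",
                                  if (nrow(ad)) fmt1(ad[1, ]) else "-"))
      }
    }
    lines <- c(lines, "")
  }
  strat <- df[df$stratum != "all", ]
  if (nrow(strat)) {
    lines <- c(lines, "== Stratified by household income (adjusted) ==",
               sprintf("%-10s %8s  %-22s %-22s", "metric", "buffer_m",
                       "low income", "high income"))
    for (metric in unique(strat$metric)) {
      for (b in sort(unique(strat$buffer_m[strat$metric == metric]))) {
        lo <- strat[strat$metric == metric & strat$buffer_m == b &
                      strat$stratum == "low_income", ]
        hi <- strat[strat$metric == metric & strat$buffer_m == b &
                      strat$stratum == "high_income", ]
        lines <- c(lines, sprintf("%-10s %8g  %-22s %-22s", metric, b,
                                  if (nrow(lo)) fmt1(lo[1, ]) else "-",
                                  if (nrow(hi)) fmt1(hi[1, ]) else "-"))
      }
    }
    lines <- c(lines, "")
  }
  monthly <- df[grepl("^month-", df$window) & df$stratum == "all", ]
  if (nrow(monthly)) {
    lines <- c(lines, "== Monthly NDVI series (adjusted) ==")
    for (b in sort(unique(monthly$buffer_m))) {
      lines <- c(lines, sprintf("buffer %g m:", b))
      sub <- monthly[monthly$buffer_m == b, ]
      sub <- sub[order(sub$window), ]
      for (i in seq_len(nrow(sub))) {
        lines <- c(lines, sprintf("  %s  %s", sub$window[i], fmt1(sub[i, ])))
      }
    }
    lines <- c(lines, "")
  }
  lines
}
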