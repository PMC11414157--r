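# Independent brute-force oracles and small fixture builders shared by the
# unit and acceptance tests. The oracles deliberately re-derive everything
# from first principles (loop/enumerate over all cells) instead of reusing
# any package internals.

# Exhaustive buffer oracle: test every cell center, no window trimming.
oracle_buffer_cells <- function(grid, center, radius) {
  hits <- NULL
  for (r in seq_len(grid$n_rows)) {
    for (c in seq_len(grid$n_cols)) {
      cx <- grid$origin_x + (c - 0.5) * grid$cell_size
      cy <- grid$origin_y - (r - 0.5) * grid$cell_size
      if ((cx - center[1])^2 + (cy - center[2])^2 <= radius^2) {
        hits <- rbind(hits, c(r, c))
      }
    }
  }
  if (is.null(hits)) {
    # same degenerate-buffer contract: fall back to the containing cell
    col <- floor((center[1] - grid$origin_x) / grid$cell_size) + 1
    row <- floor((grid$origin_y - center[2]) / grid$cell_size) + 1
    hits <- cbind(row, col)
  }
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  hits <- unname(hits)
  storage.mode(hits) <- "integer"
  hits
}

oracle_buffer_mean <- function(grid, center, radius, rescale = FALSE) {
  cells <- oracle_buffer_cells(grid, center, radius)
  vals <- numeric(0)
  for (i in seq_len(nrow(cells))) {
    v <- grid$values[cells[i, 1], cells[i, 2]]
    if (!is.na(v)) vals <- c(vals, if (rescale) max(0, v) else v)
  }
  if (length(vals) == 0) NA_real_ else sum(vals) / length(vals)
}

oracle_bluegreen <- function(grid, legend, center, radius) {
  cells <- oracle_buffer_cells(grid, center, radius)
  n_bg <- 0L; n_ok <- 0L
  bg <- unname(legend$classes[legend$blue_green])
  for (i in seq_len(nrow(cells))) {
    v <- grid$values[cells[i, 1], cells[i, 2]]
    if (!is.na(v)) {
      n_ok <- n_ok + 1L
      if (v %in% bg) n_bg <- n_bg + 1L
    }
  }
  if (n_ok == 0L) NA_real_ else n_bg / n_ok
}

# Expand a 2x2 table into subject-level outcome/exposure vectors:
# a exposed cases, b exposed non-cases, c unexposed cases, d unexposed.
make_2x2 <- function(a, b, c, d) {
  list(y = rep(c(1, 0, 1, 0), c(a, b, c, d)),
       x = rep(c(1, 1, 0, 0), c(a, b, c, d)))
}

# Small participant table with every categorical level represented (first
# rows enumerate the levels; the rest are drawn independently so no two
# covariate columns are collinear).
make_full_level_cohort <- function(n = 120, seed = 42) {
  set.seed(seed)
  lv <- greenexp:::participant_levels
  draw <- function(levels) {
    v <- sample(levels, n, replace = TRUE)
    v[seq_along(levels)] <- levels
    factor(v, levels)
  }
  df <- data.frame(
    id = sprintf("S%03d", seq_len(n)),
    x = runif(n, 1000, 2000), y = runif(n, 1000, 2000),
    cesd = sample(0:10, n, replace = TRUE),
    age_group = draw(lv$age_group),
    sex = draw(lv$sex),
    income = draw(lv$income),
    education = draw(lv$education),
    marital = draw(lv$marital),
    smoking = draw(lv$smoking),
    alcohol = draw(lv$alcohol),
    physical_activity = draw(lv$physical_activity),
    hypertension = sample(c(TRUE, FALSE), n, replace = TRUE),
    dyslipidemia = sample(c(TRUE, FALSE), n, replace = TRUE),
    diabetes = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.25, 0.75)),
    population_density = runif(n, 2000, 20000),
    crime_rate = runif(n, 20, 30),
    park_area_pc = runif(n, 6, 10),
    mean_temp = runif(n, 12, 14),
    stringsAsFactors = FALSE
  )
  df$exposure <- runif(n)
  df
}

# A quick ndvi-only simulation config for loops.
slim_config <- function(seed, n = 617, true_or = 1, windows = "annual",
                        causal_window = "annual", ...) {
  sim_config(seed = seed, n_participants = n, radii = 250,
             windows = windows, metrics = "ndvi",
             true_or_per_iqr = true_or, causal_window = causal_window, ...)
}

random_test_grid <- function(n_rows, n_cols, cell_size,
                             nodata_frac = 0, lulc_codes = NULL) {
  vals <- if (is.null(lulc_codes)) {
    matrix(runif(n_rows * n_cols, -1, 1), n_rows, n_cols)
  } else {
    matrix(sample(lulc_codes, n_rows * n_cols, replace = TRUE),
           n_rows, n_cols)
  }
  if (nodata_frac > 0) {
    vals[runif(n_rows * n_cols) < nodata_frac] <- NA
  }
  raster_grid(vals, origin_x = runif(1, -1e4, 1e4),
              origin_y = runif(1, -1e4, 1e4),
              cell_size = cell_size)
}
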