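# Allowed categorical levels for the participant table. Reference levels used
# by the design matrix are set separately (see build_design_matrix).
participant_levels <- list(
  age_group = c("60-64", "65-69", "70-74", "75-79", "80-84"),
  sex = c("male", "female"),
  income = c("<1M", "1-2M", "2-3M", "3-5M", ">=5M"),
  education = c("<=high-school", ">high-school"),
  marital = c("married", "widowed", "divorced", "never"),
  smoking = c("no", "yes"),
  alcohol = c("no", "yes"),
  physical_activity = c("no", "yes")
)

participant_columns <- c(
  "id", "x", "y", "cesd", "age_group", "sex", "income", "education", "marital",
  "smoking", "alcohol", "physical_activity", "hypertension", "dyslipidemia",
  "diabetes", "population_density", "crime_rate", "park_area_pc", "mean_temp"
)

results_columns <- c(
  "metric", "buffer_m", "window", "stratum", "adjusted", "n", "n_cases",
  "iqr", "beta", "se", "or_", "ci_low", "ci_high", "p"
)

#' Read a raster grid from an Esri ASCII grid file
#'
#' Parses the standard `.asc` header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, optional `NODATA_value`) followed by row-major
#' values, row 1 = north. NDVI grids are range-checked to `[-1, 1]`; LULC grids
#' must contain integer class codes. GeoTIFF input is not supported; convert to
#' an ASCII grid first.
#'
#' @param path path to a `.asc` file.
#' @param kind `"ndvi"` (continuous, range-checked) or `"lulc"` (integer codes).
#' @param crs_label CRS identifier to attach (the `.asc` format carries none).
#' @return a [raster_grid].
#' @export
read_grid <- function(path, kind = c("ndvi", "lulc"), crs_label = "local-metric") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("raster file not found: %s", path),
                               call. = FALSE)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    stop(sprintf(paste("GeoTIFF input is not supported: %s;",
                       "supply an Esri ASCII grid (.asc)"), path), call. = FALSE)
  }
  lines <- readLines(path, n = 7L)
  header <- list()
  n_header <- 0L
  for (ln in lines) {
    parts <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (length(parts) == 2L && grepl("^[A-Za-z_]+$", parts[1L]) &&
        !is.na(suppressWarnings(as.numeric(parts[2L])))) {
      header[[tolower(parts[1L])]] <- as.numeric(parts[2L])
      n_header <- n_header + 1L
    } else break
  }
  required <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(required %in% names(header))) {
    stop(sprintf("unreadable raster format in %s: missing header fields %s",
                 path, paste(setdiff(required, names(header)), collapse = ", ")),
         call. = FALSE)
  }
  if (any(c("dx", "dy") %in% names(header))) {
    stop(sprintf("non-square cells (dx/dy header) are not supported: %s", path),
         call. = FALSE)
  }
  nodata <- if ("nodata_value" %in% names(header)) header$nodata_value else -9999
  n_rows <- as.integer(header$nrows)
  n_cols <- as.integer(header$ncols)
  vals <- scan(path, what = numeric(), skip = n_header, quiet = TRUE)
  if (length(vals) != n_rows * n_cols) {
    stop(sprintf("%s declares %d x %d cells but contains %d values",
                 path, n_rows, n_cols, length(vals)), call. = FALSE)
  }
  m <- matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  if (kind == "ndvi") {
    validate_ndvi_values(m, what = sprintf("NDVI (%s)", basename(path)))
  } else {
    nz <- m[!is.na(m)]
    if (length(nz) && any(nz != round(nz))) {
      stop(sprintf("LULC grid %s contains non-integer class codes", path),
           call. = FALSE)
    }
  }
  raster_grid(m,
              origin_x = header$xllcorner,
              origin_y = header$yllcorner + n_rows * header$cellsize,
              cell_size = header$cellsize, nodata = nodata,
              crs_label = crs_label)
}

#' Write a raster grid to an Esri ASCII grid file
#'
#' `NA` cells are written as the grid's nodata sentinel. Grids whose non-nodata
#' values are all whole numbers (LULC codes) are written as integers; continuous
#' grids are written with 17 significant digits so that
#' `read_grid(write_grid(g))` round-trips losslessly.
#'
#' @param grid a [raster_grid].
#' @param path output path (parent directory must exist).
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "raster_grid"))
  if (!dir.exists(dirname(path))) {
    stop(sprintf("cannot write %s: directory does not exist", path), call. = FALSE)
  }
  m <- grid$values
  nz <- m[!is.na(m)]
  integerish <- length(nz) == 0L || all(nz == round(nz))
  fmt <- function(v) {
    out <- if (integerish) sprintf("%d", as.integer(round(v)))
           else formatC(v, digits = 17, format = "g")
    out[is.na(v)] <- fmt_num(grid$nodata)
    out
  }
  header <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %s", fmt_num(grid$origin_x)),
    sprintf("yllcorner %s", fmt_num(grid$origin_y - grid$n_rows * grid$cell_size)),
    sprintf("cellsize %s", fmt_num(grid$cell_size)),
    sprintf("NODATA_value %s", fmt_num(grid$nodata))
  )
  body <- apply(m, 1L, function(row) paste(fmt(row), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

fmt_num <- function(x) {
  ifelse(x == round(x) & abs(x) < 1e15, sprintf("%d", as.integer(x)),
         formatC(x, digits = 17, format = "g"))
}

#' Read a composite-series manifest
#'
#' The manifest is a CSV with columns `date` (ISO-8601) and `path`; relative
#' paths are resolved against the manifest's directory. Each raster is read
#' with `kind = "ndvi"`.
#'
#' @param path manifest CSV path.
#' @return a [composite_series].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop(sprintf("manifest not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "path") %in% names(df))) {
    stop(sprintf("manifest %s must have columns date, path", path), call. = FALSE)
  }
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path,
                  file.path(dirname(path), df$path))
  grids <- lapply(paths, read_grid, kind = "ndvi")
  composite_series(as.Date(df$date), grids)
}

#' Write a composite series plus manifest
#'
#' @param series a [composite_series].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix for the individual `.asc` layers.
#' @return the manifest path, invisibly.
#' @export
write_manifest <- function(series, dir, prefix = "ndvi") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("%s_%s.asc", prefix, format(series$dates, "%Y%m%d"))
  for (i in seq_along(files)) {
    write_grid(series$grids[[i]], file.path(dir, files[i]))
  }
  manifest <- file.path(dir, sprintf("%s_manifest.csv", prefix))
  utils::write.csv(data.frame(date = format(series$dates, "%Y-%m-%d"),
                              path = files),
                   manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}

#' Read and validate a participant table
#'
#' Expects exactly the documented columns. Categorical fields are validated
#' against the allowed levels (errors report the offending data row); CES-D
#' must be an integer 0-10 or empty. Missing CES-D is retained here (as `NA`)
#' and excluded later by the association stage, so exclusion counts can be
#' reported.
#'
#' @param path CSV path.
#' @return a `data.frame` with factor-typed categoricals, one row per subject.
#' @export
read_participants <- function(path) {
  if (!file.exists(path)) stop(sprintf("participant file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(id = "character"))
  unknown <- setdiff(names(df), participant_columns)
  if (length(unknown)) {
    stop(sprintf("unknown participant column(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  missing_cols <- setdiff(participant_columns, names(df))
  if (length(missing_cols)) {
    stop(sprintf("participant file lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df <- df[participant_columns]
  validate_participants(df)
}

#' Validate an in-memory participant table
#'
#' @param df data.frame with the participant schema.
#' @return the validated data.frame (categoricals as factors).
#' @export
validate_participants <- function(df) {
  if (anyDuplicated(df$id)) stop("participant ids must be unique", call. = FALSE)
  bad_cesd <- which(!is.na(df$cesd) &
                      (df$cesd != round(df$cesd) | df$cesd < 0 | df$cesd > 10))
  if (length(bad_cesd)) {
    stop(sprintf("cesd out of range 0..10 in row(s): %s",
                 paste(bad_cesd, collapse = ", ")), call. = FALSE)
  }
  for (col in names(participant_levels)) {
    lv <- participant_levels[[col]]
    vals <- as.character(df[[col]])
    bad <- which(!is.na(vals) & !(vals %in% lv))
    if (length(bad)) {
      stop(sprintf("unknown %s level '%s' in row %d (allowed: %s)",
                   col, vals[bad[1L]], bad[1L], paste(lv, collapse = ", ")),
           call. = FALSE)
    }
    df[[col]] <- factor(vals, levels = lv)
  }
  for (col in c("hypertension", "dyslipidemia", "diabetes")) {
    df[[col]] <- as.logical(df[[col]])
    if (anyNA(df[[col]])) {
      stop(sprintf("%s must be TRUE/FALSE (row %d)", col,
                   which(is.na(df[[col]]))[1L]), call. = FALSE)
    }
  }
  for (col in c("population_density", "crime_rate", "park_area_pc")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0)
    if (length(bad)) {
      stop(sprintf("%s must be finite and >= 0 (row %d)", col, bad[1L]),
           call. = FALSE)
    }
  }
  if (any(!is.finite(df$mean_temp))) {
    stop("mean_temp must be finite", call. = FALSE)
  }
  if (any(!is.finite(df$x)) || any(!is.finite(df$y))) {
    stop("participant coordinates must be finite", call. = FALSE)
  }
  df
}

#' Write a participant table
#' @param participants data.frame with the participant schema.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_participants <- function(participants, path) {
  out <- participants[participant_columns]
  for (col in names(participant_levels)) out[[col]] <- as.character(out[[col]])
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write association results to CSV or JSON
#'
#' The format is chosen by extension (`.csv` or `.json`). Numeric fields are
#' written at full double precision so a read-back reproduces them exactly.
#'
#' @param results a list of `association_result` objects or a data.frame in the
#'   results schema (see [results_table]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  df <- if (is.data.frame(results)) results else results_table(results)
  stopifnot(identical(names(df), results_columns))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    # I(17) = 17 *significant* digits, enough for lossless double round-trip
    jsonlite::write_json(df, path, dataframe = "rows", digits = I(17),
                         na = "null", auto_unbox = TRUE)
  } else {
    out <- df
    for (col in c("iqr", "beta", "se", "or_", "ci_low", "ci_high", "p")) {
      out[[col]] <- ifelse(is.na(df[[col]]), "",
                           formatC(df[[col]], digits = 17, format = "g"))
    }
    utils::write.csv(out, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read association results written by [write_results]
#' @param path `.csv` or `.json` path.
#' @return a data.frame in the results schema.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop(sprintf("results file not found: %s", path),
                               call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
    if (nrow(df) == 0L) {
      df <- empty_results_df()
    }
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  stopifnot(identical(names(df), results_columns))
  for (col in c("buffer_m", "iqr", "beta", "se", "or_", "ci_low", "ci_high", "p")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  for (col in c("n", "n_cases")) df[[col]] <- as.integer(df[[col]])
  df$adjusted <- as.logical(df$adjusted)
  df
}

empty_results_df <- function() {
  df <- data.frame(metric = character(), buffer_m = numeric(),
                   window = character(), stratum = character(),
                   adjusted = logical(), n = integer(), n_cases = integer(),
                   iqr = numeric(), beta = numeric(), se = numeric(),
                   or_ = numeric(), ci_low = numeric(), ci_high = numeric(),
                   p = numeric(), stringsAsFactors = FALSE)
  df
}
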