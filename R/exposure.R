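#' Rescale NDVI to the [0, 1] greenness scale
#'
#' Negative NDVI — water, bare soil, built surfaces, snow/ice — is mapped to
#' exactly zero and positive values are kept as-is (`max(0, v)`). An affine
#' `(v+1)/2` map would give water a value of 0.5, which is not the intended
#' "no vegetation = 0" semantics. The map is idempotent on `[0, 1]`, monotone
#' non-decreasing, and preserves `NA` (nodata).
#'
#' @param v numeric vector/matrix of NDVI in `[-1, 1]` (NA allowed).
#' @return values in `[0, 1]`, same shape as `v`.
#' @examples
#' rescale_ndvi(c(-0.3, 0, 0.62))
#' @export
rescale_ndvi <- function(v) {
  validate_ndvi_values(v)
  pmax(v, 0)
}

#' Cells of a circular buffer
#'
#' Returns every grid cell whose center lies within Euclidean distance
#' `radius` (closed boundary, `<=`) of `center`, intersected with the grid
#' extent. A 250 m buffer centered at the center of a 250 m cell therefore
#' selects the focal cell plus its four rook neighbors. If no cell center
#' falls inside the radius but the center point is on the raster, the single
#' containing cell is returned so that every on-raster location gets an
#' exposure.
#'
#' @param grid a [raster_grid].
#' @param center numeric `c(x, y)` in projected meters.
#' @param radius buffer radius in meters (> 0).
#' @return integer matrix with columns `row`, `col` (1-based), ordered
#'   row-major; attribute `"linear"` carries the corresponding linear indices
#'   into `grid$values`.
#' @export
buffer_cells <- function(grid, center, radius) {
  stopifnot(inherits(grid, "raster_grid"), length(center) == 2L)
  x <- as.numeric(center[[1L]]); y <- as.numeric(center[[2L]])
  if (!is.finite(radius) || radius <= 0) {
    stop("radius must be a positive finite number", call. = FALSE)
  }
  if (!point_in_grid(grid, x, y)) {
    stop(sprintf("buffer center (%g, %g) lies outside the raster extent", x, y),
         call. = FALSE)
  }
  cx <- cell_centers_x(grid)
  cy <- cell_centers_y(grid)
  ci <- which(abs(cx - x) <= radius)
  ri <- which(abs(cy - y) <= radius)
  rows <- integer(0); cols <- integer(0)
  if (length(ci) && length(ri)) {
    d2 <- outer((cy[ri] - y)^2, (cx[ci] - x)^2, "+")
    hit <- d2 <= radius^2
    if (any(hit)) {
      idx <- which(hit, arr.ind = TRUE)
      rows <- ri[idx[, 1L]]
      cols <- ci[idx[, 2L]]
    }
  }
  if (length(rows) == 0L) {
    # degenerate buffer smaller than half a cell: fall back to containing cell
    rc <- point_to_cell(grid, x, y)
    rows <- rc[["row"]]; cols <- rc[["col"]]
  }
  ord <- order(rows, cols)
  out <- cbind(row = as.integer(rows[ord]), col = as.integer(cols[ord]))
  attr(out, "linear") <- (out[, "col"] - 1L) * grid$n_rows + out[, "row"]
  out
}

#' Buffer-mean raster value
#'
#' Arithmetic mean of (optionally transformed) cell values over the circular
#' buffer, ignoring nodata cells. For NDVI exposure the transform is
#' [rescale_ndvi], applied per cell before averaging.
#'
#' @param grid a [raster_grid].
#' @param center numeric `c(x, y)` meters.
#' @param radius buffer radius in meters.
#' @param transform `"identity"` or `"rescale_ndvi"`.
#' @return the mean, or `NA` if every buffer cell is nodata.
#' @export
buffer_mean <- function(grid, center, radius,
                        transform = c("identity", "rescale_ndvi")) {
  transform <- match.arg(transform)
  cells <- buffer_cells(grid, center, radius)
  vals <- grid$values[attr(cells, "linear")]
  if (transform == "rescale_ndvi") vals <- rescale_ndvi(vals)
  if (all(is.na(vals))) return(NA_real_)
  mean(vals, na.rm = TRUE)
}

series_month <- function(dates) as.integer(format(dates, "%m"))

#' Monthly mean NDVI exposure
#'
#' Averages the rescaled buffer-mean NDVI over the composites whose start date
#' falls in the given calendar month (a 16-day composite is assigned to the
#' month containing its start date, the usual composite labeling convention).
#' Composites whose buffer mean is missing (all nodata) are dropped; a month
#' with no usable composites yields `NA` with a warning.
#'
#' @param series a [composite_series].
#' @param center numeric `c(x, y)` meters.
#' @param radius buffer radius in meters.
#' @param month calendar month 1-12.
#' @return mean exposure in `[0, 1]`, or `NA`.
#' @export
monthly_mean_exposure <- function(series, center, radius, month) {
  stopifnot(inherits(series, "composite_series"),
            month %in% 1:12)
  sel <- which(series_month(series$dates) == month)
  if (length(sel) == 0L) {
    warning(sprintf("no composites fall in month %02d; exposure is missing", month),
            call. = FALSE)
    return(NA_real_)
  }
  means <- vapply(sel, function(i) {
    buffer_mean(series$grids[[i]], center, radius, transform = "rescale_ndvi")
  }, numeric(1))
  if (all(is.na(means))) return(NA_real_)
  mean(means, na.rm = TRUE)
}

#' Annual mean NDVI exposure
#'
#' Unweighted mean of the rescaled buffer-mean NDVI over all composites in the
#' series (composite-weighted: months contributing three composites weigh
#' slightly more than months with two). Set `weighting = "month"` to average
#' the twelve monthly means instead.
#'
#' @param series a [composite_series].
#' @param center numeric `c(x, y)` meters.
#' @param radius buffer radius in meters.
#' @param weighting `"composite"` (default) or `"month"`.
#' @return mean exposure in `[0, 1]`, or `NA`.
#' @export
annual_mean_exposure <- function(series, center, radius,
                                 weighting = c("composite", "month")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(series, "composite_series"))
  means <- vapply(seq_along(series$dates), function(i) {
    buffer_mean(series$grids[[i]], center, radius, transform = "rescale_ndvi")
  }, numeric(1))
  if (all(is.na(means))) return(NA_real_)
  if (weighting == "composite") {
    mean(means, na.rm = TRUE)
  } else {
    monthly <- tapply(means, series_month(series$dates),
                      function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE))
    mean(monthly, na.rm = TRUE)
  }
}

#' Blue-greenspace proportion within a buffer
#'
#' Fraction of non-nodata buffer cells whose land-cover code belongs to the
#' legend's blue-green class set (water, parks, forests, agriculture). Ranges
#' from 0 (no blue-greenspace in the buffer) to 1 (buffer entirely
#' blue-green).
#'
#' @param lulc a categorical [raster_grid] of class codes.
#' @param legend a [lulc_legend].
#' @param center numeric `c(x, y)` meters.
#' @param radius buffer radius in meters.
#' @return proportion in `[0, 1]`, or `NA` if all buffer cells are nodata.
#' @export
bluegreen_proportion <- function(lulc, legend, center, radius) {
  stopifnot(inherits(legend, "lulc_legend"))
  cells <- buffer_cells(lulc, center, radius)
  codes <- lulc$values[attr(cells, "linear")]
  known <- codes[!is.na(codes)]
  bad <- setdiff(unique(known), legend$classes)
  if (length(bad)) {
    stop(sprintf("LULC codes not in legend: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (length(known) == 0L) return(NA_real_)
  mean(known %in% blue_green_codes(legend))
}

exposure_windows <- function(windows) {
  out <- character(0)
  if ("annual" %in% windows) out <- c(out, "annual")
  if ("monthly" %in% windows) out <- c(out, sprintf("month-%02d", 1:12))
  extra <- setdiff(windows, c("annual", "monthly"))
  bad <- extra[!grepl("^month-(0[1-9]|1[0-2])$", extra)]
  if (length(bad)) stop(sprintf("unknown window(s): %s", paste(bad, collapse = ", ")),
                        call. = FALSE)
  unique(c(out, extra))
}

#' Build the participant x metric x radius x window exposure table
#'
#' Computes rescaled buffer-mean NDVI exposures (per requested window) and/or
#' blue-greenspace land-cover proportions for every participant and radius.
#' Participants whose coordinates fall off the raster get `NA` exposures and a
#' single summary warning rather than aborting the batch; malformed inputs
#' (e.g. unknown LULC codes) remain hard errors.
#'
#' @param participants participant data.frame (needs `id`, `x`, `y`).
#' @param series a [composite_series] of NDVI composites, or `NULL` to skip
#'   the NDVI metric.
#' @param lulc a land-cover [raster_grid], or `NULL` to skip blue-greenspace.
#' @param legend a [lulc_legend] (required with `lulc`).
#' @param radii numeric vector of buffer radii in meters.
#' @param windows any of `"annual"`, `"monthly"` (expands to `month-01` ..
#'   `month-12`), or explicit `month-XX` labels; applies to the NDVI metric.
#'   Blue-greenspace is time-invariant and always uses window `"static"`.
#' @param annual_weighting `"composite"` or `"month"` (see
#'   [annual_mean_exposure]).
#' @return a data.frame of class `exposure_table` with columns
#'   `participant_id`, `metric`, `buffer_m`, `window`, `value`.
#' @export
build_exposure_table <- function(participants, series = NULL, lulc = NULL,
                                 legend = NULL,
                                 radii = c(250, 500, 1000, 2000),
                                 windows = c("annual", "monthly"),
                                 annual_weighting = c("composite", "month")) {
  annual_weighting <- match.arg(annual_weighting)
  if (nrow(participants) == 0L) stop("no participants supplied", call. = FALSE)
  if (length(radii) == 0L || any(radii <= 0)) {
    stop("radii must be a non-empty vector of positive distances", call. = FALSE)
  }
  if (!is.null(lulc) && is.null(legend)) {
    stop("a legend is required with an LULC raster", call. = FALSE)
  }
  ids <- as.character(participants$id)
  n <- length(ids)
  off_raster <- character(0)
  blocks <- list()

  if (!is.null(series)) {
    stopifnot(inherits(series, "composite_series"))
    geom <- series$grids[[1L]]
    wins <- exposure_windows(windows)
    months <- series_month(series$dates)
    month_of <- as.integer(sub("^month-", "", grep("^month-", wins, value = TRUE)))
    absent <- setdiff(month_of, months)
    if (length(absent)) {
      warning(sprintf("no composites in month(s) %s; those exposures are missing",
                      paste(sprintf("%02d", absent), collapse = ", ")),
              call. = FALSE)
    }
    # rescale every composite once; stack as cells x composites for fast lookup
    V <- vapply(series$grids, function(g) as.vector(rescale_ndvi(g$values)),
                numeric(geom$n_rows * geom$n_cols))
    V <- matrix(V, ncol = length(series$dates))
    nw <- length(wins)
    nr <- length(radii)
    vals <- matrix(NA_real_, nrow = n * nr, ncol = nw)
    k <- 0L
    for (i in seq_len(n)) {
      center <- c(participants$x[i], participants$y[i])
      for (r in radii) {
        k <- k + 1L
        lin <- tryCatch(attr(buffer_cells(geom, center, r), "linear"),
                        error = function(e) NULL)
        if (is.null(lin)) {
          off_raster <- unique(c(off_raster, ids[i]))
          next
        }
        comp_means <- colMeans(V[lin, , drop = FALSE], na.rm = TRUE)
        comp_means[is.nan(comp_means)] <- NA_real_
        for (j in seq_len(nw)) {
          w <- wins[j]
          if (w == "annual") {
            vals[k, j] <- if (all(is.na(comp_means))) NA_real_
                   else if (annual_weighting == "composite") {
                     mean(comp_means, na.rm = TRUE)
                   } else {
                     mm <- tapply(comp_means, months, mean, na.rm = TRUE)
                     mm[is.nan(mm)] <- NA_real_
                     mean(mm, na.rm = TRUE)
                   }
          } else {
            mo <- as.integer(sub("^month-", "", w))
            sel <- comp_means[months == mo]
            vals[k, j] <- if (length(sel) == 0L || all(is.na(sel))) NA_real_
                   else mean(sel, na.rm = TRUE)
          }
        }
      }
    }
    blocks[[length(blocks) + 1L]] <- data.frame(
      participant_id = rep(ids, each = nr * nw),
      metric = "ndvi",
      buffer_m = rep(rep(radii, each = nw), times = n),
      window = rep(wins, times = n * nr),
      value = as.vector(t(vals)),
      stringsAsFactors = FALSE
    )
  }

  if (!is.null(lulc)) {
    bg <- matrix(NA_real_, nrow = length(radii), ncol = n)
    for (i in seq_len(n)) {
      center <- c(participants$x[i], participants$y[i])
      for (j in seq_along(radii)) {
        bg[j, i] <- tryCatch(bluegreen_proportion(lulc, legend, center, radii[j]),
                        error = function(e) {
                          if (grepl("outside the raster extent", conditionMessage(e))) {
                            off_raster <<- unique(c(off_raster, ids[i]))
                            NA_real_
                          } else stop(e)
                        })
      }
    }
    blocks[[length(blocks) + 1L]] <- data.frame(
      participant_id = rep(ids, each = length(radii)),
      metric = "bluegreen",
      buffer_m = rep(radii, times = n),
      window = "static",
      value = as.vector(bg),
      stringsAsFactors = FALSE
    )
  }

  if (length(off_raster)) {
    warning(sprintf("%d participant(s) fall off the raster; exposures set missing: %s",
                    length(off_raster),
                    paste(utils::head(off_raster, 5L), collapse = ", ")),
            call. = FALSE)
  }
  if (length(blocks) == 0L) {
    stop("no exposure metric requested: supply an NDVI series and/or an LULC raster",
         call. = FALSE)
  }
  validate_exposure_table(do.call(rbind, blocks))
}

#' Validate an exposure table
#'
#' Checks the key uniqueness and `[0, 1]` value range invariants and attaches
#' the `exposure_table` class.
#'
#' @param df data.frame with columns `participant_id`, `metric`, `buffer_m`,
#'   `window`, `value`.
#' @return the validated data.frame, classed `exposure_table`.
#' @export
validate_exposure_table <- function(df) {
  need <- c("participant_id", "metric", "buffer_m", "window", "value")
  stopifnot(all(need %in% names(df)))
  keys <- paste(df$participant_id, df$metric, df$buffer_m, df$window)
  if (anyDuplicated(keys)) {
    stop("duplicate (participant, metric, buffer, window) keys in exposure table",
         call. = FALSE)
  }
  v <- df$value[!is.na(df$value)]
  if (length(v) && (min(v) < 0 || max(v) > 1)) {
    stop("exposure values must lie in [0, 1]", call. = FALSE)
  }
  if (any(df$metric == "bluegreen" & df$window != "static")) {
    stop("bluegreen exposures must use window 'static'", call. = FALSE)
  }
  class(df) <- unique(c("exposure_table", class(df)))
  df
}

#' Write an exposure table to CSV
#' @param exposures an `exposure_table` data.frame.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_exposure_table <- function(exposures, path) {
  out <- as.data.frame(exposures)
  out$value <- ifelse(is.na(out$value), "",
                      formatC(out$value, digits = 17, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an exposure table written by [write_exposure_table]
#' @param path CSV path.
#' @return an `exposure_table` data.frame.
#' @export
read_exposure_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("exposure file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant_id = "character"))
  df$value <- as.numeric(df$value)
  validate_exposure_table(df)
}
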