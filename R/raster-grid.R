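#' Georeferenced rectangular raster grid
#'
#' A minimal planar raster container used for both NDVI layers and categorical
#' land-use/land-cover (LULC) surfaces. Coordinates are projected meters; the
#' package never reprojects, so inputs must already be in a metric CRS.
#'
#' Cell `(r, c)` (1-based) covers the half-open square
#' `[origin_x + (c-1)*cell_size, origin_x + c*cell_size)` in x and
#' `(origin_y - r*cell_size, origin_y - (r-1)*cell_size]` in y; row 1 is
#' northernmost. The cell center is
#' `(origin_x + (c-0.5)*cell_size, origin_y - (r-0.5)*cell_size)`.
#'
#' @param values numeric matrix (`n_rows` x `n_cols`); `NA` marks nodata cells.
#' @param origin_x,origin_y projected coordinates (m) of the top-left corner.
#' @param cell_size cell edge length in meters (square cells).
#' @param nodata sentinel written to / read from files in place of `NA`.
#' @param crs_label free-text identifier of the projected, meter-unit CRS.
#' @return an object of class `raster_grid`.
#' @examples
#' g <- raster_grid(matrix(runif(12, 0, 1), 3, 4), 0, 750, 250)
#' dim(g$values)
#' @export
raster_grid <- function(values, origin_x, origin_y, cell_size,
                        nodata = -9999, crs_label = "local-metric") {
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(cell_size) || length(cell_size) != 1L || !is.finite(cell_size) ||
      cell_size <= 0) {
    stop("cell_size must be a single positive number", call. = FALSE)
  }
  if (nrow(values) < 1L || ncol(values) < 1L) {
    stop("grid must have at least one row and one column", call. = FALSE)
  }
  if (!is.finite(origin_x) || !is.finite(origin_y)) {
    stop("grid origin must be finite", call. = FALSE)
  }
  structure(
    list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         cell_size = as.numeric(cell_size),
         n_rows = nrow(values), n_cols = ncol(values),
         values = values, nodata = as.numeric(nodata),
         crs_label = as.character(crs_label)),
    class = "raster_grid"
  )
}

#' @export
print.raster_grid <- function(x, ...) {
  cat(sprintf("<raster_grid> %d x %d cells of %g m, origin (%g, %g), CRS '%s'\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_x, x$origin_y, x$crs_label))
  v <- x$values[!is.na(x$values)]
  if (length(v)) {
    cat(sprintf("  values in [%g, %g], %d nodata cells\n",
                min(v), max(v), sum(is.na(x$values))))
  } else {
    cat("  all cells nodata\n")
  }
  invisible(x)
}

grid_xmin <- function(g) g$origin_x
grid_xmax <- function(g) g$origin_x + g$n_cols * g$cell_size
grid_ymax <- function(g) g$origin_y
grid_ymin <- function(g) g$origin_y - g$n_rows * g$cell_size

#' X coordinates of cell-column centers, west to east
#' @param grid a `raster_grid`.
#' @return numeric vector of length `n_cols`.
#' @export
cell_centers_x <- function(grid) {
  grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$cell_size
}

#' Y coordinates of cell-row centers, north to south
#' @param grid a `raster_grid`.
#' @return numeric vector of length `n_rows`.
#' @export
cell_centers_y <- function(grid) {
  grid$origin_y - (seq_len(grid$n_rows) - 0.5) * grid$cell_size
}

#' Does a point fall inside the grid extent?
#'
#' Uses the half-open cell convention: x in `[xmin, xmax)`, y in `(ymin, ymax]`.
#' @param grid a `raster_grid`.
#' @param x,y projected coordinates (m).
#' @return logical.
#' @export
point_in_grid <- function(grid, x, y) {
  is.finite(x) && is.finite(y) &&
    x >= grid_xmin(grid) && x < grid_xmax(grid) &&
    y > grid_ymin(grid) && y <= grid_ymax(grid)
}

#' Locate the cell containing a point
#' @param grid a `raster_grid`.
#' @param x,y projected coordinates (m); must fall inside the grid extent.
#' @return integer vector `c(row, col)`, 1-based, row 1 = north.
#' @export
point_to_cell <- function(grid, x, y) {
  if (!point_in_grid(grid, x, y)) {
    stop(sprintf("point (%g, %g) lies outside the raster extent [%g, %g) x (%g, %g]",
                 x, y, grid_xmin(grid), grid_xmax(grid), grid_ymin(grid),
                 grid_ymax(grid)), call. = FALSE)
  }
  col <- floor((x - grid$origin_x) / grid$cell_size) + 1
  # cells are closed at their top edge: a point exactly on a row boundary
  # belongs to the row below it
  row <- floor((grid$origin_y - y) / grid$cell_size) + 1
  row <- max(1L, min(grid$n_rows, as.integer(row)))
  col <- max(1L, min(grid$n_cols, as.integer(col)))
  c(row = as.integer(row), col = as.integer(col))
}

same_geometry <- function(a, b, tol = 1e-9) {
  abs(a$origin_x - b$origin_x) <= tol && abs(a$origin_y - b$origin_y) <= tol &&
    abs(a$cell_size - b$cell_size) <= tol &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    identical(a$crs_label, b$crs_label)
}

validate_ndvi_values <- function(values, what = "NDVI") {
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < -1 || max(v) > 1)) {
    stop(sprintf("%s values must lie in [-1, 1]; found range [%g, %g]",
                 what, min(v), max(v)), call. = FALSE)
  }
  invisible(TRUE)
}

#' Dated series of NDVI composites on a shared grid
#'
#' Bundles an ordered sequence of (date, grid) pairs, e.g. the ~23 16-day
#' vegetation-index composites of one year. All grids must share one geometry;
#' dates must be strictly increasing. A gap other than the nominal composite
#' interval is reported as a warning, not an error.
#'
#' @param dates `Date` vector.
#' @param grids list of `raster_grid` objects, same length as `dates`.
#' @param nominal_interval expected spacing between composites in days.
#' @return an object of class `composite_series` with elements `dates`, `grids`.
#' @export
composite_series <- function(dates, grids, nominal_interval = 16L) {
  dates <- as.Date(dates)
  if (length(dates) != length(grids) || length(dates) == 0L) {
    stop("need one grid per date and at least one composite", call. = FALSE)
  }
  if (any(diff(as.numeric(dates)) <= 0)) {
    stop("composite dates must be strictly increasing", call. = FALSE)
  }
  ok <- vapply(grids, inherits, logical(1), what = "raster_grid")
  if (!all(ok)) stop("all entries must be raster_grid objects", call. = FALSE)
  g1 <- grids[[1L]]
  for (i in seq_along(grids)[-1L]) {
    if (!same_geometry(g1, grids[[i]])) {
      stop(sprintf("composite %d does not share the series geometry", i),
           call. = FALSE)
    }
  }
  gaps <- diff(as.numeric(dates))
  if (length(gaps) && any(gaps != nominal_interval)) {
    warning(sprintf("composite spacing deviates from the nominal %d days (gaps: %s)",
                    nominal_interval,
                    paste(unique(gaps[gaps != nominal_interval]), collapse = ", ")),
            call. = FALSE)
  }
  structure(list(dates = dates, grids = grids), class = "composite_series")
}

#' @export
print.composite_series <- function(x, ...) {
  cat(sprintf("<composite_series> %d composites, %s .. %s\n",
              length(x$dates), min(x$dates), max(x$dates)))
  print(x$grids[[1L]])
  invisible(x)
}

#' @export
length.composite_series <- function(x) length(x$dates)

#' Land-use/land-cover legend with a blue-green class set
#'
#' @param classes named integer vector mapping class name to raster code,
#'   e.g. `c(water = 10, park = 20, forest = 30, agriculture = 40, urban = 50)`.
#' @param blue_green character vector of class names counted as blue-greenspace
#'   (typically water, public parks, forests, agriculture).
#' @return an object of class `lulc_legend`.
#' @export
lulc_legend <- function(classes, blue_green) {
  if (length(classes) == 0L || is.null(names(classes)) || any(names(classes) == "")) {
    stop("classes must be a non-empty named vector of codes", call. = FALSE)
  }
  if (anyDuplicated(classes) || anyDuplicated(names(classes))) {
    stop("class codes and names must be unique", call. = FALSE)
  }
  missing_bg <- setdiff(blue_green, names(classes))
  if (length(missing_bg)) {
    stop(sprintf("blue-green classes not in legend: %s",
                 paste(missing_bg, collapse = ", ")), call. = FALSE)
  }
  structure(list(classes = stats::setNames(as.integer(classes), names(classes)),
                 blue_green = as.character(blue_green)),
            class = "lulc_legend")
}

#' Codes counted as blue-greenspace
#' @param legend a `lulc_legend`.
#' @return integer vector of raster codes.
#' @export
blue_green_codes <- function(legend) {
  unname(legend$classes[legend$blue_green])
}
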