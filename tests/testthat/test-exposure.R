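test_that("rescale_ndvi clamps negatives to zero and is idempotent/monotone", {
  expect_equal(rescale_ndvi(-0.3), 0)
  expect_equal(rescale_ndvi(0), 0)
  expect_equal(rescale_ndvi(0.62), 0.62)
  expect_true(is.na(rescale_ndvi(NA)))
  expect_error(rescale_ndvi(1.7), "\\[-1, 1\\]")
  v <- seq(-1, 1, by = 0.01)
  r <- rescale_ndvi(v)
  expect_true(all(r >= 0 & r <= 1))
  expect_identical(rescale_ndvi(r), r)          # idempotent
  expect_true(all(diff(r) >= 0))                # monotone
  m <- matrix(c(-0.5, 0.5, NA, 0.1), 2, 2)
  expect_identical(dim(rescale_ndvi(m)), dim(m))
})

test_that("buffer_cells reproduces the rook/disc neighborhoods at 250/500 m", {
  g <- raster_grid(matrix(0, 9, 9), 0, 2250, 250)
  ctr <- c(cell_centers_x(g)[5], cell_centers_y(g)[5])
  b250 <- buffer_cells(g, ctr, 250)
  expect_equal(nrow(b250), 5L)   # focal cell + 4 rook neighbors at exactly 250 m
  expect_true(all(abs(b250[, "row"] - 5) + abs(b250[, "col"] - 5) <= 1))
  b500 <- buffer_cells(g, ctr, 500)
  expect_equal(nrow(b500), 13L)  # offsets with i^2 + j^2 <= 4
  offs <- cbind(b500[, "row"] - 5, b500[, "col"] - 5)
  expect_true(all(rowSums(offs^2) <= 4))
  # tiny radius falls back to the containing cell
  b10 <- buffer_cells(g, ctr + c(30, 40), 10)
  expect_equal(nrow(b10), 1L)
  expect_equal(unname(b10[1, ]), c(5L, 5L))
  expect_error(buffer_cells(g, c(-5000, 0), 250), "outside the raster")
  expect_error(buffer_cells(g, ctr, 0), "radius")
})

test_that("buffer nesting and translation equivariance hold", {
  set.seed(11)
  for (i in 1:20) {
    g <- random_test_grid(sample(10:30, 1), sample(10:30, 1),
                          cell_size = runif(1, 50, 400))
    ctr <- c(runif(1, grid_xmin <- g$origin_x, g$origin_x + g$n_cols * g$cell_size - 1e-6),
             runif(1, g$origin_y - g$n_rows * g$cell_size + 1e-6, g$origin_y))
    r1 <- runif(1, 10, 800); r2 <- r1 + runif(1, 0, 800)
    k1 <- attr(buffer_cells(g, ctr, r1), "linear")
    k2 <- attr(buffer_cells(g, ctr, r2), "linear")
    expect_true(all(k1 %in% k2))
    # shift grid and center together: identical cells and mean
    off <- c(1250, -750)
    g2 <- raster_grid(g$values, g$origin_x + off[1], g$origin_y + off[2],
                      g$cell_size)
    expect_identical(unclass(buffer_cells(g2, ctr + off, r1))[, ],
                     unclass(buffer_cells(g, ctr, r1))[, ])
    expect_equal(buffer_mean(g2, ctr + off, r1), buffer_mean(g, ctr, r1))
  }
})

test_that("buffer_mean averages transformed non-nodata cells", {
  g <- raster_grid(matrix(0.4, 9, 9), 0, 2250, 250)
  ctr <- c(cell_centers_x(g)[5], cell_centers_y(g)[5])
  expect_equal(buffer_mean(g, ctr, 600), 0.4)
  # plant known values on the 5-cell rook buffer
  vals <- matrix(NA_real_, 9, 9)
  vals[5, 5] <- 0.6; vals[4, 5] <- 0.2; vals[6, 5] <- 0.4
  vals[5, 4] <- 0.8; vals[5, 6] <- 1.0
  g2 <- raster_grid(vals, 0, 2250, 250)
  expect_equal(buffer_mean(g2, ctr, 250), 0.6)  # (0.2+0.4+0.6+0.8+1.0)/5
  vals[4, 5] <- NA                              # drop the 0.2 cell
  g3 <- raster_grid(vals, 0, 2250, 250)
  expect_equal(buffer_mean(g3, ctr, 250), 0.7)  # 2.8/4
  all_na <- raster_grid(matrix(NA_real_, 3, 3), 0, 750, 250)
  expect_true(is.na(buffer_mean(all_na, c(375, 375), 250)))
  # rescaling happens per cell before averaging
  neg <- raster_grid(matrix(-0.5, 3, 3), 0, 750, 250)
  expect_equal(buffer_mean(neg, c(375, 375), 250, transform = "rescale_ndvi"), 0)
  expect_equal(buffer_mean(neg, c(375, 375), 250, transform = "identity"), -0.5)
})

test_that("monthly and annual window means follow the composite calendar", {
  mk <- function(val) raster_grid(matrix(val, 5, 5), 0, 1250, 250)
  ctr <- c(625, 625)
  # two January composites -> their average
  s <- composite_series(as.Date(c("2021-01-01", "2021-01-17", "2021-02-02")),
                        list(mk(0.3), mk(0.5), mk(0.9)))
  expect_equal(monthly_mean_exposure(s, ctr, 250, 1), 0.4)
  expect_equal(monthly_mean_exposure(s, ctr, 250, 2), 0.9)
  expect_warning(m3 <- monthly_mean_exposure(s, ctr, 250, 7), "no composites")
  expect_true(is.na(m3))
  # single-composite month is its own mean
  expect_equal(monthly_mean_exposure(s, ctr, 250, 2), 0.9)
  # annual mean over 23 composites with buffer-means k/100
  suppressWarnings({
    s23 <- composite_series(as.Date("2021-01-01") + 16 * (0:22),
                            lapply(1:23, function(k) mk(k / 100)))
  })
  expect_equal(annual_mean_exposure(s23, ctr, 250), 0.12)
  # constant series -> the constant
  s_const <- composite_series(as.Date("2021-01-01") + 16 * (0:5),
                              lapply(1:6, function(k) mk(0.25)))
  expect_equal(annual_mean_exposure(s_const, ctr, 250), 0.25)
})

test_that("annual mean commutes with monthly means under equal composite counts", {
  mk <- function(val) raster_grid(matrix(val, 5, 5), 0, 1250, 250)
  ctr <- c(625, 625)
  set.seed(3)
  # exactly two composites in each of 12 months
  dates <- as.Date(sprintf("2021-%02d-%02d", rep(1:12, each = 2), c(3, 18)))
  vals <- runif(24, 0, 1)
  suppressWarnings(s <- composite_series(dates, lapply(vals, mk)))
  monthly <- vapply(1:12, function(m) monthly_mean_exposure(s, ctr, 250, m),
                    numeric(1))
  expect_equal(annual_mean_exposure(s, ctr, 250), mean(monthly))
  expect_equal(annual_mean_exposure(s, ctr, 250, weighting = "month"),
               mean(monthly))
})

test_that("bluegreen_proportion counts legend classes within the buffer", {
  legend <- lulc_legend(c(water = 10, park = 20, forest = 30,
                          agriculture = 40, urban = 50),
                        c("water", "park", "forest", "agriculture"))
  ctr <- c(1250, 1250)
  all_water <- raster_grid(matrix(10, 10, 10), 0, 2500, 250)
  expect_equal(bluegreen_proportion(all_water, legend, ctr, 600), 1)
  all_urban <- raster_grid(matrix(50, 10, 10), 0, 2500, 250)
  expect_equal(bluegreen_proportion(all_urban, legend, ctr, 600), 0)
  # half park / half urban in stripes -> 0.5 over a symmetric buffer
  stripes <- raster_grid(matrix(c(20, 50), 10, 10), 0, 2500, 250)
  expect_equal(bluegreen_proportion(stripes, legend, ctr, 5000), 0.5)
  bad <- raster_grid(matrix(99, 4, 4), 0, 1000, 250)
  expect_error(bluegreen_proportion(bad, legend, c(500, 500), 300),
               "not in legend")
  all_na <- raster_grid(matrix(NA_real_, 4, 4), 0, 1000, 250)
  expect_true(is.na(bluegreen_proportion(all_na, legend, c(500, 500), 300)))
  # complement property: blue-green share + other share = 1
  set.seed(4)
  mixed <- random_test_grid(20, 20, 100, lulc_codes = c(10, 20, 30, 40, 50))
  ctr2 <- c(mixed$origin_x + 1000, mixed$origin_y - 1000)
  other_legend <- lulc_legend(c(water = 10, park = 20, forest = 30,
                                agriculture = 40, urban = 50), "urban")
  expect_equal(bluegreen_proportion(mixed, legend, ctr2, 700) +
                 bluegreen_proportion(mixed, other_legend, ctr2, 700), 1)
})

test_that("build_exposure_table enumerates keys and degrades off-raster rows", {
  set.seed(5)
  grids <- lapply(1:4, function(i) {
    raster_grid(matrix(runif(400, 0, 1), 20, 20), 0, 5000, 250)
  })
  suppressWarnings(
    s <- composite_series(as.Date(c("2021-01-01", "2021-01-17",
                                    "2021-02-02", "2021-02-18")), grids))
  lulc <- raster_grid(matrix(c(10, 50), 50, 50), 0, 5000, 100)
  legend <- lulc_legend(c(water = 10, urban = 50), "water")
  p <- data.frame(id = c("A", "B"), x = c(2500, 2600), y = c(2500, 2400))
  tab <- build_exposure_table(p, s, lulc, legend, radii = c(250, 500),
                              windows = "annual")
  expect_s3_class(tab, "exposure_table")
  expect_equal(nrow(tab), 2 * 2 * 2)  # 2 participants x 2 radii x (annual + static)
  expect_true(all(tab$value >= 0 & tab$value <= 1))
  expect_setequal(unique(tab$metric), c("ndvi", "bluegreen"))
  # matches the standalone per-participant operations
  expect_equal(tab$value[tab$participant_id == "A" & tab$metric == "ndvi" &
                           tab$buffer_m == 250],
               annual_mean_exposure(s, c(2500, 2500), 250))
  expect_equal(tab$value[tab$participant_id == "B" & tab$metric == "bluegreen" &
                           tab$buffer_m == 500],
               bluegreen_proportion(lulc, legend, c(2600, 2400), 500))
  # off-raster participant: rows exist, values missing, one warning
  p2 <- rbind(p, data.frame(id = "C", x = 99999, y = 99999))
  expect_warning(tab2 <- build_exposure_table(p2, s, lulc, legend,
                                              radii = 250, windows = "annual"),
                 "off the raster")
  expect_equal(sum(tab2$participant_id == "C"), 2L)
  expect_true(all(is.na(tab2$value[tab2$participant_id == "C"])))
  expect_error(build_exposure_table(p[0, ], s, radii = 250), "no participants")
  # monthly windows expand to month-01..month-12 (absent months warn, NA)
  expect_warning(
    tab3 <- build_exposure_table(p, s, radii = 250, windows = "monthly"),
    "no composites in month")
  expect_equal(sum(tab3$participant_id == "A"), 12L)
  expect_true(all(is.na(tab3$value[tab3$window == "month-07"])))
  expect_false(anyNA(tab3$value[tab3$window %in% c("month-01", "month-02")]))
})

test_that("exposure tables round-trip through CSV", {
  dir <- withr::local_tempdir()
  tab <- validate_exposure_table(data.frame(
    participant_id = c("A", "A", "B"),
    metric = c("ndvi", "bluegreen", "ndvi"),
    buffer_m = c(250, 250, 250),
    window = c("annual", "static", "annual"),
    value = c(0.123456789123, 0.5, NA)))
  path <- file.path(dir, "exposure.csv")
  write_exposure_table(tab, path)
  back <- read_exposure_table(path)
  expect_identical(back$value, tab$value)
  expect_identical(back$participant_id, tab$participant_id)
  # invariants rejected: duplicate keys, out-of-range, bluegreen non-static
  expect_error(validate_exposure_table(rbind(tab, tab[1, ])), "duplicate")
  bad <- tab; bad$value[1] <- 1.2
  expect_error(validate_exposure_table(bad), "\\[0, 1\\]")
  bad2 <- tab; bad2$window[2] <- "annual"
  expect_error(validate_exposure_table(bad2), "static")
})
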