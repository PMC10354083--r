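test_that("median composite collapses a stack per pixel, ignoring nodata", {
  a <- radiance_raster(matrix(1, 4, 5))
  b <- radiance_raster(matrix(3, 4, 5))
  expect_equal(composite_median_raster(list(a, b))$values, matrix(2, 4, 5))
  expect_equal(composite_median_raster(list(a))$values, a$values)

  set.seed(42)
  stack <- replicate(12, random_raster(6, 7, na_frac = 0.15), simplify = FALSE)
  comp <- composite_median_raster(stack)
  for (i in 1:6) {
    for (j in 1:7) {
      vals <- vapply(stack, function(r) r$values[i, j], numeric(1))
      expect_equal(comp$values[i, j], oracle_median(vals[!is.na(vals)]))
    }
  }

  shifted <- radiance_raster(matrix(1, 4, 5), x0 = 1)
  expect_error(composite_median_raster(list(a, shifted)), "geometry")
  small <- radiance_raster(matrix(1, 3, 5))
  expect_error(composite_median_raster(list(a, small)), "geometry")
})

test_that("ascii grid IO round-trips values, geometry and nodata", {
  set.seed(7)
  r <- random_raster(5, 8, pixel = 0.5, x0 = -3.25, y0 = 10, na_frac = 0.2)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_raster(r, path)
  r2 <- read_ascii_raster(path)
  expect_equal(r2$values, r$values)
  expect_equal(
    c(r2$x0, r2$y0, r2$pixel, r2$ncols, r2$nrows),
    c(r$x0, r$y0, r$pixel, r$ncols, r$nrows)
  )
  expect_equal(r2$crs, r$crs)

  writeLines(c("ncols 2", "nrows 1", "cellsize 1", "1 2"), path)
  expect_error(read_ascii_raster(path), "xllcorner")
})

test_that("buffer median matches hand-countable cases", {
  const <- radiance_raster(matrix(3.5, 10, 10))
  expect_equal(median_radiance_in_buffer(const, 5, 5, 2), 3.5)
  expect_equal(median_radiance_in_buffer(const, 1.3, 8.7, 4.9), 3.5)

  # single column holding exactly {0, 1, 2, 3, 4}; buffer catches all five
  col5 <- radiance_raster(matrix(c(0, 1, 2, 3, 4), 5, 1))
  expect_equal(median_radiance_in_buffer(col5, 0.5, 2.5, 2.0), 2)
  # radius 1.2 catches {1, 2, 3} -> 2; radius 1.0 exactly reaches them too
  expect_equal(median_radiance_in_buffer(col5, 0.5, 2.5, 1.2), 2)
  expect_equal(median_radiance_in_buffer(col5, 0.5, 2.5, 1.0), 2)
})

test_that("buffer median equals the exhaustive pixel-centre oracle", {
  set.seed(99)
  for (case in 1:200) {
    r <- random_raster(
      nr = sample(4:12, 1), nc = sample(4:12, 1),
      pixel = runif(1, 0.5, 2), x0 = runif(1, -5, 5), y0 = runif(1, -5, 5),
      na_frac = 0.1
    )
    ext <- urbantol:::.raster_extent(r)
    px <- runif(1, ext["xmin"], ext["xmax"])
    py <- runif(1, ext["ymin"], ext["ymax"])
    radius <- runif(1, r$pixel, 4 * r$pixel)
    oracle <- oracle_buffer_median(r, px, py, radius)
    if (is.na(oracle)) {
      expect_error(median_radiance_in_buffer(r, px, py, radius))
    } else {
      expect_equal(median_radiance_in_buffer(r, px, py, radius), oracle)
    }
  }
})

test_that("buffer median is translation invariant and radius-monotone in coverage", {
  set.seed(5)
  r <- random_raster(8, 8)
  shift <- c(13.5, -7.25)
  r2 <- radiance_raster(r$values, x0 = r$x0 + shift[1], y0 = r$y0 + shift[2])
  for (k in 1:20) {
    px <- runif(1, 1, 7)
    py <- runif(1, 1, 7)
    rad <- runif(1, 1, 3)
    expect_equal(
      median_radiance_in_buffer(r, px, py, rad),
      median_radiance_in_buffer(r2, px + shift[1], py + shift[2], rad)
    )
    # pixel count used never decreases with radius (via the oracle count)
    count_at <- function(radius) {
      xc <- urbantol:::.raster_xc(r)
      yc <- urbantol:::.raster_yc(r)
      sum(outer((yc - py)^2, (xc - px)^2, `+`) <= radius^2)
    }
    expect_gte(count_at(rad * 1.5), count_at(rad))
  }
})

test_that("buffer median rejects uncovered or outside points", {
  r <- radiance_raster(matrix(1, 4, 4))
  expect_error(median_radiance_in_buffer(r, 10, 2, 1), "outside")
  expect_error(median_radiance_in_buffer(r, 0.01, 0.01, 0.05), "buffer")
  expect_error(median_radiance_in_buffer(r, 2, 2, -1), "positive")
  allna <- radiance_raster(matrix(NA_real_, 4, 4))
  expect_error(median_radiance_in_buffer(allna, 2, 2, 1), "non-missing")
})

test_that("wgs84 buffer distances use great circles", {
  # at 60 degrees latitude one degree of longitude is ~55.7 km while one
  # degree of latitude is ~111 km: a 60-km buffer at the centre of a
  # 3x3-degree grid includes the E/W neighbours but not the N/S ones
  # (planar distance would include all four)
  v <- matrix(c(9, 9, 9, 1, 5, 1, 9, 9, 9), 3, 3) # E/W 9, N/S 1, centre 5
  r <- radiance_raster(v, x0 = 0, y0 = 58.5, pixel = 1, crs = "wgs84")
  got <- median_radiance_in_buffer(r, 1.5, 60, 60)
  expect_equal(got, oracle_median(c(5, 9, 9)))
})
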