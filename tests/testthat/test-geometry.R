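test_that("hex cell assignment is a deterministic function", {
  g <- hex_grid(5)
  set.seed(3)
  q <- sample(-20:20, 50, replace = TRUE)
  r <- sample(-20:20, 50, replace = TRUE)
  ctr <- cell_center(g, q, r)
  got <- assign_cell(g, ctr[, 1], ctr[, 2])
  expect_equal(got[, "q"], q)
  expect_equal(got[, "r"], r)

  x <- runif(100, -50, 50)
  y <- runif(100, -50, 50)
  expect_identical(assign_cell(g, x, y), assign_cell(g, x, y))
  expect_error(assign_cell(g, NaN, 1), "finite")
})

test_that("adjacent hex centres sit one width apart (across flats)", {
  g <- hex_grid(5)
  c0 <- cell_center(g, 0, 0)
  for (nb in list(c(1, 0), c(0, 1), c(-1, 0), c(0, -1), c(1, -1), c(-1, 1))) {
    cn <- cell_center(g, nb[1], nb[2])
    expect_equal(sqrt(sum((cn - c0)^2)), 5, tolerance = 1e-12)
  }
})

test_that("assigned cell is the nearest lattice centre (Voronoi oracle)", {
  g <- hex_grid(4, origin = c(1, -2))
  set.seed(17)
  x <- runif(1000, -30, 30)
  y <- runif(1000, -30, 30)
  got <- assign_cell(g, x, y)
  # enumerate all candidate centres in a window and pick the nearest
  cand <- expand.grid(q = -15:15, r = -15:15)
  ctr <- cell_center(g, cand$q, cand$r)
  for (k in seq_len(1000)) {
    d2 <- (ctr[, 1] - x[k])^2 + (ctr[, 2] - y[k])^2
    best <- which.min(d2)
    expect_equal(unname(got[k, ]), c(cand$q[best], cand$r[best]))
  }
})

test_that("hex assignment partitions a point set", {
  g <- hex_grid(5)
  w <- tiny_world()
  qr <- assign_cell(g, w$dataset$x, w$dataset$y)
  ids <- urbantol:::.cell_id(qr)
  # a point maps to exactly one cell, and re-assignment agrees
  expect_identical(ids, urbantol:::.cell_id(assign_cell(g, w$dataset$x, w$dataset$y)))
  # points inside a cell are closer to their own centre than any neighbour's
  ctr_own <- cell_center(g, qr[, 1], qr[, 2])
  d_own <- sqrt((ctr_own[, 1] - w$dataset$x)^2 + (ctr_own[, 2] - w$dataset$y)^2)
  expect_true(all(d_own <= g$width / sqrt(3) + 1e-9)) # circumradius bound
})

test_that("points are tested against polygons with boundary inclusion", {
  square <- range_poly(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)))
  expect_true(in_range(square, 1, 1)) # centroid
  expect_false(in_range(square, 3, 1)) # outside
  expect_true(in_range(square, 0, 1)) # on an edge
  expect_true(in_range(square, 2, 2)) # on a vertex
  expect_true(in_range(square, 1, 0)) # on the bottom edge

  # a hole: outer square with inner square removed
  holed <- range_poly(list(list(
    rbind(c(0, 0), c(4, 0), c(4, 4), c(0, 4)),
    rbind(c(1, 1), c(3, 1), c(3, 3), c(1, 3))
  )))
  expect_true(in_range(holed, 0.5, 0.5))
  expect_false(in_range(holed, 2, 2)) # inside the hole
})

test_that("ray casting agrees with an independent point-in-polygon oracle", {
  # non-convex polygon; oracle is mgcv::in.out on strictly interior points
  poly <- rbind(
    c(0, 0), c(4, 0), c(4, 3), c(2, 1.5), c(1, 3.2), c(0, 3)
  )
  rp <- range_poly(poly)
  bnd <- rbind(poly, poly[1, ])
  set.seed(31)
  x <- runif(1000, -1, 5)
  y <- runif(1000, -1, 4)
  got <- in_range(rp, x, y)
  oracle <- mgcv::in.out(bnd, cbind(x, y))
  expect_equal(got, as.vector(oracle))
})

test_that("clip_to_range keeps inside points and rejects empty ranges", {
  cl <- base_checklist(3)
  cl$lon <- c(0.5, 5, 1)
  cl$lat <- c(0.5, 5, 0) # third point on the boundary
  square <- range_poly(rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2)))
  out <- clip_to_range(cl, square)
  expect_equal(out$checklist_id, c("C001", "C003"))
  expect_equal(attr(out, "n_removed"), 1)
  expect_error(clip_to_range(cl, structure(list(), class = "range_poly")), "empty")
  expect_error(clip_to_range(cl, list(1)), "empty|invalid")
})

test_that("geojson ranges parse into polygons", {
  rng <- read_geojson_ranges(
    system.file("extdata", "fixture_range.geojson", package = "urbantol")
  )
  expect_s3_class(rng, "range_poly")
  expect_true(in_range(rng, 0.5, 0.5))
  expect_false(in_range(rng, 9.5, 9.5))

  # MultiPolygon in a FeatureCollection
  path <- withr::local_tempfile(fileext = ".geojson")
  writeLines('{"type":"FeatureCollection","features":[{"type":"Feature",
    "geometry":{"type":"MultiPolygon","coordinates":
    [[[[0,0],[1,0],[1,1],[0,1],[0,0]]],[[[5,5],[6,5],[6,6],[5,6],[5,5]]]]}}]}', path)
  rng2 <- read_geojson_ranges(path)
  expect_true(all(in_range(rng2, c(0.5, 5.5), c(0.5, 5.5))))
  expect_false(in_range(rng2, 3, 3))
})
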