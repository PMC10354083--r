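#' Species range polygons
#'
#' A range is a set of polygons, each a list of rings (first ring the outer
#' boundary, any further rings holes); every ring is a two-column matrix of
#' vertex coordinates (closed or open — the closing edge is implied).
#' Containment uses the even-odd rule, so holes need no special casing, and
#' points exactly on a boundary count as inside: whether a checklist sits on
#' the range edge should not depend on floating-point luck.
#'
#' @param rings a ring (two-column matrix), a polygon (list of rings), or a
#'   list of polygons.
#' @return An object of class `range_poly` (a list of polygons).
#' @export
range_poly <- function(rings) {
  if (is.matrix(rings)) rings <- list(list(rings))
  if (is.list(rings) && length(rings) && is.matrix(rings[[1]])) {
    rings <- list(rings)
  }
  for (poly in rings) {
    for (ring in poly) {
      if (!is.matrix(ring) || ncol(ring) != 2 || nrow(ring) < 3) {
        stop("each ring must be a two-column matrix with >= 3 vertices",
          call. = FALSE
        )
      }
    }
  }
  structure(rings, class = "range_poly")
}

#' Read range polygons from GeoJSON
#'
#' Accepts a GeoJSON `Polygon`, `MultiPolygon`, `Feature` or
#' `FeatureCollection` and returns the union of all polygon geometries it
#' contains.
#'
#' @param path path to a GeoJSON file.
#' @return A [range_poly()].
#' @export
read_geojson_ranges <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  polys <- list()
  grab <- function(geom) {
    ring_mat <- function(ring) {
      do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    }
    if (geom$type == "Polygon") {
      polys[[length(polys) + 1]] <<- lapply(geom$coordinates, ring_mat)
    } else if (geom$type == "MultiPolygon") {
      for (pp in geom$coordinates) {
        polys[[length(polys) + 1]] <<- lapply(pp, ring_mat)
      }
    }
  }
  walk <- function(obj) {
    if (is.null(obj$type)) {
      return()
    }
    switch(obj$type,
      FeatureCollection = lapply(obj$features, walk),
      Feature = walk(obj$geometry),
      grab(obj)
    )
    invisible()
  }
  walk(g)
  if (!length(polys)) stop("no polygon geometry found in ", path, call. = FALSE)
  range_poly(polys)
}

# Is (px, py) inside (or on the border of) a single ring? Even-odd
# ray-casting with an explicit on-segment test so boundary points are
# always inside.
.point_in_ring <- function(px, py, ring) {
  n <- nrow(ring)
  xs <- ring[, 1]
  ys <- ring[, 2]
  # drop an explicit closing vertex
  if (xs[1] == xs[n] && ys[1] == ys[n]) {
    n <- n - 1
    xs <- xs[seq_len(n)]
    ys <- ys[seq_len(n)]
  }
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    x1 <- xs[j]; y1 <- ys[j]; x2 <- xs[i]; y2 <- ys[i]
    # on-segment: collinear and within the bounding box
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    if (cross == 0 &&
      px >= min(x1, x2) && px <= max(x1, x2) &&
      py >= min(y1, y2) && py <= max(y1, y2)) {
      return(TRUE)
    }
    if ((y1 > py) != (y2 > py)) {
      xint <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
      if (px < xint) inside <- !inside
    }
    j <- i
  }
  inside
}

#' Test points against range polygons
#'
#' @param ranges a [range_poly()].
#' @param x,y point coordinates (same CRS as the polygons).
#' @return Logical vector: inside (or on the boundary of) any polygon.
#' @export
in_range <- function(ranges, x, y) {
  stopifnot(inherits(ranges, "range_poly"))
  vapply(seq_along(x), function(k) {
    for (poly in ranges) {
      crossings <- 0L
      for (ring in poly) {
        res <- .point_in_ring(x[k], y[k], ring)
        if (isTRUE(res)) crossings <- crossings + 1L
      }
      # even-odd across rings: inside outer but not in a hole
      if (crossings %% 2L == 1L) {
        return(TRUE)
      }
    }
    FALSE
  }, logical(1))
}

#' Clip checklists to a species range
#'
#' Drops checklists whose location falls outside the species' known range,
#' the standard guard against vagrant or misidentified records. Points on
#' the range boundary are retained.
#'
#' @param checklists a checklist data frame with `lon`/`lat` columns.
#' @param ranges a [range_poly()] in the same CRS as the checklist
#'   coordinates.
#' @return The surviving subset of `checklists`, with an attribute
#'   `n_removed`.
#' @export
clip_to_range <- function(checklists, ranges) {
  if (!inherits(ranges, "range_poly") || !length(ranges)) {
    stop("empty or invalid range polygon set", call. = FALSE)
  }
  keep <- in_range(ranges, checklists$lon, checklists$lat)
  out <- checklists[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}
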