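#' Radiance raster objects
#'
#' A minimal single-band raster container for night-time-lights radiance
#' (nW cm^-2 sr^-1). Values are stored as a numeric matrix with row 1 the
#' southernmost row, so the centre of cell `[i, j]` sits at
#' `(x0 + (j - 0.5) * pixel, y0 + (i - 0.5) * pixel)`. Missing pixels are
#' `NA` in memory and written as the `nodata` marker on disk.
#'
#' @param values numeric matrix (rows = south to north, cols = west to east);
#'   all finite values must be non-negative.
#' @param x0,y0 coordinates of the lower-left corner of the grid (km for
#'   `crs = "planar_km"`, degrees for `crs = "wgs84"`).
#' @param pixel pixel edge length (> 0), in the CRS units.
#' @param nodata marker value used on disk for missing pixels.
#' @param crs `"planar_km"` (synthetic worlds, exact geometry) or `"wgs84"`.
#' @return An object of class `radiance_raster`.
#' @seealso [read_ascii_raster()], [median_radiance_in_buffer()]
#' @export
radiance_raster <- function(values, x0 = 0, y0 = 0, pixel = 1,
                            nodata = -9999, crs = c("planar_km", "wgs84")) {
  crs <- match.arg(crs)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.finite(pixel) || pixel <= 0) {
    stop("pixel size must be a positive number", call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE)) {
    stop("radiance values must be non-negative (use NA for nodata)",
      call. = FALSE
    )
  }
  structure(
    list(
      values = values, x0 = x0, y0 = y0, pixel = pixel,
      ncols = ncol(values), nrows = nrow(values),
      nodata = nodata, crs = crs
    ),
    class = "radiance_raster"
  )
}

#' @export
print.radiance_raster <- function(x, ...) {
  rng <- range(x$values, na.rm = TRUE)
  cat(
    sprintf(
      "<radiance_raster> %d x %d pixels, pixel %g (%s)\n  origin (%g, %g), radiance %.4g..%.4g, %d nodata\n",
      x$nrows, x$ncols, x$pixel, x$crs, x$x0, x$y0,
      rng[1], rng[2], sum(is.na(x$values))
    )
  )
  invisible(x)
}

# pixel-centre coordinate vectors
.raster_xc <- function(r) r$x0 + (seq_len(r$ncols) - 0.5) * r$pixel
.raster_yc <- function(r) r$y0 + (seq_len(r$nrows) - 0.5) * r$pixel

.raster_extent <- function(r) {
  c(
    xmin = r$x0, xmax = r$x0 + r$ncols * r$pixel,
    ymin = r$y0, ymax = r$y0 + r$nrows * r$pixel
  )
}

.same_geometry <- function(a, b) {
  isTRUE(all.equal(
    c(a$x0, a$y0, a$pixel, a$ncols, a$nrows),
    c(b$x0, b$y0, b$pixel, b$ncols, b$nrows)
  )) && a$crs == b$crs
}

#' Read / write a plain-text radiance grid
#'
#' The on-disk format is the ESRI ASCII grid: a six-line header (`ncols`,
#' `nrows`, `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`) followed by
#' `nrows` whitespace-separated rows, northernmost row first. A seventh,
#' optional header line `crs planar_km|wgs84` carries the coordinate system;
#' it defaults to `wgs84` when absent.
#'
#' @param path file path.
#' @return `read_ascii_raster()` returns a [radiance_raster()];
#'   `write_ascii_raster()` returns `path` invisibly.
#' @export
read_ascii_raster <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    hdr[[tolower(kv[1])]] <- kv[2]
    i <- i + 1
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  miss <- setdiff(need, names(hdr))
  if (length(miss)) {
    stop("raster header missing field(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  nodata <- as.numeric(hdr[["nodata_value"]] %||% "-9999")
  vals <- scan(
    text = paste(lines[i:length(lines)], collapse = "\n"),
    quiet = TRUE
  )
  nc <- as.integer(hdr$ncols)
  nr <- as.integer(hdr$nrows)
  if (length(vals) != nc * nr) {
    stop("raster body has ", length(vals), " values, expected ", nc * nr,
      call. = FALSE
    )
  }
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m <- m[nr:1, , drop = FALSE] # file stores north first; flip to south-first
  m[m == nodata] <- NA_real_
  radiance_raster(m,
    x0 = as.numeric(hdr$xllcorner), y0 = as.numeric(hdr$yllcorner),
    pixel = as.numeric(hdr$cellsize), nodata = nodata,
    crs = hdr$crs %||% "wgs84"
  )
}

#' @param raster a [radiance_raster()].
#' @rdname read_ascii_raster
#' @export
write_ascii_raster <- function(raster, path) {
  stopifnot(inherits(raster, "radiance_raster"))
  m <- raster$values
  m[is.na(m)] <- raster$nodata
  m <- m[raster$nrows:1, , drop = FALSE]
  hdr <- c(
    paste("ncols", raster$ncols),
    paste("nrows", raster$nrows),
    paste("xllcorner", format(raster$x0, digits = 15)),
    paste("yllcorner", format(raster$y0, digits = 15)),
    paste("cellsize", format(raster$pixel, digits = 15)),
    paste("NODATA_value", format(raster$nodata, digits = 15)),
    paste("crs", raster$crs)
  )
  body <- apply(m, 1, function(row) paste(format(row, digits = 15), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Per-pixel median composite of a raster stack
#'
#' Collapses a stack of co-registered monthly radiance rasters into a single
#' raster by taking the median of each pixel across layers, ignoring missing
#' values. A pixel that is missing in every layer stays missing. The median
#' is the robust choice for combining monthly night-lights layers: transient
#' sources (fires, flaring) affect few months and do not move it.
#'
#' @param stack a list of [radiance_raster()] objects sharing grid geometry.
#' @return A single [radiance_raster()].
#' @export
composite_median_raster <- function(stack) {
  if (!length(stack)) stop("empty raster stack", call. = FALSE)
  base <- stack[[1]]
  for (r in stack[-1]) {
    if (!.same_geometry(base, r)) {
      stop("raster stack layers do not share grid geometry", call. = FALSE)
    }
  }
  arr <- vapply(stack, function(r) r$values, base$values)
  dim(arr) <- c(base$nrows * base$ncols, length(stack))
  med <- apply(arr, 1, stats::median, na.rm = TRUE)
  med[is.nan(med)] <- NA_real_
  out <- base
  out$values <- matrix(med, base$nrows, base$ncols)
  out
}

#' Median radiance within a buffer of a point
#'
#' Returns the median radiance over all non-missing pixels whose centres lie
#' within `radius_km` of the point — the urbanisation covariate attached to
#' each checklist. For even pixel counts the usual mean of the two middle
#' values is returned. Points and rasters in WGS84 are measured with
#' great-circle (haversine) distances; planar rasters use Euclidean
#' distance, which is exact for the synthetic worlds.
#'
#' @param raster a [radiance_raster()].
#' @param x,y point coordinates (vectors allowed; degrees lon/lat for WGS84
#'   rasters, km otherwise).
#' @param radius_km buffer radius in kilometres (default 5, the radius used
#'   for checklist-level radiance extraction).
#' @return Numeric vector of median radiance values, one per point.
#' @export
median_radiance_in_buffer <- function(raster, x, y, radius_km = 5) {
  stopifnot(inherits(raster, "radiance_raster"))
  if (!is.finite(radius_km) || radius_km <= 0) {
    stop("radius_km must be positive", call. = FALSE)
  }
  ext <- .raster_extent(raster)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite point coordinates", call. = FALSE)
  }
  outside <- x < ext["xmin"] | x > ext["xmax"] | y < ext["ymin"] | y > ext["ymax"]
  if (any(outside)) {
    stop(sum(outside), " point(s) outside the raster extent", call. = FALSE)
  }
  xc <- .raster_xc(raster)
  yc <- .raster_yc(raster)
  wgs <- raster$crs == "wgs84"
  # degrees subtended by the radius, for the bounding-box prefilter
  out <- numeric(length(x))
  for (k in seq_along(x)) {
    if (wgs) {
      dlat <- radius_km / .KM_PER_DEG
      dlon <- radius_km / (.KM_PER_DEG * max(cos(y[k] * pi / 180), 1e-8))
      jj <- which(xc >= x[k] - dlon & xc <= x[k] + dlon)
      ii <- which(yc >= y[k] - dlat & yc <= y[k] + dlat)
    } else {
      jj <- which(xc >= x[k] - radius_km & xc <= x[k] + radius_km)
      ii <- which(yc >= y[k] - radius_km & yc <= y[k] + radius_km)
    }
    if (!length(ii) || !length(jj)) {
      stop("no raster pixels within the buffer at point ", k, call. = FALSE)
    }
    sub <- raster$values[ii, jj, drop = FALSE]
    if (wgs) {
      pts <- cbind(rep(xc[jj], each = length(ii)), rep(yc[ii], length(jj)))
      d <- geosphere::distHaversine(pts, c(x[k], y[k])) / 1000
      keep <- d <= radius_km
    } else {
      dx2 <- (xc[jj] - x[k])^2
      dy2 <- (yc[ii] - y[k])^2
      keep <- outer(dy2, dx2, `+`) <= radius_km^2
    }
    vals <- sub[keep]
    vals <- vals[!is.na(vals)]
    if (!length(vals)) {
      stop("no non-missing pixels within the buffer at point ", k,
        call. = FALSE
      )
    }
    out[k] <- stats::median(vals)
  }
  out
}
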