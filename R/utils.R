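#' Derive a reproducible child seed from a master seed
#'
#' Deterministically hashes a master seed together with an arbitrary set of
#' labels (species codes, run indices, stage names) into a new integer seed.
#' This is how a single pipeline seed fans out into independent streams for
#' the raster, the checklist draw, and each of the per-species resampling
#' runs: two streams differ in at least one label, so they get unrelated
#' seeds, while the same labels always reproduce the same stream.
#'
#' The hash is a multiplicative congruential mix modulo 2^31 - 1, applied to
#' the UTF-8 bytes of each label, so results are identical across platforms.
#'
#' @importFrom stats .lm.fit
#' @param master integer master seed.
#' @param ... further labels (character or numeric scalars) identifying the
#'   stream.
#' @return A single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(42, "checklists")
#' derive_seed(42, "spA", 7)
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1 (prime)
  h <- as.numeric(master) %% m
  for (part in list(...)) {
    bytes <- if (is.character(part)) {
      as.numeric(utf8ToInt(part))
    } else {
      # split a numeric into digits so all arithmetic stays < 2^53
      as.numeric(utf8ToInt(format(part, scientific = FALSE)))
    }
    for (b in bytes) h <- (h * 69069 + b + 1) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# Run `expr` under `seed` without disturbing the caller's RNG state.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Kilometres per degree of latitude on the authalic sphere; used by the
# simple local equirectangular projection for WGS84 inputs.
.KM_PER_DEG <- 6371.0088 * pi / 180

#' Project lon/lat to local planar kilometres
#'
#' Equirectangular projection about a reference point: metres-true along the
#' reference parallel and the meridian. Adequate at the scale of a buffer or
#' a regional grid; an equal-area projection should be substituted for
#' continental-scale gridding.
#'
#' @param lon,lat coordinates in degrees (WGS84).
#' @param ref numeric length-2, reference `c(lon, lat)` mapped to (0, 0).
#' @return A two-column matrix of x/y in kilometres.
#' @export
project_lonlat <- function(lon, lat, ref) {
  cbind(
    x = (lon - ref[1]) * .KM_PER_DEG * cos(ref[2] * pi / 180),
    y = (lat - ref[2]) * .KM_PER_DEG
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
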