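#' Week-of-year for stratification
#'
#' Weeks are 7-day blocks counted from 1 January: week =
#' `floor((day_of_year - 1) / 7) + 1`, with days 365/366 folded into week
#' 52 so every year has exactly 52 strata.
#'
#' @param dates a `Date` vector.
#' @return Integer weeks in `[1, 52]`.
#' @export
week_of_year <- function(dates) {
  doy <- as.integer(format(dates, "%j"))
  pmin((doy - 1L) %/% 7L + 1L, 52L)
}

# Attach stratification fields (x/y analysis coordinates, cell id, year,
# week, detection flag) to a species dataset.
add_strata <- function(dataset, grid, week_scheme = c("per_year", "pooled")) {
  week_scheme <- match.arg(week_scheme)
  qr <- assign_cell(grid, dataset$x, dataset$y, lonlat = FALSE)
  dataset$cell <- .cell_id(qr)
  dataset$year <- as.integer(format(dataset$date, "%Y"))
  dataset$week <- week_of_year(dataset$date)
  dataset$detected <- dataset$count >= 1
  yr <- if (week_scheme == "per_year") dataset$year else 0L
  dataset$stratum <- paste(dataset$cell, yr, dataset$week, sep = "|")
  dataset
}

#' Spatiotemporal class-balanced subsampling
#'
#' Thins a species dataset to at most one checklist per (grid cell, year,
#' week) stratum *per detection class*: detections and non-detections are
#' sampled independently, so thinning the spatial and temporal clustering
#' of effort does not also discard most of the (rarer) detections. Within
#' a stratum-class the retained checklist is chosen uniformly at random;
#' the draw is a pure function of `seed`, and re-applying the subsampler
#' to its own output returns it unchanged (every stratum then holds a
#' single candidate).
#'
#' @param dataset a species dataset with `stratum` and `detected` columns
#'   (see [species_dataset()] / `add_strata`).
#' @param seed integer seed for the uniform within-stratum draw.
#' @param per_class sample detections and non-detections independently
#'   (default); `FALSE` keeps one checklist per stratum regardless of
#'   class.
#' @return A list with `data` (the retained rows), `retained` (their row
#'   indices in `dataset`), `seed`, and `n_strata`.
#' @export
spatiotemporal_subsample <- function(dataset, seed, per_class = TRUE) {
  if (is.null(dataset$stratum) || is.null(dataset$detected)) {
    stop("dataset lacks stratum/detected columns; build it with species_dataset()",
      call. = FALSE
    )
  }
  key <- if (per_class) {
    paste(dataset$stratum, as.integer(dataset$detected), sep = "|")
  } else {
    dataset$stratum
  }
  u <- local_seed(seed, stats::runif(nrow(dataset)))
  ord <- order(key, u, method = "radix")
  keep_sorted <- !duplicated(key[ord])
  retained <- sort(ord[keep_sorted])
  list(
    data = dataset[retained, , drop = FALSE],
    retained = retained,
    seed = seed,
    n_strata = length(unique(key))
  )
}

#' Species inclusion rule
#'
#' A species enters the analysis only if, after filtering but before
#' subsampling, at least `min_detections` checklists record it (count >=
#' 1). Below that, the resampled radiance coefficient is too unstable to
#' rank.
#'
#' @param dataset a species dataset with a `count` column.
#' @param min_detections inclusion threshold (default 1000, boundary
#'   inclusive: exactly 1000 detections is included).
#' @return A list with `include` (logical) and `n_detections`.
#' @export
species_inclusion_check <- function(dataset, min_detections = 1000) {
  n_det <- sum(dataset$count >= 1, na.rm = TRUE)
  list(include = n_det >= min_detections, n_detections = n_det)
}
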