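#' Resampling-averaged urban tolerance index
#'
#' The core estimator: repeat the subsample-and-fit cycle `n_runs` times
#' (default 100), each run drawing an independent spatiotemporal subsample
#' and refitting the abundance model, and average the radiance coefficient
#' across runs. The spread of the run estimates reflects the uncertainty
#' introduced by random within-cell sampling; the 95% interval over runs is
#' reported alongside the mean. A positive index classifies the species as
#' urban tolerant, a negative one as urban avoidant.
#'
#' Species failing [species_inclusion_check()] return an exclusion result
#' rather than an error; runs whose fit does not converge are dropped and
#' counted, and the estimate is declared unstable (an error) if fewer than
#' `min_converged_frac` of runs survive.
#'
#' The smooth bases are anchored on the full species dataset once and
#' row-subset per run, so all runs share identical basis functions and
#' differ only through the subsample — and the loop stays cheap.
#'
#' @param dataset a [species_dataset()] (must carry strata; see `grid`).
#' @param grid optional [hex_grid()]; required if `dataset` lacks stratum
#'   columns.
#' @param smooths list of [smooth_spec()]s for the abundance model.
#' @param n_runs number of subsample-and-fit cycles.
#' @param master_seed integer; per-run seeds derive from
#'   `derive_seed(master_seed, species, run)`.
#' @param min_detections inclusion threshold on detection checklists.
#' @param ci_type `"percentile"` (2.5/97.5 percentiles of run estimates,
#'   default) or `"normal"` (mean +/- 1.96 sd).
#' @param min_converged_frac minimum fraction of converged runs.
#' @param per_class,log_alan,min_rows passed to the subsampler / model.
#' @return An object of class `tolerance_estimate` (or
#'   `tolerance_exclusion` when the species fails inclusion): species
#'   code, `runs` (the per-run coefficients), `index`, `ci`,
#'   `classification`, counts of runs attempted/converged.
#' @export
compute_tolerance_index <- function(dataset, grid = NULL,
                                    smooths = default_smooths(),
                                    n_runs = 100, master_seed = 1,
                                    min_detections = 1000,
                                    ci_type = c("percentile", "normal"),
                                    min_converged_frac = 0.5,
                                    per_class = TRUE, log_alan = FALSE,
                                    min_rows = 100) {
  ci_type <- match.arg(ci_type)
  species <- dataset$species_code[1] %||% "species"
  if (is.null(dataset$stratum)) {
    if (is.null(grid)) {
      stop("dataset lacks strata; supply a hex_grid", call. = FALSE)
    }
    dataset <- add_strata(dataset, grid)
  }
  incl <- species_inclusion_check(dataset, min_detections)
  if (!incl$include) {
    return(structure(
      list(
        species = species, included = FALSE,
        n_detections = incl$n_detections, min_detections = min_detections
      ),
      class = "tolerance_exclusion"
    ))
  }

  # one design over the full dataset; runs subset its rows
  des <- build_gam_design(dataset, smooths, log_alan = log_alan)
  y_all <- dataset$count[des$rows]
  d_used <- dataset[des$rows, , drop = FALSE]

  # every run warm-starts from one full-data fit: faster, and runs that
  # happen to draw the same subsample produce bit-identical estimates
  init <- tryCatch(
    fit_nb_glm(des$X, y_all)$coefficients,
    error = function(e) NULL
  )
  runs <- rep(NA_real_, n_runs)
  for (r in seq_len(n_runs)) {
    seed_r <- derive_seed(master_seed, species, r)
    sub <- spatiotemporal_subsample(d_used, seed_r, per_class = per_class)
    idx <- sub$retained
    if (length(idx) < min_rows || all(y_all[idx] == 0)) next
    fit <- tryCatch(
      fit_nb_glm(des$X[idx, , drop = FALSE], y_all[idx], init = init),
      error = function(e) NULL
    )
    if (is.null(fit) || !fit$converged) next
    runs[r] <- unname(fit$coefficients["alan"])
  }

  ok <- !is.na(runs)
  if (mean(ok) < min_converged_frac) {
    stop(
      "unstable estimate for ", species, ": only ", sum(ok), "/", n_runs,
      " runs converged",
      call. = FALSE
    )
  }
  est <- runs[ok]
  index <- mean(est)
  ci <- if (ci_type == "percentile") {
    unname(stats::quantile(est, c(0.025, 0.975)))
  } else {
    index + c(-1, 1) * 1.96 * stats::sd(est)
  }
  classification <- if (index > 0) {
    "tolerant"
  } else if (index < 0) {
    "avoidant"
  } else {
    "tolerant-boundary"
  }
  structure(
    list(
      species = species, included = TRUE, runs = runs, index = index,
      ci_low = ci[1], ci_high = ci[2], ci_type = ci_type,
      classification = classification,
      n_runs = n_runs, n_converged = sum(ok),
      n_detections = incl$n_detections, master_seed = master_seed
    ),
    class = "tolerance_estimate"
  )
}

#' @export
print.tolerance_estimate <- function(x, ...) {
  cat(sprintf(
    "Urban tolerance index for %s: %.4f [%.4f, %.4f] (%s CI over %d/%d runs) -> %s\n",
    x$species, x$index, x$ci_low, x$ci_high, x$ci_type,
    x$n_converged, x$n_runs, x$classification
  ))
  invisible(x)
}

#' @export
print.tolerance_exclusion <- function(x, ...) {
  cat(sprintf(
    "%s excluded: %d detection checklists (< %d required)\n",
    x$species, x$n_detections, x$min_detections
  ))
  invisible(x)
}

#' Rank species by urban tolerance
#'
#' Orders tolerance estimates by decreasing index (ties broken by species
#' code), the ranking displayed in a tolerance ladder plot, and counts the
#' tolerant/avoidant split. Exclusion results are dropped with a note.
#'
#' @param estimates a list of `tolerance_estimate` (and possibly
#'   `tolerance_exclusion`) objects.
#' @return A data frame of class `tolerance_ranking` with columns species,
#'   index, ci_low, ci_high, classification, n_converged; attributes
#'   `n_tolerant`, `n_avoidant`, `excluded` (species codes).
#' @export
rank_species <- function(estimates) {
  if (inherits(estimates, "tolerance_estimate")) estimates <- list(estimates)
  if (!length(estimates)) stop("no estimates to rank", call. = FALSE)
  excl <- vapply(estimates, inherits, logical(1), "tolerance_exclusion")
  excluded <- vapply(estimates[excl], `[[`, character(1), "species")
  estimates <- estimates[!excl]
  if (!length(estimates)) stop("no included species to rank", call. = FALSE)
  df <- data.frame(
    species = vapply(estimates, `[[`, character(1), "species"),
    index = vapply(estimates, `[[`, numeric(1), "index"),
    ci_low = vapply(estimates, `[[`, numeric(1), "ci_low"),
    ci_high = vapply(estimates, `[[`, numeric(1), "ci_high"),
    classification = vapply(estimates, `[[`, character(1), "classification"),
    n_converged = vapply(estimates, `[[`, numeric(1), "n_converged"),
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$index, df$species), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
    n_tolerant = sum(df$classification == "tolerant"),
    n_avoidant = sum(df$classification == "avoidant"),
    excluded = excluded,
    class = c("tolerance_ranking", "data.frame")
  )
}

#' @export
print.tolerance_ranking <- function(x, ...) {
  cat(sprintf(
    "Urban tolerance ranking: %d species (%d tolerant, %d avoidant)\n",
    nrow(x), attr(x, "n_tolerant"), attr(x, "n_avoidant")
  ))
  print.data.frame(x, digits = 4)
  if (length(attr(x, "excluded"))) {
    cat("Excluded:", paste(attr(x, "excluded"), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Dot-and-error-bar plot of a tolerance ranking
#'
#' One point per species at its index with a horizontal 95% interval over
#' the resampling runs; tolerant species in blue, avoidant in orange, with
#' a reference line at zero.
#'
#' @param x a `tolerance_ranking`.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.tolerance_ranking <- function(x, ...) {
  n <- nrow(x)
  ypos <- rev(seq_len(n))
  cols <- ifelse(x$index > 0, "#2166ac", "#e08214")
  op <- graphics::par(mar = c(4, 8, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(
    x$index, ypos,
    xlim = range(c(x$ci_low, x$ci_high, 0)),
    pch = 19, col = cols, yaxt = "n",
    xlab = "Urban tolerance index (radiance coefficient)", ylab = "", ...
  )
  graphics::segments(x$ci_low, ypos, x$ci_high, ypos, col = cols)
  graphics::abline(v = 0, lty = 2, col = "grey40")
  graphics::axis(2, at = ypos, labels = x$species, las = 1, cex.axis = 0.7)
  invisible(x)
}
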