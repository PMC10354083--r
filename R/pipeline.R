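#' Assemble a per-species analysis dataset
#'
#' Joins one species' observations onto the (filtered, range-clipped)
#' checklist table, producing one row per checklist with the count
#' response (0 on complete checklists without the species), the buffer-
#' median radiance covariate, analysis coordinates, and the subsampling
#' strata. Presence markers (`"X"` counts) are resolved by `x_handling`:
#' mapped to count 1 — the minimal abundance consistent with a detection —
#' or dropped.
#'
#' @param checklists checklist table (after filtering/clipping).
#' @param observations observation table (`checklist_id`, `species_code`,
#'   `count`, `count_raw`).
#' @param species species code to extract.
#' @param raster a [radiance_raster()] for the radiance covariate.
#' @param grid a [hex_grid()] for the strata.
#' @param buffer_radius_km radiance buffer radius (default 5 km).
#' @param x_handling `"one"` (presence marker counts as 1, default) or
#'   `"drop"` (discard those checklists).
#' @param week_scheme `"per_year"` strata (default) or `"pooled"` weeks
#'   across years.
#' @return A species dataset: data frame with covariates `x`, `y`,
#'   `day_of_year`, `duration_min`, `distance_km`, `n_observers`,
#'   `time_started`, `alan`, response `count`, and stratum fields.
#' @export
species_dataset <- function(checklists, observations, species, raster, grid,
                            buffer_radius_km = 5,
                            x_handling = c("one", "drop"),
                            week_scheme = c("per_year", "pooled")) {
  x_handling <- match.arg(x_handling)
  crs <- attr(checklists, "crs") %||% "wgs84"
  obs <- observations[observations$species_code == species, , drop = FALSE]
  m <- match(checklists$checklist_id, obs$checklist_id)
  count <- obs$count[m]
  raw <- obs$count_raw[m]
  is_x <- !is.na(m) & is.na(count)
  if (x_handling == "one") {
    count[is_x] <- 1
  }
  count[is.na(m)] <- 0
  d <- checklists
  d$species_code <- species
  d$count <- count
  d$count_raw <- ifelse(is.na(m), "0", raw)
  if (x_handling == "drop" && any(is_x)) {
    d <- d[!is_x, , drop = FALSE]
  }
  if (crs == "wgs84") {
    ref <- grid$ref_lonlat %||% c(mean(d$lon), mean(d$lat))
    p <- project_lonlat(d$lon, d$lat, ref)
    d$x <- p[, 1]
    d$y <- p[, 2]
  } else {
    d$x <- d$lon
    d$y <- d$lat
  }
  d$day_of_year <- as.integer(format(d$date, "%j"))
  d$alan <- median_radiance_in_buffer(raster, d$lon, d$lat, buffer_radius_km)
  d <- add_strata(d, grid, week_scheme = match.arg(week_scheme))
  rownames(d) <- NULL
  d
}

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the standard
#' defaults: 300-min and 5-km effort caps, the 2010-01-01..2021-06-30
#' window, a 5-km hexagonal grid, a 5-km radiance buffer, 100 resampling
#' runs, the 1000-detection inclusion rule, and the documented policy
#' switches (presence-marker handling, week scheme, CI type, per-class
#' subsampling, log-radiance).
#'
#' @param max_duration_min,max_distance_km,date_start,date_end checklist
#'   filter thresholds (see [filter_rules()]).
#' @param grid_width_km hexagonal cell width (across flats).
#' @param buffer_radius_km radiance buffer radius.
#' @param n_runs resampling runs per species.
#' @param min_detections species inclusion threshold.
#' @param master_seed seed from which all run seeds derive.
#' @param ci_type,x_handling,week_scheme,per_class,log_alan policy
#'   switches (see the stage functions).
#' @param min_rows insufficient-data floor per fit.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(max_duration_min = 300, max_distance_km = 5,
                            date_start = "2010-01-01", date_end = "2021-06-30",
                            grid_width_km = 5, buffer_radius_km = 5,
                            n_runs = 100, min_detections = 1000,
                            master_seed = 1,
                            ci_type = c("percentile", "normal"),
                            x_handling = c("one", "drop"),
                            week_scheme = c("per_year", "pooled"),
                            per_class = TRUE, log_alan = FALSE,
                            min_rows = 100) {
  stopifnot(
    max_duration_min > 0, max_distance_km > 0, grid_width_km > 0,
    buffer_radius_km > 0, n_runs >= 1, min_detections >= 0
  )
  structure(
    list(
      rules = filter_rules(max_duration_min, max_distance_km, date_start, date_end),
      grid_width_km = grid_width_km, buffer_radius_km = buffer_radius_km,
      n_runs = n_runs, min_detections = min_detections,
      master_seed = master_seed, ci_type = match.arg(ci_type),
      x_handling = match.arg(x_handling), week_scheme = match.arg(week_scheme),
      per_class = per_class, log_alan = log_alan, min_rows = min_rows
    ),
    class = "pipeline_config"
  )
}

#' Run the full urban-tolerance pipeline
#'
#' Executes filter -> range clip -> radiance extraction -> per-species
#' inclusion -> resampled tolerance index -> ranking -> trait regression,
#' and returns every stage output plus a manifest (config, seed, package
#' version) that suffices to re-run the analysis identically. With a seed
#' fixed, the output bundle is a pure function of the inputs. Species for
#' which no checklists pass inclusion are reported in the ranking
#' attributes rather than aborting the run; a run in which *no* species
#' passes returns an empty estimates list with a message.
#'
#' @param checklists,observations tables from [read_checklists()] (or the
#'   synthetic generators).
#' @param raster a [radiance_raster()].
#' @param species character vector of species codes to score; default all
#'   codes present in `observations`.
#' @param ranges optional [range_poly()] (or named list of them, one per
#'   species code) for range clipping.
#' @param traits optional trait table; when given and at least 10 species
#'   are scored, the trait regression is fitted.
#' @param config a [pipeline_config()].
#' @param outdir optional directory; stage outputs are written there as
#'   CSV (filter report, index table, trait summary, manifest as JSON).
#' @param verbose print per-stage counts.
#' @return A list of class `urbantol_run`: `filter_report`, `estimates`
#'   (per-species tolerance objects), `ranking`, `trait_model` (or NULL),
#'   `manifest`.
#' @export
run_pipeline <- function(checklists, observations, raster, species = NULL,
                         ranges = NULL, traits = NULL,
                         config = pipeline_config(), outdir = NULL,
                         verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  n_in <- nrow(checklists)
  flt <- filter_checklists(checklists, config$rules)
  say(
    "filter: %d checklists in, %d retained", n_in,
    attr(flt$report, "retained")
  )
  cl <- flt$checklists

  crs <- attr(checklists, "crs") %||% "wgs84"
  grid <- if (crs == "wgs84") {
    hex_grid(config$grid_width_km, ref_lonlat = c(mean(cl$lon), mean(cl$lat)))
  } else {
    hex_grid(config$grid_width_km)
  }

  if (is.null(species)) species <- sort(unique(observations$species_code))
  estimates <- list()
  for (sp in species) {
    cl_sp <- cl
    rng <- if (inherits(ranges, "range_poly")) ranges else ranges[[sp]]
    if (!is.null(rng)) {
      cl_sp <- clip_to_range(cl_sp, rng)
      say("%s: range clip removed %d checklists", sp, attr(cl_sp, "n_removed"))
    }
    ds <- species_dataset(
      cl_sp, observations, sp, raster, grid,
      buffer_radius_km = config$buffer_radius_km,
      x_handling = config$x_handling, week_scheme = config$week_scheme
    )
    est <- compute_tolerance_index(
      ds,
      smooths = default_smooths(), n_runs = config$n_runs,
      master_seed = config$master_seed,
      min_detections = config$min_detections, ci_type = config$ci_type,
      per_class = config$per_class, log_alan = config$log_alan,
      min_rows = config$min_rows
    )
    if (inherits(est, "tolerance_exclusion")) {
      say(
        "%s: excluded (%d detection checklists < %d)",
        sp, est$n_detections, config$min_detections
      )
    } else {
      say(
        "%s: index %.4f [%.4f, %.4f], %d/%d runs", sp, est$index,
        est$ci_low, est$ci_high, est$n_converged, est$n_runs
      )
    }
    estimates[[sp]] <- est
  }

  included <- Filter(function(e) inherits(e, "tolerance_estimate"), estimates)
  ranking <- NULL
  if (length(included)) {
    ranking <- rank_species(estimates)
  } else {
    say("no species passed the inclusion rule; empty index table")
  }

  tm <- NULL
  if (!is.null(traits) && !is.null(ranking) && nrow(ranking) >= 10) {
    tr <- traits[traits$species_code %in% ranking$species, , drop = FALSE]
    tm <- fit_trait_model(ranking, tr)
    say("trait model: R^2 = %.4f on %d species", tm$r_squared, nrow(tm$data))
  }

  manifest <- list(
    package = "urbantol",
    version = as.character(utils::packageVersion("urbantol")),
    config = unclass(config)[setdiff(names(config), "rules")],
    rules = lapply(config$rules, as.character),
    master_seed = config$master_seed,
    n_checklists_in = n_in,
    n_checklists_retained = attr(flt$report, "retained"),
    species = species
  )

  out <- structure(
    list(
      filter_report = flt$report, estimates = estimates, ranking = ranking,
      trait_model = tm, manifest = manifest
    ),
    class = "urbantol_run"
  )
  if (!is.null(outdir)) write_run(out, outdir)
  out
}

#' @export
print.urbantol_run <- function(x, ...) {
  cat("Urban tolerance pipeline run\n")
  print(x$filter_report)
  if (!is.null(x$ranking)) print(x$ranking) else cat("No species included.\n")
  if (!is.null(x$trait_model)) print(x$trait_model)
  invisible(x)
}

#' Write pipeline outputs to a directory
#'
#' Emits the filter report, the per-species index table and run-level
#' estimates, the trait-model summary tables, and a JSON manifest.
#'
#' @param run an `urbantol_run`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(run$filter_report, file.path(outdir, "filter_report.csv"),
    row.names = FALSE
  )
  if (!is.null(run$ranking)) {
    utils::write.csv(run$ranking, file.path(outdir, "tolerance_index.csv"),
      row.names = FALSE
    )
    runs <- do.call(rbind, lapply(
      Filter(function(e) inherits(e, "tolerance_estimate"), run$estimates),
      function(e) {
        data.frame(species = e$species, run = seq_along(e$runs), beta_alan = e$runs)
      }
    ))
    utils::write.csv(runs, file.path(outdir, "run_estimates.csv"),
      row.names = FALSE
    )
  }
  if (!is.null(run$trait_model)) {
    utils::write.csv(run$trait_model$coefficients,
      file.path(outdir, "trait_model_coefficients.csv"),
      row.names = FALSE
    )
    utils::write.csv(run$trait_model$ftests,
      file.path(outdir, "trait_model_ftests.csv"),
      row.names = FALSE
    )
  }
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, force = TRUE
  )
  invisible(outdir)
}
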