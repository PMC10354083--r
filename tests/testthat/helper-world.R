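# Shared synthetic fixtures, built once per test run and memoised.
.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small but complete synthetic world: raster, checklists, and a species
# dataset with strata attached (truth beta_alan = 0.5, theta = 1.5).
tiny_world <- function() {
  memo("tiny_world", {
    cfg <- synth_config(
      extent_km = c(40, 40), n_cities = 2, n_checklists = 4000, seed = 11
    )
    raster <- make_alan_raster(cfg)
    checklists <- simulate_checklists(cfg, raster)
    truth <- species_truth("tinyA", beta_alan = 0.5, theta = 1.5)
    grid <- hex_grid(5)
    dataset <- simulate_species_counts(
      checklists, raster, truth,
      seed = derive_seed(11, "tinyA")
    )
    dataset <- urbantol:::add_strata(dataset, grid)
    list(
      cfg = cfg, raster = raster, checklists = checklists,
      truth = truth, grid = grid, dataset = dataset
    )
  })
}

# A 12-run tolerance estimate on the tiny world, shared across tests.
tiny_est <- function() {
  memo("tiny_est", {
    compute_tolerance_index(tiny_world()$dataset,
      n_runs = 12, master_seed = 5, min_detections = 500
    )
  })
}

# Independent sort-based median (oracle for composite/buffer medians).
oracle_median <- function(v) {
  v <- sort(v)
  n <- length(v)
  if (n == 0) {
    return(NA_real_)
  }
  if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
}

# Brute-force buffer median: enumerate every pixel centre of the raster.
oracle_buffer_median <- function(raster, px, py, radius) {
  xc <- raster$x0 + (seq_len(raster$ncols) - 0.5) * raster$pixel
  yc <- raster$y0 + (seq_len(raster$nrows) - 0.5) * raster$pixel
  vals <- c()
  for (j in seq_len(raster$ncols)) {
    for (i in seq_len(raster$nrows)) {
      if ((xc[j] - px)^2 + (yc[i] - py)^2 <= radius^2 &&
        !is.na(raster$values[i, j])) {
        vals <- c(vals, raster$values[i, j])
      }
    }
  }
  oracle_median(vals)
}

# random raster for geometry tests
random_raster <- function(nr, nc, pixel = 1, x0 = 0, y0 = 0, na_frac = 0) {
  v <- matrix(stats::runif(nr * nc, 0, 10), nr, nc)
  if (na_frac > 0) v[stats::runif(nr * nc) < na_frac] <- NA
  radiance_raster(v, x0 = x0, y0 = y0, pixel = pixel)
}

# a minimal valid checklist row for filter tests
base_checklist <- function(n = 1) {
  data.frame(
    checklist_id = sprintf("C%03d", seq_len(n)),
    lon = 0.5, lat = 0.5, date = as.Date("2015-06-01"),
    time_started = 450, duration_min = 60, distance_km = 0,
    n_observers = 1, protocol = "Stationary", complete = TRUE,
    stringsAsFactors = FALSE
  )
}
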