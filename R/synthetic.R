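# Synthetic world with known ground truth: an artificial-light landscape,
# spatially clustered checklist effort biased toward bright pixels,
# negative-binomial species counts whose log-mean is linear in local
# radiance, and a trait table with a known body-mass effect. Every
# downstream stage of the pipeline can be tested by parameter recovery
# against these generators, with no external data.

#' Configuration of a synthetic world
#'
#' Defaults describe a compact coastal-city landscape: a 60 x 60 km extent
#' at 1-km pixels with 3 exponentially decaying light domes (peak 4
#' nW cm^-2 sr^-1, decay length 8 km, half-normal pixel noise sd 0.1),
#' 20,000 checklists over three years whose placement is biased toward
#' bright pixels (density proportional to `(radiance + 0.05)^0.5`), and
#' effort distributions typical of checklist data (duration gamma with
#' mean ~60 min, travelling distance exponential capped below 5 km,
#' observers 1 + Poisson(1), start times concentrated in the morning).
#' Fractions of deliberately rule-violating checklists (incomplete,
#' over-duration, over-distance, off-window dates) can be injected to
#' exercise the filter; they default to zero.
#'
#' @param extent_km width and height of the world, km.
#' @param pixel_km raster resolution, km (> 0).
#' @param n_cities number of light sources (>= 0).
#' @param city_peak_radiance peak radiance of each source.
#' @param decay_km exponential decay length of radiance with distance.
#' @param noise_sd sd of the half-normal pixel noise (0 for none).
#' @param n_checklists number of checklists to simulate.
#' @param brightness_bias exponent (>= 0) steering checklist placement
#'   toward bright pixels; 0 gives uniform placement.
#' @param brightness_eps additive floor inside the placement weight.
#' @param date_range inclusive range checklist dates are drawn from.
#' @param p_stationary probability a checklist uses the stationary
#'   protocol (distance 0).
#' @param violation_rates named list of fractions: `incomplete`,
#'   `duration` (> 300 min), `distance` (> 5 km), `date` (outside the
#'   standard filter window).
#' @param presence_marker_rate fraction of detections whose count is
#'   emitted as the presence marker `"X"` by [simulate_species_counts()].
#' @param seed integer master seed for the world.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(extent_km = c(60, 60), pixel_km = 1,
                         n_cities = 3, city_peak_radiance = 4,
                         decay_km = 8, noise_sd = 0.1,
                         n_checklists = 20000,
                         brightness_bias = 0.5, brightness_eps = 0.05,
                         date_range = c("2014-01-01", "2016-12-31"),
                         p_stationary = 0.6,
                         violation_rates = list(
                           incomplete = 0, duration = 0, distance = 0, date = 0
                         ),
                         presence_marker_rate = 0,
                         seed = 1) {
  if (any(extent_km <= 0) || pixel_km <= 0) {
    stop("extent and pixel size must be positive", call. = FALSE)
  }
  if (n_cities < 0 || brightness_bias < 0) {
    stop("n_cities and brightness_bias must be non-negative", call. = FALSE)
  }
  if (city_peak_radiance < 0 || noise_sd < 0) {
    stop("radiance parameters must be non-negative", call. = FALSE)
  }
  structure(
    list(
      extent_km = extent_km, pixel_km = pixel_km, n_cities = n_cities,
      city_peak_radiance = city_peak_radiance, decay_km = decay_km,
      noise_sd = noise_sd, n_checklists = n_checklists,
      brightness_bias = brightness_bias, brightness_eps = brightness_eps,
      date_range = as.Date(date_range), p_stationary = p_stationary,
      violation_rates = utils::modifyList(
        list(incomplete = 0, duration = 0, distance = 0, date = 0),
        violation_rates
      ),
      presence_marker_rate = presence_marker_rate, seed = seed
    ),
    class = "synth_config"
  )
}

#' Known per-species ground truth
#'
#' The data-generating parameters of one synthetic species: intercept and
#' radiance slope of the log-mean count (the slope is the quantity the
#' pipeline must recover), smooth effort effects, and the
#' negative-binomial dispersion.
#'
#' The effort effects are fixed smooth shapes scaled by the supplied
#' coefficients: `duration * log(duration/60)`, `doy * sin(2 pi doy/365)`,
#' `tod * sin(2 pi (t - 420)/1440)`, `observers * (sqrt(n) - 1)` and
#' `distance * d`.
#'
#' @param species_code identifier.
#' @param beta0 intercept of the log-mean.
#' @param beta_alan radiance slope of the log-mean (finite).
#' @param theta negative-binomial dispersion (> 0).
#' @param effort_effects named coefficients for the shapes above.
#' @return A list of class `species_truth`.
#' @export
species_truth <- function(species_code, beta0 = -1, beta_alan = 0.5,
                          theta = 1.5,
                          effort_effects = list(
                            duration = 0.2, doy = 0.15, tod = 0.2,
                            observers = 0.1, distance = 0.05
                          )) {
  if (!is.finite(beta_alan)) stop("beta_alan must be finite", call. = FALSE)
  if (!is.finite(theta) || theta <= 0) stop("theta must be > 0", call. = FALSE)
  structure(
    list(
      species_code = species_code, beta0 = beta0, beta_alan = beta_alan,
      theta = theta,
      effort_effects = utils::modifyList(
        list(duration = 0, doy = 0, tod = 0, observers = 0, distance = 0),
        effort_effects
      )
    ),
    class = "species_truth"
  )
}

#' Generate the artificial-light raster of a synthetic world
#'
#' City centres are placed uniformly in the extent; pixel radiance is the
#' sum over cities of `peak * exp(-distance / decay_km)` plus independent
#' half-normal noise (truncation at zero keeps radiance physically
#' non-negative). Deterministic given the config seed.
#'
#' @param config a [synth_config()].
#' @return A planar-km [radiance_raster()].
#' @export
make_alan_raster <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  local_seed(derive_seed(config$seed, "alan-raster"), {
    nc <- ceiling(config$extent_km[1] / config$pixel_km)
    nr <- ceiling(config$extent_km[2] / config$pixel_km)
    xc <- (seq_len(nc) - 0.5) * config$pixel_km
    yc <- (seq_len(nr) - 0.5) * config$pixel_km
    vals <- matrix(0, nr, nc)
    cities <- NULL
    if (config$n_cities > 0) {
      cx <- stats::runif(config$n_cities, 0, config$extent_km[1])
      cy <- stats::runif(config$n_cities, 0, config$extent_km[2])
      cities <- cbind(x = cx, y = cy)
      for (ci in seq_len(config$n_cities)) {
        d <- sqrt(outer((yc - cy[ci])^2, (xc - cx[ci])^2, `+`))
        vals <- vals + config$city_peak_radiance * exp(-d / config$decay_km)
      }
    }
    if (config$noise_sd > 0) {
      vals <- vals + abs(stats::rnorm(nr * nc, 0, config$noise_sd))
    }
    out <- radiance_raster(vals,
      x0 = 0, y0 = 0, pixel = config$pixel_km, crs = "planar_km"
    )
    # ground-truth source locations, for tests and plots
    attr(out, "cities") <- cities
    out
  })
}

#' Simulate brightness-biased checklist effort
#'
#' Draws checklist locations by sampling pixels with probability
#' proportional to `(radiance + eps)^brightness_bias` (then uniformly
#' within the pixel), mimicking the concentration of observers where
#' people live; effort covariates come from the configured distributions.
#' A configurable fraction of checklists violates each filter rule so the
#' filter stage can be exercised; with all violation rates zero every
#' generated checklist passes [filter_checklists()] under default rules.
#' Deterministic given the config seed.
#'
#' @param config a [synth_config()].
#' @param raster the world's [radiance_raster()] (must cover the extent).
#' @return A checklist table in the layout of [read_checklists()]
#'   (`lon`/`lat` carry planar km; attribute `crs = "planar_km"`).
#' @export
simulate_checklists <- function(config, raster) {
  stopifnot(inherits(config, "synth_config"), inherits(raster, "radiance_raster"))
  ext <- .raster_extent(raster)
  if (ext["xmax"] < config$extent_km[1] || ext["ymax"] < config$extent_km[2]) {
    stop("raster does not cover the configured extent", call. = FALSE)
  }
  n <- config$n_checklists
  local_seed(derive_seed(config$seed, "checklists"), {
    w <- (as.vector(raster$values) + config$brightness_eps)^config$brightness_bias
    pix <- sample.int(length(w), n, replace = TRUE, prob = w)
    ij <- arrayInd(pix, dim(raster$values))
    x <- raster$x0 + (ij[, 2] - stats::runif(n)) * raster$pixel
    y <- raster$y0 + (ij[, 1] - stats::runif(n)) * raster$pixel

    stationary <- stats::runif(n) < config$p_stationary
    protocol <- ifelse(stationary, "Stationary", "Traveling")
    duration <- pmin(stats::rgamma(n, shape = 2, scale = 30), 295)
    distance <- ifelse(stationary, 0, pmin(stats::rexp(n, rate = 1 / 1.5), 4.9))
    observers <- 1 + stats::rpois(n, 1)
    time_started <- (420 + stats::rnorm(n, 0, 150)) %% 1440
    days <- as.integer(config$date_range[2] - config$date_range[1])
    date <- config$date_range[1] + sample.int(days + 1L, n, replace = TRUE) - 1L
    complete <- rep(TRUE, n)

    vr <- config$violation_rates
    if (vr$incomplete > 0) {
      complete[stats::runif(n) < vr$incomplete] <- FALSE
    }
    if (vr$duration > 0) {
      v <- stats::runif(n) < vr$duration
      duration[v] <- stats::runif(sum(v), 301, 600)
    }
    if (vr$distance > 0) {
      v <- stats::runif(n) < vr$distance & !stationary
      distance[v] <- stats::runif(sum(v), 5.1, 20)
    }
    if (vr$date > 0) {
      v <- stats::runif(n) < vr$date
      date[v] <- as.Date("2005-06-15") + sample.int(300, sum(v), replace = TRUE)
    }

    out <- data.frame(
      checklist_id = sprintf("S%07d", seq_len(n)),
      lon = x, lat = y, date = date,
      time_started = round(time_started) %% 1440,
      duration_min = round(duration),
      distance_km = round(distance, 3),
      n_observers = observers,
      protocol = protocol,
      complete = complete,
      stringsAsFactors = FALSE
    )
    attr(out, "crs") <- "planar_km"
    out
  })
}

# the fixed effort-effect shapes shared by simulation and documentation
.effort_contribution <- function(truth, checklists) {
  ef <- truth$effort_effects
  ef$duration * log(pmax(checklists$duration_min, 1) / 60) +
    ef$doy * sin(2 * pi * as.integer(format(checklists$date, "%j")) / 365) +
    ef$tod * sin(2 * pi * (checklists$time_started - 420) / 1440) +
    ef$observers * (sqrt(checklists$n_observers) - 1) +
    ef$distance * checklists$distance_km
}

#' Simulate species counts on checklists
#'
#' For each checklist, draws a count from a negative binomial with
#' dispersion `theta` and log-mean `beta0 + beta_alan * radiance + effort
#' effects`, where the radiance covariate is the buffer-median at the
#' checklist location — exactly the covariate the pipeline later
#' extracts, so recovery of `beta_alan` is a clean test of the chain.
#'
#' @param checklists a checklist table (planar km) inside the raster.
#' @param raster the world's [radiance_raster()].
#' @param truth a [species_truth()].
#' @param buffer_radius_km radius of the radiance buffer (default 5).
#' @param presence_marker_rate fraction of detections emitted with the
#'   presence marker `"X"` in `count_raw` (the numeric count is kept in
#'   `count`).
#' @param alan optional precomputed buffer-median radiance per checklist
#'   (one extraction can be shared across species in the same world).
#' @param seed integer; defaults to a stream derived from the species
#'   code.
#' @return A species dataset (see [species_dataset()]): the checklist
#'   covariates plus `x`, `y`, `alan`, `count`, `count_raw` and
#'   `species_code`. The true radiance slope is attached as attribute
#'   `truth`.
#' @export
simulate_species_counts <- function(checklists, raster, truth,
                                    buffer_radius_km = 5,
                                    presence_marker_rate = 0, alan = NULL,
                                    seed = derive_seed(1, truth$species_code)) {
  stopifnot(inherits(truth, "species_truth"))
  if (is.null(alan)) {
    alan <- median_radiance_in_buffer(
      raster, checklists$lon, checklists$lat, buffer_radius_km
    )
  }
  eta <- truth$beta0 + truth$beta_alan * alan +
    .effort_contribution(truth, checklists)
  local_seed(seed, {
    y <- stats::rnbinom(nrow(checklists), size = truth$theta, mu = exp(eta))
    count_raw <- as.character(y)
    if (presence_marker_rate > 0) {
      mark <- y >= 1 & stats::runif(length(y)) < presence_marker_rate
      count_raw[mark] <- "X"
    }
    out <- checklists
    out$x <- checklists$lon
    out$y <- checklists$lat
    out$day_of_year <- as.integer(format(checklists$date, "%j"))
    out$alan <- alan
    out$count <- y
    out$count_raw <- count_raw
    out$species_code <- truth$species_code
    attr(out, "truth") <- truth
    attr(out, "crs") <- "planar_km"
    out
  })
}

#' Simulate a species trait table with a known mass effect
#'
#' Draws traits over realistic raptor ranges (body mass log-uniform on
#' 100–4000 g, nest substrate breadth 1–6, habitat breadth 1–30, feeding
#' guild among generalist/bird/mammal/fish specialist, migratory status
#' local dispersal or partial migrant) and a true tolerance index
#' `intercept + mass_effect * z(mass) + Normal(0, noise_sd)` — all other
#' traits have no effect, so the trait regression should recover
#' `mass_effect` and reject the rest at the nominal rate.
#'
#' @param n_species number of species (>= 10).
#' @param mass_effect slope on z-scored body mass.
#' @param noise_sd residual sd of the true index.
#' @param intercept intercept of the true index.
#' @param seed integer seed.
#' @return A list with `traits` (a trait table) and `index` (named true
#'   index vector).
#' @export
simulate_trait_table <- function(n_species = 24, mass_effect = -0.7,
                                 noise_sd = 0.4, intercept = 0.3, seed = 1) {
  if (n_species < 10) {
    stop("need at least 10 species for a trait table", call. = FALSE)
  }
  local_seed(seed, {
    mass <- exp(stats::runif(n_species, log(100), log(4000)))
    # the first species cycle through the guild and movement classes so the
    # table always carries every level (as a real raptor assemblage does)
    guild <- sample(.GUILD_LEVELS, n_species,
      replace = TRUE, prob = c(0.4, 0.25, 0.2, 0.15)
    )
    guild[1:4] <- .GUILD_LEVELS
    mig <- sample(.MIGRATORY_LEVELS, n_species, replace = TRUE)
    mig[1:2] <- .MIGRATORY_LEVELS
    traits <- data.frame(
      species_code = sprintf("sp%02d", seq_len(n_species)),
      body_mass_g = round(mass, 1),
      nest_substrate_breadth = sample(1:6, n_species, replace = TRUE),
      habitat_breadth = sample(1:30, n_species, replace = TRUE),
      feeding_guild = guild,
      migratory_status = mig,
      stringsAsFactors = FALSE
    )
    index <- intercept + mass_effect * scale_center(traits$body_mass_g) +
      stats::rnorm(n_species, 0, noise_sd)
    names(index) <- traits$species_code
    list(traits = traits, index = index)
  })
}
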