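test_that("every generator is bit-identical under the same seed", {
  cfg <- synth_config(n_checklists = 500, seed = 21)
  expect_identical(make_alan_raster(cfg), make_alan_raster(cfg))
  r <- make_alan_raster(cfg)
  expect_identical(simulate_checklists(cfg, r), simulate_checklists(cfg, r))
  cl <- simulate_checklists(cfg, r)
  tr <- species_truth("spA", beta_alan = 0.4)
  expect_identical(
    simulate_species_counts(cl, r, tr, seed = 5),
    simulate_species_counts(cl, r, tr, seed = 5)
  )
  expect_identical(
    simulate_trait_table(24, seed = 3),
    simulate_trait_table(24, seed = 3)
  )
  # a different seed changes the draw
  cfg2 <- synth_config(n_checklists = 500, seed = 22)
  expect_false(identical(make_alan_raster(cfg)$values, make_alan_raster(cfg2)$values))
})

test_that("the radiance field is sums of decaying city domes plus noise", {
  zero <- synth_config(n_cities = 0, noise_sd = 0, seed = 1)
  expect_true(all(make_alan_raster(zero)$values == 0))

  one <- synth_config(n_cities = 1, noise_sd = 0, city_peak_radiance = 7, seed = 2)
  r <- make_alan_raster(one)
  city <- attr(r, "cities")
  ij <- which(r$values == max(r$values), arr.ind = TRUE)
  # the maximum sits in the pixel containing the city
  expect_equal(unname(ceiling(city[1, "x"] / r$pixel)), unname(ij[1, "col"]))
  expect_equal(unname(ceiling(city[1, "y"] / r$pixel)), unname(ij[1, "row"]))
  expect_lte(max(r$values), 7)
  # radiance decays exactly exponentially with distance from the city
  xc <- urbantol:::.raster_xc(r)
  yc <- urbantol:::.raster_yc(r)
  d <- sqrt(outer((yc - city[1, "y"])^2, (xc - city[1, "x"])^2, `+`))
  expect_equal(r$values, 7 * exp(-d / one$decay_km), tolerance = 1e-12)

  expect_error(synth_config(pixel_km = 0), "positive")
  expect_error(synth_config(extent_km = c(-1, 10)), "positive")
  expect_error(synth_config(brightness_bias = -1), "non-negative")
})

test_that("brightness_bias = 0 places checklists uniformly across pixels", {
  cfg <- synth_config(
    extent_km = c(10, 10), n_checklists = 6000, brightness_bias = 0, seed = 8
  )
  r <- make_alan_raster(cfg)
  cl <- simulate_checklists(cfg, r)
  pix <- ceiling(cl$lon / r$pixel) + (ceiling(cl$lat / r$pixel) - 1) * r$ncols
  counts <- tabulate(pix, nbins = r$ncols * r$nrows)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.01)

  # and a strong bias concentrates effort in bright pixels
  cfgb <- synth_config(extent_km = c(10, 10), n_checklists = 6000, brightness_bias = 3, seed = 8)
  rb <- make_alan_raster(cfgb)
  clb <- simulate_checklists(cfgb, rb)
  med_bright <- median(rb$values[cbind(ceiling(clb$lat / rb$pixel), ceiling(clb$lon / rb$pixel))])
  expect_gt(med_bright, median(rb$values))
})

test_that("zero violation rates mean every checklist passes the filter", {
  cfg <- synth_config(n_checklists = 1000, seed = 13)
  cl <- simulate_checklists(cfg, make_alan_raster(cfg))
  out <- filter_checklists(cl)
  expect_equal(nrow(out$checklists), 1000)
  expect_true(all(out$report$removed == 0))
})

test_that("counts follow the negative-binomial law (moment check)", {
  # constant mean: mu = exp(beta0), theta = 2, no covariate effects
  cfg <- synth_config(n_checklists = 100000, seed = 30)
  r <- make_alan_raster(cfg)
  cl <- simulate_checklists(cfg, r)
  tr <- species_truth("spM",
    beta0 = 0.7, beta_alan = 0, theta = 2,
    effort_effects = list()
  )
  ds <- simulate_species_counts(cl, r, tr, alan = rep(0, nrow(cl)), seed = 31)
  mu <- exp(0.7)
  expect_equal(mean(ds$count), mu, tolerance = 0.05)
  expect_equal(var(ds$count), mu + mu^2 / 2, tolerance = 0.05)
  expect_error(species_truth("bad", theta = 0), "theta")
  expect_error(species_truth("bad", beta_alan = Inf), "finite")
})

test_that("beta_alan = 0 leaves counts uncorrelated with radiance", {
  cfg <- synth_config(n_checklists = 50000, extent_km = c(30, 30), seed = 33)
  r <- make_alan_raster(cfg)
  cl <- simulate_checklists(cfg, r)
  tr <- species_truth("sp0", beta_alan = 0, effort_effects = list())
  ds <- simulate_species_counts(cl, r, tr, seed = 34)
  expect_lt(abs(cor(ds$count, ds$alan)), 0.05)
})

test_that("a NB-GLM on raw simulated data recovers the radiance slope", {
  cfg <- synth_config(n_checklists = 50000, extent_km = c(30, 30), seed = 35)
  r <- make_alan_raster(cfg)
  cl <- simulate_checklists(cfg, r)
  tr <- species_truth("spR", beta_alan = 0.5, effort_effects = list())
  ds <- simulate_species_counts(cl, r, tr, seed = 36)
  # independent fit oracle on the unthinned data
  fit <- MASS::glm.nb(count ~ alan, data = ds)
  expect_equal(unname(coef(fit)["alan"]), 0.5, tolerance = 0.1)
  expect_lt(abs(coef(fit)["alan"] - 0.5), 0.05)
})

test_that("presence markers appear at the configured rate", {
  cfg <- synth_config(n_checklists = 4000, seed = 40)
  r <- make_alan_raster(cfg)
  cl <- simulate_checklists(cfg, r)
  tr <- species_truth("spX", beta_alan = 0.3)
  ds <- simulate_species_counts(cl, r, tr, presence_marker_rate = 0.3, seed = 41)
  det <- ds$count >= 1
  expect_equal(mean(ds$count_raw[det] == "X"), 0.3, tolerance = 0.1)
  expect_true(all(ds$count_raw[!det] == "0"))
})

test_that("trait tables have realistic ranges and a recoverable mass effect", {
  tt <- simulate_trait_table(24, mass_effect = -0.7, noise_sd = 0, seed = 2)
  expect_true(all(tt$traits$body_mass_g >= 100 & tt$traits$body_mass_g <= 4000))
  expect_true(all(tt$traits$nest_substrate_breadth %in% 1:6))
  expect_true(all(tt$traits$habitat_breadth %in% 1:30))
  expect_true(all(tt$traits$feeding_guild %in% c(
    "generalist", "bird specialist", "mammal specialist", "fish specialist"
  )))
  # noiseless: the trait model recovers the slope to machine precision
  tm <- suppressWarnings(fit_trait_model(tt$index, tt$traits))
  est <- tm$coefficients
  expect_equal(est$estimate[est$term == "body_mass"], -0.7, tolerance = 1e-10)
  expect_equal(tm$r_squared, 1, tolerance = 1e-10)
  expect_error(simulate_trait_table(9), "at least 10")
})
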