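test_that("scale_center standardises to mean 0, sample sd 1", {
  expect_equal(scale_center(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(6)
  x <- rnorm(57, 12, 9)
  z <- scale_center(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_equal(scale_center(z), z, tolerance = 1e-12) # idempotent
  expect_error(scale_center(rep(4, 10)), "constant")
})

test_that("a noiseless mass-only signal is recovered exactly", {
  tt <- simulate_trait_table(20, mass_effect = -0.7, noise_sd = 0, intercept = 0.3, seed = 8)
  # a perfect fit makes summary.lm/drop1 warn; that is the point of the case
  tm <- suppressWarnings(fit_trait_model(tt$index, tt$traits))
  est <- setNames(tm$coefficients$estimate, tm$coefficients$term)
  expect_equal(unname(est["body_mass"]), -0.7, tolerance = 1e-10)
  expect_equal(unname(est["(Intercept)"]), 0.3, tolerance = 1e-10)
  others <- setdiff(names(est), c("body_mass", "(Intercept)"))
  expect_true(all(abs(est[others]) < 1e-10))
  expect_equal(tm$r_squared, 1, tolerance = 1e-12)
})

test_that("estimates and F tests match a linear-algebra oracle", {
  tt <- simulate_trait_table(24, mass_effect = -0.5, noise_sd = 0.4, seed = 15)
  tm <- fit_trait_model(tt$index, tt$traits)
  X <- model.matrix(tm$lm)
  y <- tm$data$index
  beta_oracle <- drop(solve(crossprod(X)) %*% crossprod(X, y))
  expect_lt(max(abs(tm$coefficients$estimate - beta_oracle)), 1e-10)

  # drop-one F for body mass from first principles
  rss <- function(M) sum(lm.fit(M, y)$residuals^2)
  rss_full <- rss(X)
  j <- which(colnames(X) == "body_mass")
  f_oracle <- ((rss(X[, -j, drop = FALSE]) - rss_full) / 1) /
    (rss_full / (nrow(X) - ncol(X)))
  got <- tm$ftests$F[tm$ftests$predictor == "body_mass"]
  expect_equal(got, f_oracle, tolerance = 1e-10)

  # and for the feeding-guild block (3 contrasts dropped together)
  jg <- grep("feeding_guild", colnames(X))
  fg_oracle <- ((rss(X[, -jg, drop = FALSE]) - rss_full) / length(jg)) /
    (rss_full / (nrow(X) - ncol(X)))
  expect_equal(tm$ftests$F[tm$ftests$predictor == "feeding_guild"], fg_oracle,
    tolerance = 1e-10
  )

  # CI uses Student t with residual df
  tq <- qt(0.975, tm$df_residual)
  expect_equal(
    tm$coefficients$ci_high - tm$coefficients$estimate,
    tq * tm$coefficients$se,
    tolerance = 1e-10
  )
  # t statistic is estimate / SE
  expect_equal(tm$coefficients$t,
    tm$coefficients$estimate / tm$coefficients$se,
    tolerance = 1e-12
  )
})

test_that("the summary table has the canonical shape", {
  tt <- simulate_trait_table(24, seed = 5)
  tm <- fit_trait_model(tt$index, tt$traits)
  expect_equal(tm$coefficients$term, c(
    "(Intercept)", "body_mass", "nest_substrate_breadth", "habitat_breadth",
    "feeding_guildbird specialist", "feeding_guildmammal specialist",
    "feeding_guildfish specialist", "migratory_statuspartial migrant"
  ))
  expect_equal(unname(tm$reference), c("generalist", "local dispersal"))
  expect_equal(tm$ftests$predictor, c(
    "body_mass", "nest_substrate_breadth", "habitat_breadth",
    "feeding_guild", "migratory_status"
  ))
  expect_gte(tm$r_squared, 0)
  expect_lte(tm$r_squared, 1)
})

test_that("residuals are orthogonal to every design column", {
  tt <- simulate_trait_table(24, seed = 19)
  tm <- fit_trait_model(tt$index, tt$traits)
  X <- model.matrix(tm$lm)
  expect_lt(max(abs(crossprod(X, residuals(tm)))), 1e-10)
})

test_that("a missing factor level is a named rank-deficiency error", {
  tt <- simulate_trait_table(15, seed = 3)
  tt$traits$feeding_guild[tt$traits$feeding_guild == "fish specialist"] <- "generalist"
  expect_error(fit_trait_model(tt$index, tt$traits), "fish specialist")
  tt2 <- simulate_trait_table(15, seed = 3)
  tt2$traits$feeding_guild[1] <- "nectarivore"
  expect_error(fit_trait_model(tt2$index, tt2$traits), "nectarivore")
})

test_that("marginal effects expose the fitted line, levels and partial residuals", {
  tt <- simulate_trait_table(24, mass_effect = -0.6, noise_sd = 0.3, seed = 27)
  tm <- fit_trait_model(tt$index, tt$traits)
  me <- marginal_effects(tm, "body_mass", n_grid = 50)
  # the slope of the returned line equals the coefficient
  slope <- coef(lm(fit ~ value, data = me$grid))[["value"]]
  expect_equal(slope, coef(tm)[["body_mass"]], tolerance = 1e-10)
  # partial residuals average to the mean term contribution
  X <- model.matrix(tm$lm)
  contrib <- X[, "body_mass"] * coef(tm)[["body_mass"]]
  expect_equal(mean(me$partial$partial_residual), mean(contrib), tolerance = 1e-10)
  expect_true(all(me$grid$ci_low <= me$grid$fit & me$grid$fit <= me$grid$ci_high))

  # categorical predictor: one effect per level, reference at the intercept
  mg <- marginal_effects(tm, "feeding_guild")
  expect_equal(nrow(mg$grid), 4)
  expect_equal(mg$grid$fit[1], coef(tm)[["(Intercept)"]], tolerance = 1e-12)
  expect_equal(
    mg$grid$fit[2] - mg$grid$fit[1],
    coef(tm)[["feeding_guildbird specialist"]],
    tolerance = 1e-12
  )
  expect_error(marginal_effects(tm, "wingspan"), "unknown")
})
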