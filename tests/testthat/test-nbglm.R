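# fixed 50-row dataset used by the likelihood-oracle checks
nb_fixture <- function() {
  memo("nb_fixture", {
    set.seed(1234)
    n <- 50
    x1 <- rnorm(n)
    x2 <- runif(n)
    X <- cbind(`(Intercept)` = 1, x1 = x1, x2 = x2)
    mu <- exp(0.4 + 0.6 * x1 - 0.8 * x2)
    y <- rnbinom(n, size = 1.3, mu = mu)
    list(X = X, y = y)
  })
}

test_that("an intercept-only fit returns log of the mean count", {
  y <- c(2, 2, 2, 2)
  f <- fit_nb_glm(matrix(1, 4, 1), y)
  expect_equal(unname(coef(f)), log(2), tolerance = 1e-10)
  # also with dispersion fixed at an arbitrary value
  f2 <- fit_nb_glm(matrix(1, 4, 1), y, theta = 3)
  expect_equal(unname(coef(f2)), log(2), tolerance = 1e-10)
  y3 <- c(0, 1, 5, 2, 4)
  f3 <- fit_nb_glm(matrix(1, 5, 1), y3, theta = 2)
  expect_equal(unname(coef(f3)), log(mean(y3)), tolerance = 1e-10)
})

test_that("theta = 1e8 reproduces the Poisson fit", {
  fx <- nb_fixture()
  f <- fit_nb_glm(fx$X, fx$y, theta = 1e8)
  pois <- glm.fit(fx$X, fx$y, family = poisson())
  expect_equal(unname(coef(f)), unname(coef(pois)), tolerance = 1e-6)
})

test_that("coefficients maximise the joint NB log-likelihood (optim oracle)", {
  fx <- nb_fixture()
  f <- fit_nb_glm(fx$X, fx$y)
  nll <- function(par) {
    eta <- drop(fx$X %*% par[1:3])
    -sum(dnbinom(fx$y, size = exp(par[4]), mu = exp(eta), log = TRUE))
  }
  opt <- optim(c(0, 0, 0, 0), nll, method = "BFGS",
    control = list(maxit = 1000, reltol = 1e-14)
  )
  expect_lt(max(abs(coef(f) - opt$par[1:3])), 1e-4)
  expect_equal(f$theta, exp(opt$par[4]), tolerance = 1e-3)
  expect_true(f$converged)
})

test_that("fit agrees with an independent NB-GLM implementation", {
  fx <- nb_fixture()
  f <- fit_nb_glm(fx$X, fx$y)
  m <- MASS::glm.nb(fx$y ~ x1 + x2, data = data.frame(fx$X[, -1]))
  expect_equal(unname(coef(f)), unname(coef(m)), tolerance = 1e-6)
  expect_equal(f$theta, m$theta, tolerance = 1e-4)
  expect_equal(unname(f$se), unname(summary(m)$coefficients[, 2]), tolerance = 1e-4)
})

test_that("the score vanishes at convergence", {
  fx <- nb_fixture()
  f <- fit_nb_glm(fx$X, fx$y)
  mu <- f$fitted
  score <- crossprod(fx$X, (fx$y - mu) / (1 + mu / f$theta))
  expect_lt(max(abs(score)), 1e-6 * (sum(fx$y) + 1))
})

test_that("rescaling a covariate rescales its coefficient and SE inversely", {
  fx <- nb_fixture()
  f1 <- fit_nb_glm(fx$X, fx$y)
  c_scale <- 4
  X2 <- fx$X
  X2[, "x1"] <- X2[, "x1"] * c_scale
  f2 <- fit_nb_glm(X2, fx$y)
  expect_equal(coef(f2)[["x1"]], coef(f1)[["x1"]] / c_scale, tolerance = 1e-8)
  expect_equal(f2$se[["x1"]], f1$se[["x1"]] / c_scale, tolerance = 1e-6)
  expect_equal(coef(f2)[["(Intercept)"]], coef(f1)[["(Intercept)"]], tolerance = 1e-8)
})

test_that("duplicating every row keeps coefficients and shrinks SEs by sqrt 2", {
  fx <- nb_fixture()
  f1 <- fit_nb_glm(fx$X, fx$y)
  f2 <- fit_nb_glm(rbind(fx$X, fx$X), c(fx$y, fx$y))
  expect_equal(coef(f2), coef(f1), tolerance = 1e-6)
  expect_equal(unname(f2$se / f1$se), rep(1 / sqrt(2), 3), tolerance = 1e-4)
})

test_that("degenerate inputs raise informative errors", {
  X <- cbind(1, rnorm(10))
  expect_error(fit_nb_glm(X, rep(0, 10)), "all counts are zero")
  expect_error(fit_nb_glm(X, c(rep(1, 9), 0.5)), "integer")
  expect_error(fit_nb_glm(X, rep(1, 9)), "length")
  expect_error(fit_nb_glm(cbind(X, X[, 2]), rpois(10, 2)), "rank")
  expect_error(fit_nb_glm(matrix(1, 3, 3), c(1, 2, 1)), "more rows")
})

test_that("species GAM recovers a known radiance slope", {
  w <- tiny_world()
  fit <- fit_species_gam(w$dataset)
  expect_s3_class(fit, "species_gam")
  expect_true(fit$converged)
  expect_equal(fit$beta_alan, 0.5, tolerance = 0.25)
  expect_lt(abs(fit$beta_alan - 0.5), 0.1)
  expect_gt(fit$se_alan, 0)
  # design: intercept + alan + 5 tp smooths x 3 cols + cyclic x 4 cols
  expect_equal(fit$df, 2 + 5 * 3 + 4)
  expect_equal(fit$theta, 1.5, tolerance = 0.25)
})

test_that("the Wald test on a permuted radiance covariate is calibrated", {
  w <- tiny_world()
  d <- w$dataset[seq_len(2000), ]
  des <- urbantol:::build_gam_design(d)
  y <- d$count[des$rows]
  X <- des$X
  set.seed(77)
  rej <- 0
  n_perm <- 100
  for (i in seq_len(n_perm)) {
    Xp <- X
    Xp[, "alan"] <- X[sample(nrow(X)), "alan"]
    f <- fit_nb_glm(Xp, y)
    z <- coef(f)[["alan"]] / f$se[["alan"]]
    if (abs(z) > qnorm(0.975)) rej <- rej + 1
  }
  expect_gte(rej / n_perm, 0.0)
  expect_lte(rej / n_perm, 0.12)
})

test_that("missing smooth covariates are dropped and floored", {
  w <- tiny_world()
  d <- w$dataset[seq_len(300), ]
  d$duration_min[1:30] <- NA
  fit <- fit_species_gam(d, min_rows = 100)
  expect_equal(fit$n_dropped, 30)
  expect_equal(fit$n, 270)
  expect_error(fit_species_gam(d[1:80, ]), "insufficient")
})
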