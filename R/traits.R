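#' Z-score a numeric vector
#'
#' Centres to mean zero and scales to unit sample standard deviation
#' (n - 1 denominator), the standardisation applied to every quantitative
#' trait before the regression so slopes are comparable across traits.
#'
#' @param x numeric vector with at least two distinct finite values.
#' @return The scaled vector.
#' @export
scale_center <- function(x) {
  if (length(unique(x[is.finite(x)])) < 2) {
    stop("cannot scale a constant (or all-missing) vector", call. = FALSE)
  }
  (x - mean(x)) / stats::sd(x)
}

.GUILD_LEVELS <- c("generalist", "bird specialist", "mammal specialist", "fish specialist")
.MIGRATORY_LEVELS <- c("local dispersal", "partial migrant")

#' Regress the urban tolerance index on species traits
#'
#' Ordinary least squares of the per-species tolerance index on body mass,
#' nest substrate breadth, habitat breadth, feeding guild and migratory
#' status — all traits in one model. Quantitative traits (mass and the two
#' breadths) are z-scored; feeding guild and migratory status use
#' treatment coding with reference levels "generalist" and
#' "local dispersal". Each predictor gets a drop-one (marginal) F test —
#' the full model against the model without that predictor, multi-level
#' factors dropped as a block — and coefficient CIs use Student t with
#' residual degrees of freedom.
#'
#' @param indices either a `tolerance_ranking`/data frame with `species`
#'   and `index` columns, or a named numeric vector of indices.
#' @param traits data frame with columns `species_code`, `body_mass_g`,
#'   `nest_substrate_breadth`, `habitat_breadth`, `feeding_guild`,
#'   `migratory_status`.
#' @param conf_level confidence level for coefficient intervals.
#' @return An object of class `trait_model`: `coefficients` (term,
#'   estimate, SE, t, CI limits), `ftests` (per-predictor F, df and P),
#'   `r_squared`, `df_residual`, the underlying `lm` fit, and the scaling
#'   constants used. Methods: [print()], [summary()], [coef()],
#'   [residuals()], [predict()], [plot()].
#' @export
fit_trait_model <- function(indices, traits, conf_level = 0.95) {
  if (is.data.frame(indices)) {
    idx <- indices$index
    names(idx) <- indices$species %||% indices$species_code
  } else {
    idx <- indices
  }
  m <- match(traits$species_code, names(idx))
  if (anyNA(m)) {
    stop("no tolerance index for species: ",
      paste(traits$species_code[is.na(m)], collapse = ", "),
      call. = FALSE
    )
  }
  bad_guild <- setdiff(unique(traits$feeding_guild), .GUILD_LEVELS)
  bad_mig <- setdiff(unique(traits$migratory_status), .MIGRATORY_LEVELS)
  if (length(bad_guild) || length(bad_mig)) {
    stop("unknown trait level(s): ",
      paste(c(bad_guild, bad_mig), collapse = ", "),
      call. = FALSE
    )
  }
  empty <- c(
    setdiff(.GUILD_LEVELS, unique(traits$feeding_guild)),
    setdiff(.MIGRATORY_LEVELS, unique(traits$migratory_status))
  )
  if (length(empty)) {
    stop("rank-deficient trait design; empty factor level(s): ",
      paste(empty, collapse = ", "),
      call. = FALSE
    )
  }
  d <- data.frame(
    index = as.numeric(idx[m]),
    body_mass = scale_center(traits$body_mass_g),
    nest_substrate_breadth = scale_center(traits$nest_substrate_breadth),
    habitat_breadth = scale_center(traits$habitat_breadth),
    feeding_guild = factor(traits$feeding_guild, levels = .GUILD_LEVELS),
    migratory_status = factor(traits$migratory_status, levels = .MIGRATORY_LEVELS)
  )
  fit <- stats::lm(index ~ ., data = d)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient trait design (empty level?): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  n <- nrow(d)
  p <- length(stats::coef(fit))
  if (n < p + 2) stop("too few species for the trait model", call. = FALSE)
  sm <- summary(fit)
  ci <- stats::confint(fit, level = conf_level)
  coefs <- data.frame(
    term = rownames(sm$coefficients),
    estimate = sm$coefficients[, 1],
    se = sm$coefficients[, 2],
    t = sm$coefficients[, 3],
    ci_low = ci[, 1],
    ci_high = ci[, 2],
    stringsAsFactors = FALSE
  )
  rownames(coefs) <- NULL
  dr <- stats::drop1(fit, test = "F")
  ftests <- data.frame(
    predictor = rownames(dr)[-1],
    df = dr$Df[-1],
    F = dr$`F value`[-1],
    p = dr$`Pr(>F)`[-1],
    stringsAsFactors = FALSE
  )
  structure(
    list(
      coefficients = coefs, ftests = ftests,
      r_squared = sm$r.squared, df_residual = fit$df.residual,
      reference = c(
        feeding_guild = levels(d$feeding_guild)[1],
        migratory_status = levels(d$migratory_status)[1]
      ),
      scaling = list(
        body_mass = c(mean = mean(traits$body_mass_g), sd = stats::sd(traits$body_mass_g)),
        nest_substrate_breadth = c(
          mean = mean(traits$nest_substrate_breadth),
          sd = stats::sd(traits$nest_substrate_breadth)
        ),
        habitat_breadth = c(
          mean = mean(traits$habitat_breadth),
          sd = stats::sd(traits$habitat_breadth)
        )
      ),
      lm = fit, data = d, conf_level = conf_level
    ),
    class = "trait_model"
  )
}

#' @export
print.trait_model <- function(x, ...) {
  cat(sprintf(
    "Trait model for the urban tolerance index (n = %d, R^2 = %.4f)\n",
    nrow(x$data), x$r_squared
  ))
  print(x$coefficients, digits = 3)
  cat("Drop-one F tests:\n")
  print(x$ftests, digits = 3)
  cat(sprintf(
    "References: feeding guild = %s, migratory status = %s\n",
    x$reference["feeding_guild"], x$reference["migratory_status"]
  ))
  invisible(x)
}

#' @export
summary.trait_model <- function(object, ...) object

#' @export
coef.trait_model <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
residuals.trait_model <- function(object, ...) stats::residuals(object$lm)

#' @export
predict.trait_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    stats::predict(object$lm, ...)
  } else {
    stats::predict(object$lm, newdata = newdata, ...)
  }
}

#' Marginal effect of one trait
#'
#' Model-predicted tolerance index across one predictor with the other
#' quantitative predictors held at their mean (0 on the z-scale) and
#' factors at their reference level, with pointwise confidence bands from
#' the coefficient covariance and partial residuals (model residuals plus
#' the predictor's own fitted contribution).
#'
#' @param object a [fit_trait_model()] result.
#' @param predictor one of `"body_mass"`, `"nest_substrate_breadth"`,
#'   `"habitat_breadth"`, `"feeding_guild"`, `"migratory_status"`.
#' @param n_grid grid size for quantitative predictors.
#' @return A list of class `marginal_effect`: `grid` (predictor value,
#'   fit, ci_low, ci_high; for factors one row per level) and `partial`
#'   (observed predictor value and partial residual per species).
#' @export
marginal_effects <- function(object, predictor, n_grid = 100) {
  stopifnot(inherits(object, "trait_model"))
  d <- object$data
  quant <- c("body_mass", "nest_substrate_breadth", "habitat_breadth")
  if (!predictor %in% c(quant, "feeding_guild", "migratory_status")) {
    stop("unknown predictor: ", predictor, call. = FALSE)
  }
  base <- data.frame(
    body_mass = 0, nest_substrate_breadth = 0, habitat_breadth = 0,
    feeding_guild = factor(levels(d$feeding_guild)[1], levels(d$feeding_guild)),
    migratory_status = factor(levels(d$migratory_status)[1], levels(d$migratory_status))
  )
  if (predictor %in% quant) {
    gx <- seq(min(d[[predictor]]), max(d[[predictor]]), length.out = n_grid)
    nd <- base[rep(1, n_grid), , drop = FALSE]
    nd[[predictor]] <- gx
  } else {
    lev <- levels(d[[predictor]])
    nd <- base[rep(1, length(lev)), , drop = FALSE]
    nd[[predictor]] <- factor(lev, levels = lev)
    gx <- lev
  }
  pr <- stats::predict(object$lm, newdata = nd, se.fit = TRUE)
  tq <- stats::qt(1 - (1 - object$conf_level) / 2, object$df_residual)
  grid <- data.frame(
    value = gx, fit = pr$fit,
    ci_low = pr$fit - tq * pr$se.fit, ci_high = pr$fit + tq * pr$se.fit
  )
  # the predictor's own fitted contribution on the observed data
  X <- stats::model.matrix(object$lm)
  terms_assign <- attr(X, "assign")
  labels <- attr(stats::terms(object$lm), "term.labels")
  j <- which(labels == predictor)
  cols <- which(terms_assign == j)
  contrib <- drop(X[, cols, drop = FALSE] %*% stats::coef(object$lm)[cols])
  partial <- data.frame(
    value = d[[predictor]],
    partial_residual = stats::residuals(object$lm) + contrib
  )
  structure(
    list(grid = grid, partial = partial, predictor = predictor),
    class = "marginal_effect"
  )
}

#' @export
plot.marginal_effect <- function(x, ...) {
  if (is.numeric(x$grid$value)) {
    graphics::plot(x$partial$value, x$partial$partial_residual,
      col = "grey50", pch = 19,
      xlab = x$predictor, ylab = "Urban tolerance index (partial)", ...
    )
    graphics::polygon(
      c(x$grid$value, rev(x$grid$value)),
      c(x$grid$ci_low, rev(x$grid$ci_high)),
      col = grDevices::adjustcolor("grey70", 0.4), border = NA
    )
    graphics::lines(x$grid$value, x$grid$fit, lwd = 2)
  } else {
    at <- seq_along(x$grid$value)
    graphics::plot(
      at, x$grid$fit,
      ylim = range(c(x$grid$ci_low, x$grid$ci_high, x$partial$partial_residual)),
      pch = 19, xaxt = "n", xlab = x$predictor,
      ylab = "Urban tolerance index (partial)", ...
    )
    graphics::axis(1, at = at, labels = x$grid$value, cex.axis = 0.8)
    graphics::segments(at, x$grid$ci_low, at, x$grid$ci_high, lwd = 2)
    jit <- at[match(x$partial$value, x$grid$value)] +
      stats::runif(nrow(x$partial), -0.08, 0.08)
    graphics::points(jit, x$partial$partial_residual, col = "grey50", pch = 19)
  }
  invisible(x)
}

#' @export
plot.trait_model <- function(x, predictors = c(
                               "body_mass", "nest_substrate_breadth", "habitat_breadth",
                               "feeding_guild", "migratory_status"
                             ), ...) {
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(predictors)))
  on.exit(graphics::par(op))
  for (p in predictors) plot(marginal_effects(x, p), ...)
  invisible(x)
}
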