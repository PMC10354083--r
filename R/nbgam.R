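# Negative-binomial log-link regression fitted by alternating IRLS for the
# coefficients with one-dimensional profile-likelihood maximisation for the
# dispersion. This is the per-species abundance model: counts on checklists
# regressed on the radiance covariate plus fixed-df effort smooths.

.nb_loglik <- function(y, mu, theta) {
  sum(stats::dnbinom(y, size = theta, mu = mu, log = TRUE))
}

.nb_deviance <- function(y, mu, theta) {
  yy <- pmax(y, 1e-12)
  2 * sum(y * log(yy / mu) - (y + theta) * log((y + theta) / (mu + theta)))
}

# Profile maximisation of the NB log-likelihood over log(theta) at fixed
# means: safeguarded Newton with analytic digamma/trigamma derivatives,
# falling back to golden-section (stats::optimize) if Newton misbehaves.
.nb_theta_ml <- function(y, mu, theta0, range_log = c(-7, 20), tol = 1e-8) {
  t <- min(max(log(theta0), range_log[1]), range_log[2])
  score <- function(th) {
    sum(digamma(y + th) - digamma(th) + log(th) + 1 -
      log(th + mu) - (th + y) / (th + mu))
  }
  hess <- function(th) {
    sum(trigamma(y + th) - trigamma(th) + 1 / th -
      2 / (th + mu) + (th + y) / (th + mu)^2)
  }
  ok <- FALSE
  for (it in 1:30) {
    th <- exp(t)
    g <- score(th)
    # chain rule to log scale
    gt <- th * g
    ht <- th^2 * hess(th) + gt
    if (!is.finite(gt) || !is.finite(ht) || ht >= 0) break
    step <- min(max(-gt / ht, -2), 2)
    t_new <- min(max(t + step, range_log[1]), range_log[2])
    moved <- abs(t_new - t)
    t <- t_new
    if (moved < tol) {
      ok <- TRUE
      break
    }
  }
  if (!ok && (t > range_log[1] + 1e-3 && t < range_log[2] - 1e-3)) {
    opt <- stats::optimize(
      function(lt) .nb_loglik(y, mu, exp(lt)),
      interval = c(max(range_log[1], t - 4), min(range_log[2], t + 4)),
      maximum = TRUE, tol = tol
    )
    t <- opt$maximum
  }
  exp(t)
}

# one IRLS pass for beta given theta; returns updated eta and beta
.nb_irls <- function(X, y, eta, theta, max_iter = 50, tol = 1e-10) {
  dev <- Inf
  beta <- NULL
  for (it in seq_len(max_iter)) {
    mu <- exp(eta)
    w <- mu / (1 + mu / theta) # expected-information weight, log link
    z <- eta + (y - mu) / mu
    sw <- sqrt(w)
    fit <- .lm.fit(X * sw, z * sw)
    beta <- fit$coefficients
    eta_new <- drop(X %*% beta)
    eta_new <- pmin(pmax(eta_new, -30), 30)
    dev_new <- .nb_deviance(y, exp(eta_new), theta)
    eta <- eta_new
    if (is.finite(dev) && abs(dev - dev_new) < tol * (abs(dev_new) + 0.1)) {
      dev <- dev_new
      break
    }
    dev <- dev_new
  }
  list(beta = beta, eta = eta, deviance = dev, iter = it)
}

#' Fit a negative-binomial GLM by IRLS with profiled dispersion
#'
#' Log-link negative-binomial regression of counts on a design matrix. The
#' fit alternates (i) iteratively reweighted least squares for the
#' coefficients at fixed dispersion `theta` with (ii) one-dimensional
#' maximisation of the profile log-likelihood over `log(theta)` at the
#' current means, and declares convergence when the relative deviance
#' change falls below `1e-8` and `log(theta)` moves by less than `1e-6`
#' (at most 100 outer cycles; a fit that exhausts them is returned with
#' `converged = FALSE` rather than raising). Standard errors come from the
#' expected information `(X' W X)^{-1}` at the optimum with `theta` held
#' at its estimate.
#'
#' @param X design matrix (full column rank, including any intercept).
#' @param y non-negative integer counts, `length(y) == nrow(X)`.
#' @param init optional starting coefficients.
#' @param theta optional fixed dispersion; when supplied the profile step
#'   is skipped (useful for Poisson-limit checks with very large `theta`).
#' @param control list of knobs: `eps_dev` (1e-8), `eps_theta` (1e-6),
#'   `max_outer` (100), `theta_range` (log-theta search interval,
#'   `c(-7, 20)`).
#' @return An object of class `nbgam`: coefficients, `se`, `vcov`,
#'   `theta`, `deviance`, `loglik`, `converged`, `fitted`, plus the inputs
#'   needed by the methods ([coef()], [vcov()], [predict()],
#'   [residuals()], [logLik()], [summary()]).
#' @examples
#' X <- cbind(1, scale(rpois(50, 3)))
#' y <- rnbinom(50, mu = exp(0.5 + 0.3 * X[, 2]), size = 2)
#' fit <- fit_nb_glm(X, y)
#' coef(fit)
#' @export
fit_nb_glm <- function(X, y, init = NULL, theta = NULL, control = list()) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (any(y < 0) || any(y != floor(y))) {
    stop("y must be non-negative integer counts", call. = FALSE)
  }
  if (all(y == 0)) {
    stop("degenerate response: all counts are zero", call. = FALSE)
  }
  if (n <= p) stop("need more rows than coefficients", call. = FALSE)
  if (qr(X)$rank < p) stop("design matrix is rank deficient", call. = FALSE)
  ctl <- utils::modifyList(
    list(eps_dev = 1e-8, eps_theta = 1e-6, max_outer = 100, theta_range = c(-7, 20)),
    control
  )
  fixed_theta <- !is.null(theta)

  if (is.null(init)) {
    mu0 <- pmax((y + mean(y)) / 2, 1e-3)
    eta <- log(mu0)
    # one least-squares projection onto the design to get a valid eta
    b0 <- .lm.fit(X, eta)$coefficients
    eta <- pmin(pmax(drop(X %*% b0), -30), 30)
  } else {
    eta <- pmin(pmax(drop(X %*% init), -30), 30)
  }
  if (!fixed_theta) {
    mu <- exp(eta)
    vres <- mean((y - mu)^2 - mu)
    theta <- if (vres > 1e-8) max(mean(mu)^2 / vres, 0.05) else 1e6
  }
  log_theta <- log(theta)

  dev_prev <- Inf
  converged <- FALSE
  outer <- 0L
  beta <- NULL
  repeat {
    outer <- outer + 1L
    step <- .nb_irls(X, y, eta, theta)
    beta <- step$beta
    eta <- step$eta
    mu <- exp(eta)
    if (!fixed_theta) {
      theta_new <- .nb_theta_ml(y, mu, theta, range_log = ctl$theta_range)
      d_log_theta <- abs(log(theta_new) - log_theta)
      log_theta <- log(theta_new)
      theta <- theta_new
      # at the edge of the allowed range: effectively Poisson (or maximal
      # overdispersion); treat the dispersion as settled
      at_edge <- log_theta >= ctl$theta_range[2] - 1e-3 ||
        log_theta <= ctl$theta_range[1] + 1e-3
    } else {
      d_log_theta <- 0
      at_edge <- FALSE
    }
    dev <- .nb_deviance(y, mu, theta)
    dev_ok <- is.finite(dev_prev) &&
      abs(dev_prev - dev) < ctl$eps_dev * (abs(dev) + 0.1)
    theta_ok <- d_log_theta < ctl$eps_theta || at_edge
    dev_prev <- dev
    if (dev_ok && theta_ok) {
      converged <- TRUE
      break
    }
    if (outer >= ctl$max_outer) break
  }

  w <- exp(eta) / (1 + exp(eta) / theta)
  XtWX <- crossprod(X * sqrt(w))
  vcov <- tryCatch(chol2inv(chol(XtWX)), error = function(e) solve(XtWX))
  se <- sqrt(pmax(diag(vcov), 0))
  cn <- colnames(X) %||% paste0("b", seq_len(p))
  names(beta) <- names(se) <- cn
  dimnames(vcov) <- list(cn, cn)

  structure(
    list(
      coefficients = beta, se = se, vcov = vcov,
      theta = theta, theta_fixed = fixed_theta,
      deviance = dev_prev, loglik = .nb_loglik(y, exp(eta), theta),
      converged = converged, outer_iterations = outer,
      fitted = exp(eta), y = y, X = X, n = n, df = p
    ),
    class = "nbgam"
  )
}

#' @export
print.nbgam <- function(x, ...) {
  cat(sprintf(
    "Negative-binomial GLM (log link): n = %d, %d coefficients\n  theta = %.4g%s, deviance = %.4g, %s\n",
    x$n, x$df, x$theta, if (x$theta_fixed) " (fixed)" else "",
    x$deviance, if (x$converged) "converged" else "NOT converged"
  ))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.nbgam <- function(object, ...) object$coefficients

#' @export
vcov.nbgam <- function(object, ...) object$vcov

#' @export
logLik.nbgam <- function(object, ...) {
  structure(object$loglik, df = object$df + !object$theta_fixed,
    nobs = object$n, class = "logLik"
  )
}

#' @export
fitted.nbgam <- function(object, ...) object$fitted

#' @export
residuals.nbgam <- function(object, type = c("deviance", "pearson", "response"), ...) {
  mu <- object$fitted
  y <- object$y
  type <- match.arg(type)
  switch(type,
    response = y - mu,
    pearson = (y - mu) / sqrt(mu + mu^2 / object$theta),
    deviance = {
      yy <- pmax(y, 1e-12)
      d <- 2 * (y * log(yy / mu) -
        (y + object$theta) * log((y + object$theta) / (mu + object$theta)))
      sign(y - mu) * sqrt(pmax(d, 0))
    }
  )
}

#' @export
predict.nbgam <- function(object, newX = NULL, type = c("link", "response"),
                          se.fit = FALSE, ...) {
  type <- match.arg(type)
  X <- if (is.null(newX)) object$X else as.matrix(newX)
  eta <- drop(X %*% object$coefficients)
  out <- if (type == "response") exp(eta) else eta
  if (se.fit) {
    se <- sqrt(pmax(rowSums((X %*% object$vcov) * X), 0))
    if (type == "response") se <- se * exp(eta)
    list(fit = out, se.fit = se)
  } else {
    out
  }
}

#' @export
summary.nbgam <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(
    Estimate = object$coefficients, `Std. Error` = object$se,
    `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z))
  )
  structure(
    list(
      coefficients = tab, theta = object$theta, deviance = object$deviance,
      loglik = object$loglik, converged = object$converged, n = object$n
    ),
    class = "summary.nbgam"
  )
}

#' @export
print.summary.nbgam <- function(x, ...) {
  cat(sprintf(
    "Negative-binomial GLM: n = %d, theta = %.4g, logLik = %.2f%s\n",
    x$n, x$theta, x$loglik, if (x$converged) "" else " (NOT converged)"
  ))
  stats::printCoefmat(x$coefficients, digits = 4)
  invisible(x)
}

#' Smooth-term specifications for the abundance model
#'
#' `smooth_spec()` describes one smooth term; `default_smooths()` returns
#' the standard set for checklist effort: thin-plate smooths (basis
#' dimension 4) for number of observers, joint location, duration, day of
#' year and distance travelled, and a cyclic cubic smooth (basis dimension
#' 5, period 1440 min) for the time the observation started.
#'
#' @param vars covariate column name(s); two names make a joint 2-D
#'   thin-plate smooth.
#' @param basis `"tp"` (thin-plate) or `"cc"` (cyclic cubic).
#' @param k basis dimension.
#' @param period cycle length for cyclic smooths.
#' @return `smooth_spec()`: a spec list; `default_smooths()`: a list of
#'   specs.
#' @export
smooth_spec <- function(vars, basis = c("tp", "cc"), k = 4, period = 1440) {
  basis <- match.arg(basis)
  if (basis == "cc" && length(vars) != 1) {
    stop("cyclic smooths take a single covariate", call. = FALSE)
  }
  structure(
    list(vars = vars, basis = basis, k = k, period = period),
    class = "smooth_spec"
  )
}

#' @rdname smooth_spec
#' @export
default_smooths <- function() {
  list(
    smooth_spec("n_observers", "tp", k = 4),
    smooth_spec(c("x", "y"), "tp", k = 4),
    smooth_spec("duration_min", "tp", k = 4),
    smooth_spec("day_of_year", "tp", k = 4),
    smooth_spec("distance_km", "tp", k = 4),
    smooth_spec("time_started", "cc", k = 5, period = 1440)
  )
}

# Build the model design for a species dataset: intercept, linear radiance
# term, then the centred smooth bases. Returns the matrix plus the basis
# objects (for prediction) and the count of rows dropped for missingness.
build_gam_design <- function(dataset, smooths = default_smooths(),
                             alan_col = "alan", log_alan = FALSE) {
  need <- unique(c(alan_col, unlist(lapply(smooths, `[[`, "vars"))))
  miss <- setdiff(need, names(dataset))
  if (length(miss)) {
    stop("dataset lacks column(s): ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  ok <- stats::complete.cases(dataset[, need, drop = FALSE])
  d <- dataset[ok, , drop = FALSE]
  x_alan <- d[[alan_col]]
  if (log_alan) x_alan <- log1p(x_alan)
  cols <- list(`(Intercept)` = rep(1, nrow(d)), alan = x_alan)
  bases <- list()
  for (sp in smooths) {
    xx <- as.matrix(d[, sp$vars, drop = FALSE])
    B <- if (sp$basis == "tp") {
      thinplate_basis(if (ncol(xx) == 1) drop(xx) else xx, k = sp$k)
    } else {
      cyclic_cubic_basis(drop(xx), k = sp$k, period = sp$period)
    }
    nm <- paste0("s(", paste(sp$vars, collapse = ","), ")")
    colnames(B) <- paste0(nm, ".", seq_len(ncol(B)))
    bases[[nm]] <- B
    cols[[nm]] <- B
  }
  X <- do.call(cbind, lapply(cols, unclass))
  colnames(X) <- unlist(lapply(names(cols), function(nm) {
    if (is.matrix(cols[[nm]])) colnames(cols[[nm]]) else nm
  }))
  list(X = X, rows = which(ok), n_dropped = sum(!ok), bases = bases)
}

#' Fit the per-species abundance model
#'
#' Assembles the design (intercept + linear radiance term + centred smooth
#' bases for the effort covariates) and fits the negative-binomial GLM.
#' The coefficient on the radiance term is the quantity of interest: its
#' sign and magnitude measure the species' association with night-time
#' lights once observation effort is smoothed out.
#'
#' @param dataset a species dataset (see [species_dataset()]) carrying the
#'   radiance column and all smooth covariates; rows with missing
#'   covariates are dropped and counted.
#' @param smooths list of [smooth_spec()]s.
#' @param alan_col name of the radiance column.
#' @param log_alan model `log(1 + radiance)` instead of raw radiance.
#' @param min_rows insufficient-data floor after dropping missing rows.
#' @param count_col name of the count response column.
#' @return An object of classes `species_gam` and `nbgam`, additionally
#'   carrying `beta_alan`, `se_alan`, `bases` and `n_dropped`.
#' @export
fit_species_gam <- function(dataset, smooths = default_smooths(),
                            alan_col = "alan", log_alan = FALSE,
                            min_rows = 100, count_col = "count") {
  des <- build_gam_design(dataset, smooths, alan_col, log_alan)
  if (nrow(des$X) < min_rows) {
    stop("insufficient data: ", nrow(des$X), " usable rows (< ", min_rows, ")",
      call. = FALSE
    )
  }
  y <- dataset[[count_col]][des$rows]
  fit <- fit_nb_glm(des$X, y)
  fit$beta_alan <- unname(fit$coefficients["alan"])
  fit$se_alan <- unname(fit$se["alan"])
  fit$bases <- des$bases
  fit$n_dropped <- des$n_dropped
  class(fit) <- c("species_gam", "nbgam")
  fit
}

#' @export
print.species_gam <- function(x, ...) {
  cat(sprintf(
    "Species abundance model: n = %d (%d rows dropped), theta = %.3g, %s\n  radiance coefficient = %.4f (SE %.4f)\n",
    x$n, x$n_dropped, x$theta,
    if (x$converged) "converged" else "NOT converged",
    x$beta_alan, x$se_alan
  ))
  invisible(x)
}
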