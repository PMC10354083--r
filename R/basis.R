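# Spline bases for the effort smooths. Both constructors return an
# n x (k - 1) matrix whose columns sum to zero over the construction data
# (the sum-to-zero identifiability constraint is absorbed by a QR null-space
# reparameterisation), plus the information needed to evaluate the same
# basis functions at new covariate values via eval_basis().

# thin-plate radial kernel: d = 1 -> r^3, d = 2 -> r^2 log r
.tp_eta <- function(r, d) {
  if (d == 1) {
    r^3
  } else {
    out <- r^2 * log(r)
    out[r == 0] <- 0
    out
  }
}

.tp_E <- function(x, knots, d) {
  if (d == 1) {
    .tp_eta(abs(outer(drop(x), drop(knots), `-`)), 1)
  } else {
    dx <- outer(x[, 1], knots[, 1], `-`)
    dy <- outer(x[, 2], knots[, 2], `-`)
    .tp_eta(sqrt(dx^2 + dy^2), 2)
  }
}

# null-space columns of the constraint "columns sum to zero"
.constraint_Z <- function(colsums) {
  qr.Q(qr(matrix(colsums, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
}

.finish_basis <- function(Xraw, info) {
  scales <- sqrt(colMeans(Xraw^2))
  scales[scales < 1e-12] <- 1
  Xs <- sweep(Xraw, 2, scales, `/`)
  Z <- .constraint_Z(colSums(Xs))
  X <- Xs %*% Z
  info$scales <- scales
  info$Z <- Z
  attributes(X) <- c(attributes(X), info)
  class(X) <- c("smooth_basis", "matrix")
  X
}

#' Low-rank thin-plate regression spline basis
#'
#' Builds the fixed-df thin-plate regression spline basis used for the
#' effort smooths: the full thin-plate construction on a set of knots is
#' eigen-truncated to rank `k - M` (M the dimension of the polynomial null
#' space: 2 for one covariate, 3 for a joint two-covariate smooth), the
#' null-space polynomials are appended, and the sum-to-zero constraint is
#' absorbed, leaving `k - 1` centred columns. Together with an intercept
#' the basis reproduces affine functions of the covariate exactly. The
#' basis is unpenalised: `k` is the model's effective dimension, chosen
#' small (default 4) as in fixed-df regression-spline practice.
#'
#' @param x numeric vector (1-D smooth) or two-column matrix (joint 2-D
#'   smooth, e.g. latitude and longitude).
#' @param k basis dimension before the constraint (>= M + 1); the returned
#'   matrix has `k - 1` columns.
#' @param max_knots cap on the number of knots used for the eigen
#'   construction; knots are quantiles (1-D) or an evenly spaced subsample
#'   of the unique points (2-D), chosen deterministically.
#' @return An `n x (k - 1)` matrix of class `smooth_basis` with the
#'   attributes needed by [eval_basis()]. Columns sum to zero.
#' @export
thinplate_basis <- function(x, k = 4, max_knots = 100) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  if (any(!is.finite(x))) stop("non-finite covariate values", call. = FALSE)
  d <- ncol(x)
  if (!d %in% 1:2) stop("thin-plate basis supports 1 or 2 covariates", call. = FALSE)
  M <- d + 1
  if (k < M + 1) stop("k must be at least ", M + 1, " for a ", d, "-D smooth", call. = FALSE)
  ux <- unique(x)
  if (nrow(ux) < k) {
    stop("fewer distinct covariate values (", nrow(ux), ") than k = ", k,
      call. = FALSE
    )
  }
  if (d == 1) {
    n_kn <- min(nrow(ux), max_knots)
    knots <- matrix(unique(stats::quantile(x[, 1],
      probs = seq(0, 1, length.out = n_kn), type = 1, names = FALSE
    )), ncol = 1)
  } else {
    ord <- order(ux[, 1], ux[, 2])
    idx <- unique(round(seq(1, nrow(ux), length.out = min(nrow(ux), max_knots))))
    knots <- ux[ord[idx], , drop = FALSE]
  }
  if (nrow(knots) < k - M + 1) {
    stop("too few distinct knots for the requested k", call. = FALSE)
  }
  Ekk <- .tp_E(knots, knots, d)
  eg <- eigen((Ekk + t(Ekk)) / 2, symmetric = TRUE)
  keep <- order(abs(eg$values), decreasing = TRUE)[seq_len(k - M)]
  U <- eg$vectors[, keep, drop = FALSE]
  Xraw <- cbind(.tp_E(x, knots, d) %*% U, 1, x)
  .finish_basis(Xraw, list(
    basis = "tp", d = d, k = k, knots = knots, U = U
  ))
}

#' Cyclic cubic regression spline basis
#'
#' Periodic cubic B-spline basis on evenly spaced knots over `[0, period]`,
#' used for time-of-day smooths (period 1440 min): every basis function and
#' its first two derivatives match at the period seam, so the fitted smooth
#' wraps continuously across midnight. The sum-to-zero constraint is
#' absorbed as in [thinplate_basis()], which also removes the constant from
#' the span (cyclic B-splines sum to one pointwise).
#'
#' @param t numeric vector of values in `[0, period)`.
#' @param k basis dimension before the constraint (default 5); the returned
#'   matrix has `k - 1` columns.
#' @param period the cycle length (default 1440, minutes per day).
#' @return An `n x (k - 1)` matrix of class `smooth_basis`.
#' @export
cyclic_cubic_basis <- function(t, k = 5, period = 1440) {
  if (any(!is.finite(t))) stop("non-finite covariate values", call. = FALSE)
  if (any(t < 0 | t >= period)) {
    stop("time values must lie in [0, period)", call. = FALSE)
  }
  if (k < 3) stop("cyclic basis needs k >= 3", call. = FALSE)
  knots <- seq(0, period, length.out = k + 1)
  Xraw <- mgcv::cSplineDes(t, knots)
  .finish_basis(Xraw, list(basis = "cc", k = k, knots = knots, period = period))
}

#' Evaluate a stored smooth basis at new covariate values
#'
#' Applies the basis functions (and the constraint reparameterisation fixed
#' at construction time) to new data, e.g. for marginal-effect curves or
#' the periodicity checks at the time-of-day seam. For the cyclic basis,
#' values equal to `period` wrap to 0.
#'
#' @param basis a matrix returned by [thinplate_basis()] or
#'   [cyclic_cubic_basis()].
#' @param newx new covariate values (vector or two-column matrix matching
#'   the construction dimension).
#' @return A matrix with `ncol(basis)` columns.
#' @export
eval_basis <- function(basis, newx) {
  a <- attributes(basis)
  if (is.null(a$basis)) stop("not a smooth_basis object", call. = FALSE)
  if (a$basis == "tp") {
    newx <- if (is.matrix(newx)) newx else matrix(newx, ncol = 1)
    Xraw <- cbind(.tp_E(newx, a$knots, a$d) %*% a$U, 1, newx)
  } else {
    Xraw <- mgcv::cSplineDes(as.numeric(newx) %% a$period, a$knots)
  }
  sweep(Xraw, 2, a$scales, `/`) %*% a$Z
}
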