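#' Fit a univariate partial least squares regression model
#'
#' NIPALS with deflation. The latent-variable solution is collapsed into a
#' single affine map (`coefficients`, `intercept`) so that prediction — in
#' particular pixel-wise inversion of images — is one inner product per
#' spectrum.
#'
#' @param X numeric matrix, samples x variables.
#' @param y numeric response vector, one value per row of `X`.
#' @param n_latent number of latent variables; must be at least 1 and no
#'   larger than `min(ncol(X), nrow(X) - 1)`.
#' @return object of class `plsr_model` with elements `coefficients`
#'   (length `ncol(X)`), `intercept`, `n_latent` (possibly reduced if the
#'   residual collapsed early), `x_means`, `y_mean`, and the score/loading
#'   matrices `W`, `P`, `Q` for the latent-path identity check.
#' @export
fit_plsr <- function(X, y, n_latent) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (n_latent < 1) stop("n_latent must be >= 1")
  cap <- min(p, n - 1L)
  if (n_latent > cap) {
    stop(sprintf("n_latent = %d exceeds rank bound min(n_vars, n_samples - 1) = %d",
                 n_latent, cap))
  }
  if (stats::sd(y) == 0) stop("zero-variance response")

  x_means <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_means)
  yc <- y - y_mean

  W <- matrix(0, p, n_latent)
  P <- matrix(0, p, n_latent)
  Q <- numeric(n_latent)
  a_used <- 0L
  for (a in seq_len(n_latent)) {
    w <- crossprod(Xc, yc)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-12) break  # residual X carries no covariance with y
    w <- w / wn
    t_scores <- Xc %*% w
    tt <- sum(t_scores^2)
    if (tt < 1e-12) break
    p_load <- crossprod(Xc, t_scores) / tt
    q <- sum(yc * t_scores) / tt
    Xc <- Xc - tcrossprod(t_scores, p_load)
    yc <- yc - q * t_scores
    W[, a] <- w; P[, a] <- p_load; Q[a] <- q
    a_used <- a
  }
  if (a_used == 0L) stop("no usable latent variable: X carries no covariance with y")
  W <- W[, seq_len(a_used), drop = FALSE]
  P <- P[, seq_len(a_used), drop = FALSE]
  Q <- Q[seq_len(a_used)]

  # collapsed coefficients: B = W (P'W)^-1 q
  B <- drop(W %*% solve(crossprod(P, W), Q))
  structure(list(
    coefficients = B,
    intercept = y_mean - sum(x_means * B),
    n_latent = a_used,
    x_means = x_means,
    y_mean = y_mean,
    W = W, P = P, Q = Q
  ), class = "plsr_model")
}

#' Predict from a PLSR model
#'
#' @param object a `plsr_model`.
#' @param newdata matrix or vector of spectra (same variables as training).
#' @param path `"collapsed"` (default, single affine map) or `"latent"`
#'   (score-by-score reconstruction); the two agree to numerical tolerance.
#' @param ... unused.
#' @export
predict.plsr_model <- function(object, newdata, path = c("collapsed", "latent"), ...) {
  path <- match.arg(path)
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (path == "collapsed") {
    return(drop(X %*% object$coefficients) + object$intercept)
  }
  Xc <- sweep(X, 2, object$x_means)
  pred <- rep(object$y_mean, nrow(X))
  R <- object$W %*% solve(crossprod(object$P, object$W))
  T_scores <- Xc %*% R
  drop(pred + T_scores %*% object$Q)
}

# Internal: RMSE of k-fold cross-validation at a fixed latent count.
# Folds are a list of index vectors.
rmsecv_folds <- function(X, y, folds, n_latent) {
  sq <- 0
  for (idx in folds) {
    tr_X <- X[-idx, , drop = FALSE]
    tr_y <- y[-idx]
    L <- min(n_latent, ncol(tr_X), nrow(tr_X) - 1L)
    fit <- fit_plsr(tr_X, tr_y, L)
    pred <- predict(fit, X[idx, , drop = FALSE])
    sq <- sq + sum((y[idx] - pred)^2)
  }
  sqrt(sq / length(y))
}

# Internal: seeded-random fold assignment; every fold has >= 2 samples.
make_folds <- function(n, k, seed = NULL) {
  if (k < 2) stop("k must be >= 2")
  if (n < k) stop("need at least k samples")
  if (n < 2 * k) stop(sprintf("a fold would have < 2 samples (n = %d, k = %d)", n, k))
  perm <- with_seed(seed, sample.int(n))
  split(perm, rep_len(seq_len(k), n))
}

#' Cross-validate the latent-variable count of a PLSR model
#'
#' Computes the 5-fold (by default) root mean square error of
#' cross-validation RMSEcv for each latent count `1..max_latent` and
#' returns the minimiser.
#'
#' @param X,y calibration data.
#' @param k number of folds (default 5).
#' @param max_latent largest latent count tried; capped at
#'   `min(20, floor(n/3), ncol(X), n - ceiling(n/k) - 1)`.
#' @param seed integer seed for the random fold assignment.
#' @return list with `best_n_latent`, `rmsecv` (at the best count) and
#'   `rmsecv_by_latent` (the whole curve).
#' @export
cross_validate <- function(X, y, k = 5, max_latent = 15, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  folds <- make_folds(n, k, seed)
  min_train <- min(vapply(folds, function(i) n - length(i), 1L))
  cap <- max(1L, min(20L, floor(n / 3), ncol(X), min_train - 1L))
  Ls <- seq_len(min(max_latent, cap))
  curve <- vapply(Ls, function(L) rmsecv_folds(X, y, folds, L), numeric(1))
  best <- which.min(curve)
  list(best_n_latent = Ls[best], rmsecv = curve[best],
       rmsecv_by_latent = stats::setNames(curve, Ls))
}

#' Score a variable subset by k-fold RMSEcv at a fixed latent count
#'
#' Shared scoring rule of the CARS and IRIV selectors.
#'
#' @inheritParams cross_validate
#' @param n_latent latent count (internally capped by fold training size).
#' @export
plsr_rmsecv <- function(X, y, n_latent, k = 5, seed = NULL) {
  X <- as.matrix(X)
  folds <- make_folds(nrow(X), k, seed)
  rmsecv_folds(X, y, folds, n_latent)
}

#' Evaluate predictions with the chemometric metric panel
#'
#' R-squared (one minus residual over total sum of squares about the
#' evaluated set's own mean), RMSE, and RPD (standard deviation of the
#' reference values over RMSE, n-1 denominator) with the three-way
#' interpretation label: RPD > 2 "good", 1.4-2 "some ability",
#' < 1.4 "unable".
#'
#' @param predicted,observed aligned numeric vectors.
#' @return list `R2`, `RMSE`, `RPD`, `RPD_overflow` (TRUE when RMSE is 0),
#'   `label`.
#' @export
evaluate_metrics <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed))
  sd_ref <- stats::sd(observed)
  if (sd_ref == 0) stop("zero-variance reference vector")
  res <- observed - predicted
  rmse <- sqrt(mean(res^2))
  r2 <- 1 - sum(res^2) / sum((observed - mean(observed))^2)
  overflow <- rmse == 0
  rpd <- if (overflow) Inf else sd_ref / rmse
  label <- if (rpd > 2) "good" else if (rpd >= 1.4) "some ability" else "unable"
  list(R2 = r2, RMSE = rmse, RPD = rpd, RPD_overflow = overflow, label = label)
}

#' Evaluate a fitted model on a prediction set
#'
#' @param model a `plsr_model` (or `fitted_model`, see [fit_pigment_model()]).
#' @param X_pred,y_pred prediction-set spectra (already on the model's
#'   variable subset for a bare `plsr_model`) and reference values.
#' @export
evaluate <- function(model, X_pred, y_pred) {
  pred <- predict(model, X_pred)
  evaluate_metrics(pred, y_pred)
}
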