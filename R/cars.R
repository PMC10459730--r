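#' Exponentially decreasing retention schedule for CARS
#'
#' The fraction of wavelengths retained at Monte Carlo sampling (MCS)
#' run j is \eqn{r_j = a e^{-bj}} with constants fixed by the two
#' boundary conditions \eqn{r_1 = 1} (all p variables survive the first
#' run) and \eqn{r_N = 2/p} (only two survive the last):
#' \eqn{a = (p/2)^{1/(N-1)}}, \eqn{b = \ln(p/2)/(N-1)}.
#'
#' @param p total number of variables (>= 3).
#' @param N number of MCS runs (>= 2).
#' @return list with `a`, `b` and the full ratio sequence `r` (length N).
#' @export
edf_schedule <- function(p, N) {
  if (p < 3) stop("p must be >= 3")
  if (N < 2) stop("N must be >= 2")
  a <- (p / 2)^(1 / (N - 1))
  b <- log(p / 2) / (N - 1)
  j <- seq_len(N)
  list(a = a, b = b, r = a * exp(-b * j))
}

new_variable_subset <- function(indices, source, score = NA_real_,
                                wavelengths = NULL, trace = NULL) {
  structure(list(indices = sort(unique(as.integer(indices))),
                 wavelengths = wavelengths, source = source,
                 score = score, trace = trace),
            class = "variable_subset")
}

#' Competitive adaptive reweighted sampling (CARS) wavelength selection
#'
#' Coarse screening of informative wavelengths. Each MCS run j:
#' \enumerate{
#'   \item draws 80\% of the calibration samples at random and fits a
#'     PLSR model on the currently retained wavelengths, giving absolute
#'     regression coefficients |K_i|;
#'   \item applies the exponentially decreasing function: only the top
#'     `ceiling(r_j * p)` wavelengths by |K_i| survive (ties broken to
#'     the lower index);
#'   \item adaptive reweighted sampling (ARS): p weighted draws with
#'     replacement from the survivors, probabilities
#'     \eqn{w_i = |K_i| / \sum |K_i|}; only the distinct draws stay;
#'   \item scores the run's subset by k-fold RMSEcv on the full
#'     calibration set (fixed folds across runs for comparability).
#' }
#' The subset with the minimum RMSEcv over all runs wins.
#'
#' @param X preprocessed calibration spectra (samples x bands).
#' @param y response vector.
#' @param N number of MCS runs (default 100).
#' @param k cross-validation folds for subset scoring (default 5).
#' @param seed integer seed; fixes the sample draws, the ARS draws and
#'   the CV folds, so the result is reproducible.
#' @param n_latent inner PLSR latent count; chosen once by CV on the
#'   full calibration set when `NULL`, then held fixed across runs
#'   (capped by the shrinking subset size).
#' @param wavelengths optional nm axis for bookkeeping.
#' @return a `variable_subset` with `indices`, `score` (best RMSEcv) and
#'   a `trace` data.frame (`run`, `n_retained`, `rmsecv`); the
#'   per-run retained sets are in `attr(trace, "sets")` and the inner
#'   latent count in `attr(trace, "n_latent")`.
#' @export
cars_select <- function(X, y, N = 100, k = 5, seed = NULL, n_latent = NULL,
                        wavelengths = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  sched <- edf_schedule(p, N)
  fold_seed <- child_seed(seed, "cars_folds")
  if (is.null(n_latent)) {
    n_latent <- cross_validate(X, y, k = k, max_latent = 15,
                               seed = fold_seed)$best_n_latent
  }

  retained <- seq_len(p)
  sets <- vector("list", N)
  nsv <- integer(N)
  rmse <- rep(NA_real_, N)
  with_seed(child_seed(seed, "cars_mcs"), {
    for (j in seq_len(N)) {
      idx <- sample.int(n, floor(0.8 * n))
      L <- max(1L, min(n_latent, length(retained), length(idx) - 1L))
      fit <- fit_plsr(X[idx, retained, drop = FALSE], y[idx], L)
      K <- abs(fit$coefficients)          # aligned with `retained`
      keep_n <- min(length(retained), ceiling(sched$r[j] * p))
      ord <- order(-K, seq_along(K))      # ties: lower position first
      keep_pos <- sort(ord[seq_len(keep_n)])
      retained <- retained[keep_pos]
      K <- K[keep_pos]
      # ARS: p draws (total variable count, the libPLS convention) with
      # replacement from the EDF survivors; drawing only |retained| times
      # compounds a ~0.63 shrink per run and collapses the schedule early.
      if (sum(K) > 0 && length(retained) > 1) {
        draws <- sample(length(retained), size = p,
                        replace = TRUE, prob = K / sum(K))
        pos <- sort(unique(draws))
        retained <- retained[pos]
      }
      if (length(retained) < 2) {
        warning(sprintf(
          "retained set collapsed below 2 variables at run %d; schedule truncated", j))
        break
      }
      sets[[j]] <- retained
      nsv[j] <- length(retained)
      rmse[j] <- plsr_rmsecv(X[, retained, drop = FALSE], y,
                             n_latent = min(n_latent, length(retained)),
                             k = k, seed = fold_seed)
    }
  })
  done <- which(!is.na(rmse))
  if (!length(done)) stop("CARS produced no scorable subset")
  best <- done[which.min(rmse[done])]
  trace <- data.frame(run = done, n_retained = nsv[done], rmsecv = rmse[done])
  attr(trace, "sets") <- sets[done]
  attr(trace, "n_latent") <- n_latent
  new_variable_subset(sets[[best]], source = "CARS", score = rmse[best],
                      wavelengths = if (!is.null(wavelengths)) wavelengths[sets[[best]]],
                      trace = trace)
}
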