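#' Mann-Whitney U test (rank-sum)
#'
#' Two-sample test used by IRIV to compare the RMSEcv populations of
#' models including vs excluding a wavelength. The U statistic for
#' `sample1` is \eqn{U = R_1 - n_1(n_1+1)/2} (midranks for ties). The
#' two-sided p-value is computed from the exact permutation distribution
#' (full enumeration of all \eqn{\binom{n_1+n_2}{n_1}} group
#' assignments) when the combined size is at most `exact_limit`, and
#' from the normal approximation with tie correction and continuity
#' correction otherwise.
#'
#' @param sample1,sample2 non-empty numeric vectors.
#' @param exact_limit combined-size threshold for exact enumeration
#'   (default 12).
#' @return list with `U`, `p_value` (two-sided) and `method`
#'   (`"exact"` or `"normal"`).
#' @export
mann_whitney_u <- function(sample1, sample2, exact_limit = 12) {
  x <- as.numeric(sample1); y <- as.numeric(sample2)
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("both samples must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 + n2 <= exact_limit) {
    combos <- utils::combn(n1 + n2, n1)
    us <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
    return(list(U = U, p_value = p, method = "exact"))
  }
  n <- n1 + n2
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((n + 1) - tie_term))
  if (sigma == 0) return(list(U = U, p_value = 1, method = "normal"))
  z <- (U - mu - sign(U - mu) * 0.5) / sigma
  list(U = U, p_value = min(1, 2 * stats::pnorm(-abs(z))), method = "normal")
}

# Balanced random binary inclusion matrix: each column has exactly m/2
# ones. All-zero rows (likely when p is small) are repaired by moving a
# 1 down its column from a row that can spare it, preserving the exact
# column balance.
balanced_inclusion_matrix <- function(m, p, max_retry = 100) {
  A <- vapply(seq_len(p), function(i) sample(rep(c(0L, 1L), m / 2)),
              integer(m))
  if (p == 1L) A <- matrix(A, ncol = 1)
  for (trial in seq_len(max_retry)) {
    empty <- which(rowSums(A) == 0L)
    if (!length(empty)) return(A)
    for (k in empty) {
      i <- sample.int(p, 1)
      donors <- which(A[, i] == 1L & rowSums(A) >= 2L)
      if (!length(donors)) next
      k2 <- donors[sample.int(length(donors), 1)]
      A[k, i] <- 1L; A[k2, i] <- 0L
    }
  }
  stop("could not build an inclusion matrix without empty rows")
}

# RMSEcv of the mean-only (intercept) predictor, for degenerate rows.
mean_only_rmsecv <- function(y, folds) {
  sq <- 0
  for (idx in folds) sq <- sq + sum((y[idx] - mean(y[-idx]))^2)
  sqrt(sq / length(y))
}

#' IRIV single-round variable classification
#'
#' Iteratively retained informative variables, one round: a balanced
#' m x p binary inclusion matrix A defines m random submodels; each row
#' is fitted by PLSR and scored by k-fold RMSEcv (vector RMSEcv0). For
#' each variable i, column i of A is flipped (matrix B) and every row
#' refitted (vector RMSEcvi). The pooled populations
#' \eqn{\Phi_0(i)} (models that contain i) and \eqn{\Phi_i} (models that
#' exclude i), each of size m, give
#' \eqn{DM_i = \mathrm{mean}(\Phi_0) - \mathrm{mean}(\Phi_i)} and a
#' two-sided Mann-Whitney p-value. Classification at threshold 0.05:
#' DM < 0 & p < 0.05 strong; DM < 0 & p >= 0.05 weak; DM > 0 &
#' p >= 0.05 uninformative; DM > 0 & p < 0.05 interfering.
#'
#' @param X preprocessed spectra restricted to the candidate variables.
#' @param y response.
#' @param m submodel count (rows of A); even, >= 20 (default 200).
#' @param k CV folds (default 5).
#' @param seed integer seed (matrix A and CV folds).
#' @param n_latent latent-count cap per submodel; each row uses
#'   `min(n_latent, included-variable count)`.
#' @return data.frame with one row per variable: `index`, `DM`,
#'   `p_value`, `class`.
#' @export
iriv_classify <- function(X, y, m = 200, k = 5, seed = NULL, n_latent = 10) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (p < 2) stop("need at least 2 candidate variables")
  if (m %% 2 != 0 || m < 20) stop("m must be even and >= 20")
  folds <- make_folds(nrow(X), k, child_seed(seed, "iriv_folds"))
  A <- with_seed(child_seed(seed, "iriv_A"), balanced_inclusion_matrix(m, p))

  score_row <- function(vars) {
    if (!length(vars)) return(mean_only_rmsecv(y, folds))
    rmsecv_folds(X[, vars, drop = FALSE], y,
                 folds, max(1L, min(n_latent, length(vars))))
  }
  rmsecv0 <- vapply(seq_len(m), function(kk) score_row(which(A[kk, ] == 1)),
                    numeric(1))
  DM <- numeric(p); pv <- numeric(p)
  for (i in seq_len(p)) {
    rmsecvi <- vapply(seq_len(m), function(kk) {
      row <- A[kk, ]
      row[i] <- 1L - row[i]
      score_row(which(row == 1))
    }, numeric(1))
    inc0 <- A[, i] == 1
    phi0 <- c(rmsecv0[inc0], rmsecvi[!inc0])   # models containing i
    phii <- c(rmsecv0[!inc0], rmsecvi[inc0])   # models excluding i
    DM[i] <- mean(phi0) - mean(phii)
    pv[i] <- mann_whitney_u(phi0, phii)$p_value
  }
  cls <- ifelse(DM <= 0,
                ifelse(pv < 0.05, "strong", "weak"),
                ifelse(pv < 0.05, "interfering", "uninformative"))
  data.frame(index = seq_len(p), DM = DM, p_value = pv, class = cls,
             stringsAsFactors = FALSE)
}

#' Iterate IRIV classification until only strong/weak variables remain
#'
#' Repeatedly classifies the surviving variables and drops the
#' uninformative and interfering ones; stops at the first round that
#' eliminates nothing.
#'
#' @inheritParams iriv_classify
#' @return list with `indices` (surviving 1-based columns of the input
#'   `X`), `rounds` (list of per-round classification tables, indices in
#'   input coordinates), and `n_rounds`.
#' @export
iriv_iterate <- function(X, y, m = 200, k = 5, seed = NULL, n_latent = 10) {
  X <- as.matrix(X)
  survivors <- seq_len(ncol(X))
  rounds <- list()
  round_no <- 0L
  repeat {
    round_no <- round_no + 1L
    cl <- iriv_classify(X[, survivors, drop = FALSE], y, m = m, k = k,
                        seed = child_seed(seed, paste0("round", round_no)),
                        n_latent = n_latent)
    cl$index <- survivors[cl$index]
    rounds[[round_no]] <- cl
    keep <- cl$class %in% c("strong", "weak")
    if (!any(keep)) {
      stop("all variables eliminated; increase m or skip fine selection")
    }
    if (all(keep)) break
    survivors <- cl$index[keep]
    if (length(survivors) < 2) break
  }
  list(indices = survivors, rounds = rounds, n_rounds = round_no)
}

#' Backward elimination on a retained variable set
#'
#' Greedy best-improvement removal: at each pass the RMSEcv of the
#' current t-variable model is compared with every (t-1)-variable model
#' obtained by dropping one variable; the drop giving the largest RMSEcv
#' decrease is accepted. Stops when no single removal decreases RMSEcv
#' (or two variables remain). The final RMSEcv never exceeds the
#' initial one.
#'
#' @param X preprocessed spectra (full candidate columns).
#' @param y response.
#' @param vars integer vector of candidate columns of `X` (>= 2).
#' @param k CV folds.
#' @param seed integer seed (CV folds, fixed across comparisons).
#' @param n_latent latent-count cap.
#' @return list with `indices` (final set, sorted) and `rmsecv`.
#' @export
backward_eliminate <- function(X, y, vars, k = 5, seed = NULL, n_latent = 10) {
  X <- as.matrix(X)
  vars <- sort(unique(as.integer(vars)))
  if (length(vars) < 2) stop("need at least 2 variables")
  folds <- make_folds(nrow(X), k, child_seed(seed, "backelim_folds"))
  score <- function(v) rmsecv_folds(X[, v, drop = FALSE], y, folds,
                                    max(1L, min(n_latent, length(v))))
  current <- vars
  cur_rmse <- score(current)
  while (length(current) > 2) {
    trial <- vapply(seq_along(current),
                    function(j) score(current[-j]), numeric(1))
    best <- which.min(trial)
    if (trial[best] < cur_rmse) {
      current <- current[-best]
      cur_rmse <- trial[best]
    } else break
  }
  list(indices = current, rmsecv = cur_rmse)
}

#' Coarse-fine wavelength selection: CARS followed by IRIV
#'
#' Runs [cars_select()] for the coarse screen, then [iriv_iterate()] and
#' [backward_eliminate()] on the CARS survivors for the fine screen. The
#' final subset is always contained in the CARS subset.
#'
#' @inheritParams cars_select
#' @param m IRIV submodel count (default 200).
#' @return `variable_subset` with `source = "CARS-IRIV"`; the CARS stage
#'   result is attached as attribute `"cars"` and the IRIV rounds as
#'   attribute `"iriv_rounds"`.
#' @export
cars_iriv_select <- function(X, y, N = 100, m = 200, k = 5, seed = NULL,
                             n_latent = NULL, wavelengths = NULL) {
  cars <- cars_select(X, y, N = N, k = k, seed = seed, n_latent = n_latent,
                      wavelengths = wavelengths)
  nl <- attr(cars$trace, "n_latent")
  Xc <- as.matrix(X)[, cars$indices, drop = FALSE]
  it <- iriv_iterate(Xc, y, m = m, k = k, seed = child_seed(seed, "iriv"),
                     n_latent = nl)
  kept <- cars$indices[it$indices]
  if (length(kept) >= 2) {
    be <- backward_eliminate(as.matrix(X), y, kept, k = k,
                             seed = child_seed(seed, "backelim"), n_latent = nl)
    kept <- be$indices
    score <- be$rmsecv
  } else {
    score <- plsr_rmsecv(as.matrix(X)[, kept, drop = FALSE], y, 1L, k = k,
                         seed = child_seed(seed, "backelim_folds"))
  }
  out <- new_variable_subset(kept, source = "CARS-IRIV", score = score,
                             wavelengths = if (!is.null(wavelengths)) wavelengths[kept])
  attr(out, "cars") <- cars
  attr(out, "iriv_rounds") <- it$rounds
  out
}
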