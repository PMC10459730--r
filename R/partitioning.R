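#' SPXY calibration/prediction split
#'
#' Sample-set partitioning based on joint X-Y distance (Galvao et al.):
#' pairwise Euclidean distance in the spectra and absolute difference in
#' the response are each normalised by their maximum and summed,
#' \deqn{d(i,j) = d_X(i,j)/\max d_X + d_Y(i,j)/\max d_Y,}
#' then a Kennard-Stone selection runs on the joint distance: seed with
#' the most distant pair, then repeatedly add the sample whose minimum
#' distance to the chosen set is largest, until `floor(fraction * N)`
#' calibration samples are selected. The remainder is the prediction
#' set. Ties break to the lowest index, so the split is deterministic.
#'
#' @param spectra samples x bands matrix.
#' @param response numeric response aligned to the rows, or a matrix of
#'   several responses (joint Euclidean Y-distance) for a simultaneous
#'   multi-pigment split.
#' @param fraction calibration share in (0, 1); default 0.75.
#' @return list of class `spxy_split` with `calibration`, `prediction`
#'   (1-based row indices, each sorted) and `fraction`.
#' @export
spxy_split <- function(spectra, response, fraction = 0.75) {
  X <- as.matrix(spectra)
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  Y <- if (is.null(dim(response))) matrix(response, ncol = 1) else as.matrix(response)
  if (nrow(Y) != n) stop("response not aligned to spectra")

  dX <- as.matrix(stats::dist(X))
  dY <- as.matrix(stats::dist(Y))
  mX <- max(dX); mY <- max(dY)
  if (mX == 0 && mY == 0) stop("all samples identical: SPXY distance degenerate")
  D <- (if (mX > 0) dX / mX else 0) + (if (mY > 0) dY / mY else 0)

  n_cal <- floor(fraction * n)
  if (n_cal < 2) stop("fraction too small: calibration set needs >= 2 samples")

  # seed: most distant pair (lowest indices on ties)
  seed_pair <- which(D == max(D), arr.ind = TRUE)
  seed_pair <- seed_pair[order(seed_pair[, 1], seed_pair[, 2]), , drop = FALSE]
  sel <- sort(unique(as.integer(seed_pair[1, ])))
  min_d <- unname(pmin(D[, sel[1]], D[, sel[2]]))
  min_d[sel] <- -Inf
  while (length(sel) < n_cal) {
    nxt <- as.integer(which.max(min_d))  # first (lowest) index on ties
    sel <- c(sel, nxt)
    min_d <- pmin(min_d, D[, nxt])
    min_d[nxt] <- -Inf
  }
  sel <- sort(sel)
  structure(list(calibration = sel,
                 prediction = setdiff(seq_len(n), sel),
                 fraction = fraction),
            class = "spxy_split")
}

#' Random split (explicit alternative to SPXY)
#'
#' @inheritParams spxy_split
#' @param seed integer RNG seed.
#' @export
random_split <- function(n, fraction = 0.75, seed = NULL) {
  n_cal <- floor(fraction * n)
  sel <- sort(with_seed(seed, sample.int(n, n_cal)))
  structure(list(calibration = sel, prediction = setdiff(seq_len(n), sel),
                 fraction = fraction), class = "spxy_split")
}
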