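#' Savitzky-Golay smoothing of spectra
#'
#' Per-row local least-squares polynomial smoothing. Interior points use
#' the centred window; near the edges the polynomial is fitted on the
#' truncated one-sided window (no padding), so the band count is
#' preserved and a degree-<= `polyorder` polynomial row is reproduced
#' exactly everywhere.
#'
#' @param spectra numeric matrix (samples x bands) or vector.
#' @param window odd window length, greater than `polyorder` and no
#'   larger than the band count (default 11).
#' @param polyorder polynomial degree (default 2).
#' @return smoothed matrix of the same shape.
#' @export
sg_smooth <- function(spectra, window = 11, polyorder = 2) {
  vec <- is.null(dim(spectra))
  X <- if (vec) matrix(spectra, nrow = 1) else as.matrix(spectra)
  p <- ncol(X)
  if (window %% 2 == 0) stop("window must be odd")
  if (window <= polyorder) stop("window must exceed polyorder")
  if (window > p) stop("window exceeds band count")
  half <- (window - 1) / 2

  # Precompute one smoothing row per output position: the value of the
  # local polynomial fit at that position, as a linear filter over its
  # (possibly truncated) window.
  filt <- vector("list", p)
  for (j in seq_len(p)) {
    lo <- max(1L, j - half); hi <- min(p, j + half)
    xs <- (lo:hi) - j
    V <- outer(xs, 0:polyorder, `^`)
    # fitted value at offset 0 = e1' (V'V)^-1 V' y
    w <- solve(crossprod(V), t(V))[1, ]
    filt[[j]] <- list(idx = lo:hi, w = w)
  }
  out <- X
  for (j in seq_len(p)) {
    out[, j] <- X[, filt[[j]]$idx, drop = FALSE] %*% filt[[j]]$w
  }
  if (vec) drop(out) else out
}

#' Standard normal variate transform
#'
#' Each spectrum (row) is centred and scaled to unit standard deviation
#' (n-1 denominator), removing per-sample multiplicative gain and
#' additive offset exactly.
#'
#' @param spectra matrix (samples x bands) or vector.
#' @return transformed matrix; each row has mean 0 and sd 1.
#' @export
snv <- function(spectra) {
  vec <- is.null(dim(spectra))
  X <- if (vec) matrix(spectra, nrow = 1) else as.matrix(spectra)
  m <- rowMeans(X)
  s <- apply(X, 1, stats::sd)
  bad <- which(s == 0)
  if (length(bad)) {
    stop(sprintf("degenerate (constant) spectrum in row(s): %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  out <- (X - m) / s
  if (vec) drop(out) else out
}

#' Build a preprocessing recipe
#'
#' @param steps one of `"none"`, `"sg"`, `"snv"`, `"sg+snv"` (smoothing is
#'   applied before SNV in the combination).
#' @param sg_window,sg_polyorder Savitzky-Golay parameters.
#' @return object of class `preprocess_recipe`.
#' @export
preprocess_recipe <- function(steps = c("none", "sg", "snv", "sg+snv"),
                              sg_window = 11, sg_polyorder = 2) {
  steps <- match.arg(steps)
  if (sg_window %% 2 == 0 || sg_window <= sg_polyorder) {
    stop("sg_window must be odd and exceed sg_polyorder")
  }
  structure(list(steps = steps, sg_window = sg_window,
                 sg_polyorder = sg_polyorder),
            class = "preprocess_recipe")
}

#' Apply a preprocessing recipe to spectra
#'
#' The recipe is stored inside fitted models so the same pretreatment is
#' replayed at prediction and pixel-inversion time.
#'
#' @param spectra matrix (samples x bands) or single spectrum vector.
#' @param recipe a [preprocess_recipe()] or one of its `steps` strings.
#' @export
apply_recipe <- function(spectra, recipe) {
  if (is.character(recipe)) recipe <- preprocess_recipe(recipe)
  stopifnot(inherits(recipe, "preprocess_recipe"))
  out <- spectra
  if (recipe$steps %in% c("sg", "sg+snv")) {
    out <- sg_smooth(out, recipe$sg_window, recipe$sg_polyorder)
  }
  if (recipe$steps %in% c("snv", "sg+snv")) {
    out <- snv(out)
  }
  out
}

#' Per-pigment default pretreatments
#'
#' The pipeline defaults to the pretreatment that performed best for each
#' pigment in full-spectrum PLSR comparisons: SG+SNV for chlorophyll a,
#' SG for chlorophyll b, SNV for total chlorophylls and carotenoids.
#' Overridable wherever a recipe is accepted.
#'
#' @return named list of `preprocess_recipe` objects.
#' @export
default_recipes <- function() {
  list(Chla = preprocess_recipe("sg+snv"),
       Chlb = preprocess_recipe("sg"),
       Chls = preprocess_recipe("snv"),
       Cars = preprocess_recipe("snv"))
}
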