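#' Fit a pigment prediction model with optional wavelength selection
#'
#' End-to-end single-pigment path: pretreat the raw spectra with the
#' recipe, partition with SPXY on that pigment's response, run the
#' chosen wavelength selector on the calibration set, pick the latent
#' count by cross-validation, fit the PLSR and evaluate on both sets.
#'
#' @param spectra raw samples x bands matrix.
#' @param y pigment concentrations (mg/L), aligned to the rows.
#' @param wavelengths nm axis, one per column.
#' @param recipe [preprocess_recipe()] or steps string (default
#'   `"none"`).
#' @param selector `"none"`, `"cars"` or `"cars-iriv"`.
#' @param fraction SPXY calibration share (default 0.75).
#' @param split optional precomputed `spxy_split` (reused across
#'   selectors for a fair comparison).
#' @param N,m,k selector parameters (CARS runs, IRIV submodels, CV
#'   folds).
#' @param seed integer seed.
#' @param pigment label carried into maps and reports.
#' @return object of class `fitted_model`: `plsr`, `band_indices`,
#'   `wavelengths_selected`, `recipe`, `pigment`, `selection`
#'   (`variable_subset` or NULL), `split`, and `metrics` (`calibration`
#'   and `prediction`, each an [evaluate_metrics()] panel).
#' @export
fit_pigment_model <- function(spectra, y, wavelengths,
                              recipe = "none",
                              selector = c("none", "cars", "cars-iriv"),
                              fraction = 0.75, split = NULL,
                              N = 100, m = 200, k = 5,
                              seed = 1L, pigment = "pigment") {
  selector <- match.arg(selector)
  if (is.character(recipe)) recipe <- preprocess_recipe(recipe)
  X <- apply_recipe(as.matrix(spectra), recipe)
  if (is.null(split)) split <- spxy_split(X, y, fraction)
  Xc <- X[split$calibration, , drop = FALSE]
  yc <- y[split$calibration]

  selection <- switch(selector,
    none = NULL,
    cars = cars_select(Xc, yc, N = N, k = k, seed = seed,
                       wavelengths = wavelengths),
    `cars-iriv` = cars_iriv_select(Xc, yc, N = N, m = m, k = k, seed = seed,
                                   wavelengths = wavelengths))
  idx <- if (is.null(selection)) seq_len(ncol(X)) else selection$indices

  cv <- cross_validate(Xc[, idx, drop = FALSE], yc, k = k,
                       seed = child_seed(seed, "final_cv"))
  fit <- fit_plsr(Xc[, idx, drop = FALSE], yc, cv$best_n_latent)

  cal <- evaluate(fit, Xc[, idx, drop = FALSE], yc)
  Xp <- X[split$prediction, , drop = FALSE]
  pred <- evaluate(fit, Xp[, idx, drop = FALSE], y[split$prediction])

  structure(list(plsr = fit,
                 band_indices = idx,
                 wavelengths_selected = wavelengths[idx],
                 recipe = recipe,
                 pigment = pigment,
                 selector = selector,
                 selection = selection,
                 split = split,
                 rmsecv = cv$rmsecv,
                 metrics = list(calibration = cal, prediction = pred)),
            class = "fitted_model")
}

#' @export
predict.fitted_model <- function(object, newdata, ...) {
  X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  X <- apply_recipe(X, object$recipe)
  predict(object$plsr, X[, object$band_indices, drop = FALSE])
}

#' Share of the full spectrum taken by a selected subset
#'
#' `100 * k / p` rounded half-up to two decimals (the bookkeeping
#' convention of selected-wavelength reports, e.g. 16 of 646 bands is
#' 2.48).
#'
#' @param k selected count (0 <= k <= p).
#' @param p total band count (> 0).
#' @export
percent_of_spectrum <- function(k, p) {
  if (any(p <= 0)) stop("p must be positive")
  if (any(k < 0 | k > p)) stop("k must lie in [0, p]")
  round_half_up(100 * k / p, 2)
}

#' Format a selected-wavelength share as "x.xx% (k/p)"
#'
#' @inheritParams percent_of_spectrum
#' @export
format_percent <- function(k, p) {
  sprintf("%.2f%% (%d/%d)", percent_of_spectrum(k, p), k, p)
}

#' Run the full model-comparison study on a dataset
#'
#' For each pigment and selector, trains and evaluates a model and
#' assembles a comparison table (Rc2, RMSEc, Rp2, RMSEp, RPD, selected
#' count, percent of spectrum). Wavelength selection is repeated
#' `n_runs` times with distinct child seeds and the best outcome by
#' selection RMSEcv is reported; the SPXY split is computed once per
#' pigment and shared across selectors.
#'
#' @param ds dataset as returned by [generate_dataset()] (or an
#'   equivalent list with `spectra`, `wavelengths`, `pigments`).
#' @param pigments which pigment columns to model.
#' @param selectors which selectors to compare.
#' @param recipes named list of recipes (default [default_recipes()]).
#' @param n_runs repeated selection executions (default 5).
#' @param fraction,N,m,k pipeline parameters.
#' @param seed master seed; all child seeds derive from it, so the
#'   report regenerates bit-identically.
#' @return list with `report` (data.frame) and `models` (nested list
#'   pigment -> selector -> `fitted_model`).
#' @export
run_study <- function(ds,
                      pigments = c("Chla", "Chlb", "Chls", "Cars"),
                      selectors = c("none", "cars", "cars-iriv"),
                      recipes = default_recipes(),
                      n_runs = 5, fraction = 0.75,
                      N = 100, m = 200, k = 5, seed = 1L) {
  rows <- list()
  models <- list()
  p_total <- ncol(ds$spectra)
  for (pg in pigments) {
    y <- ds$pigments[[pg]]
    recipe <- recipes[[pg]] %||% preprocess_recipe("none")
    X <- apply_recipe(as.matrix(ds$spectra), recipe)
    split <- spxy_split(X, y, fraction)
    for (sel in selectors) {
      runs <- if (sel == "none") 1L else n_runs
      best <- NULL
      for (r in seq_len(runs)) {
        fm <- fit_pigment_model(ds$spectra, y, ds$wavelengths,
                                recipe = recipe, selector = sel,
                                fraction = fraction, split = split,
                                N = N, m = m, k = k,
                                seed = child_seed(seed, paste(pg, sel, r)),
                                pigment = pg)
        score <- if (is.null(fm$selection)) fm$rmsecv else fm$selection$score
        if (is.null(best) || score < best$score) {
          best <- list(model = fm, score = score)
        }
      }
      fm <- best$model
      n_sel <- length(fm$band_indices)
      rows[[length(rows) + 1L]] <- data.frame(
        pigment = pg, selector = sel,
        Rc2 = fm$metrics$calibration$R2,
        RMSEc = fm$metrics$calibration$RMSE,
        Rp2 = fm$metrics$prediction$R2,
        RMSEp = fm$metrics$prediction$RMSE,
        RPD = fm$metrics$prediction$RPD,
        n_selected = n_sel,
        percent = percent_of_spectrum(n_sel, p_total),
        stringsAsFactors = FALSE)
      models[[pg]][[sel]] <- fm
    }
  }
  list(report = do.call(rbind, rows), models = models)
}

# ---- model serialization ---------------------------------------------------

#' Write a fitted model to JSON
#'
#' Stores the selected wavelengths, collapsed coefficients, intercept,
#' latent count, preprocessing recipe and evaluation metrics — all that
#' pixel inversion needs.
#'
#' @param model a `fitted_model`.
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  obj <- list(pigment = model$pigment,
              selector = model$selector,
              recipe = unclass(model$recipe),
              band_indices = model$band_indices,
              wavelengths = model$wavelengths_selected,
              coefficients = model$plsr$coefficients,
              intercept = model$plsr$intercept,
              n_latent = model$plsr$n_latent,
              metrics = model$metrics)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' Rebuilds a minimal `fitted_model` sufficient for prediction and
#' pixel inversion (the latent loadings are not round-tripped; the
#' collapsed affine map is).
#'
#' @param path JSON path from [write_model_json()].
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  plsr <- structure(list(coefficients = as.numeric(obj$coefficients),
                         intercept = obj$intercept,
                         n_latent = obj$n_latent),
                    class = "plsr_model")
  recipe <- preprocess_recipe(obj$recipe$steps, obj$recipe$sg_window,
                              obj$recipe$sg_polyorder)
  structure(list(plsr = plsr,
                 band_indices = as.integer(obj$band_indices),
                 wavelengths_selected = as.numeric(obj$wavelengths),
                 recipe = recipe,
                 pigment = obj$pigment,
                 selector = obj$selector,
                 selection = NULL,
                 metrics = obj$metrics),
            class = "fitted_model")
}
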