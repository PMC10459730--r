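#' Configuration for the synthetic hyperspectral leaf generator
#'
#' The generator stands in for an unreleased greenhouse dataset: 435
#' leaf samples over 10 nitrogen levels (N20..N200) and 3 canopy
#' positions, each with a 646-band reflectance spectrum on 430-900 nm.
#' Spectra are built as a smooth baseline minus
#' concentration-weighted Gaussian absorption profiles (defaults in the
#' literature pigment windows 435-510, 660-760 and 800-895 nm, width
#' 15 nm), then distorted by per-sample multiplicative gain plus
#' additive offset (the scatter SNV removes) and i.i.d. high-frequency
#' noise (which Savitzky-Golay suppresses).
#'
#' @param n_samples sample count (default 435).
#' @param n_bands band count (default 646, >= 2).
#' @param wavelength_range nm pair (default `c(430, 900)`).
#' @param nitrogen_levels level labels; concentrations follow a concave
#'   quadratic response peaking at the middle level (N100 by default).
#' @param leaf_positions position labels; a monotone Upper > Middle >
#'   Lower effect is applied.
#' @param pigment_ranges named list of `c(min, max)` mg/L for `Chla`,
#'   `Chlb`, `Cars` (total chlorophylls are the exact sum Chla + Chlb).
#' @param planted_bands named list of absorption-centre wavelengths (nm)
#'   per generative pigment; 8 per pigment by default.
#' @param profile_width Gaussian absorption width (nm, default 15).
#' @param scatter_sd sd of the multiplicative gain about 1 (default
#'   0.05); the additive offset sd is `scatter_sd / 10`.
#' @param noise_sd sd of the i.i.d. reflectance noise (default 0.002).
#'   Noise is injected before scatter so SNV removes the scatter exactly.
#' @param reference_error_sd sd of the reference-chemistry measurement
#'   error on the reported concentrations, as a fraction of each
#'   pigment's range (default 0.09). Spectra are driven by the true
#'   concentrations; the paired references carry this error, which is
#'   what caps attainable prediction R-squared near the levels typical
#'   of wet-chemistry-calibrated leaf models. Total chlorophylls are the
#'   sum of the two reported chlorophyll channels, so their identity is
#'   preserved under the error.
#' @param seed integer master seed; fans out to per-stage child seeds.
#' @export
sim_config <- function(n_samples = 435,
                       n_bands = 646,
                       wavelength_range = c(430, 900),
                       nitrogen_levels = paste0("N", seq(20, 200, by = 20)),
                       leaf_positions = c("Upper", "Middle", "Lower"),
                       pigment_ranges = list(Chla = c(3.37, 21.13),
                                             Chlb = c(1.22, 8.49),
                                             Cars = c(0.60, 3.23)),
                       planted_bands = list(
                         Chla = c(445, 475, 505, 665, 691, 715, 760, 850),
                         Chlb = c(455, 480, 500, 649, 702, 730, 805, 870),
                         Cars = c(435, 452, 470, 490, 510, 660, 820, 895)),
                       profile_width = 15,
                       scatter_sd = 0.05,
                       noise_sd = 0.002,
                       reference_error_sd = 0.09,
                       seed = 1L) {
  if (n_samples < 1 || n_bands < 2) stop("non-positive or too-small counts")
  if (wavelength_range[2] <= wavelength_range[1]) {
    stop("wavelength range must be increasing")
  }
  for (nm in names(pigment_ranges)) {
    r <- pigment_ranges[[nm]]
    if (any(r <= 0) || r[1] >= r[2]) {
      stop(sprintf("pigment range for %s must be positive with min < max", nm))
    }
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_bands = as.integer(n_bands),
                 wavelength_range = wavelength_range,
                 nitrogen_levels = nitrogen_levels,
                 leaf_positions = leaf_positions,
                 pigment_ranges = pigment_ranges,
                 planted_bands = planted_bands,
                 profile_width = profile_width,
                 scatter_sd = scatter_sd,
                 noise_sd = noise_sd,
                 reference_error_sd = reference_error_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

sim_wavelengths <- function(config) {
  seq(config$wavelength_range[1], config$wavelength_range[2],
      length.out = config$n_bands)
}

# Gaussian absorption profile per pigment over the wavelength axis,
# peak-normalised to 1, plus the nearest band index of each centre.
pure_profiles <- function(config) {
  wl <- sim_wavelengths(config)
  out <- list()
  for (pg in names(config$planted_bands)) {
    centers <- config$planted_bands[[pg]]
    prof <- rowSums(vapply(centers, function(c0) {
      exp(-(wl - c0)^2 / (2 * config$profile_width^2))
    }, numeric(length(wl))))
    out[[pg]] <- list(profile = prof / max(prof),
                      band_indices = vapply(centers, function(c0) {
                        which.min(abs(wl - c0))
                      }, integer(1)))
  }
  out
}

# Smooth leaf-like reflectance baseline: low in the visible, rising
# through the red edge to a NIR plateau.
sim_baseline <- function(wl) {
  0.30 + 0.30 / (1 + exp(-(wl - 700) / 18))
}

# Concave quadratic nitrogen response peaking at the middle level,
# times a monotone canopy-position factor (Upper > Middle > Lower).
nitrogen_position_driver <- function(level_idx, n_levels, pos_idx) {
  peak <- (n_levels + 1) / 2
  f <- 1 - 0.45 * ((level_idx - peak) / (n_levels - peak))^2
  g <- c(1.15, 1.00, 0.85)[pos_idx]
  f * g
}

#' Generate a synthetic spectra matrix with paired pigment references
#'
#' Forward model: for sample s with concentrations c (mg/L),
#' \deqn{x_s(\lambda) = \mathrm{baseline}(\lambda) -
#'   \sum_p c_p \kappa_p \phi_p(\lambda) + \epsilon,}
#' then multiplicative/additive scatter. \eqn{\kappa_p} scales each
#' pigment's maximum absorption depth to 0.10 reflectance units at the
#' top of its range so spectra stay positive. Total chlorophylls are the
#' exact sum of the a and b channels in every sample.
#'
#' @param config a [sim_config()].
#' @return list with `spectra` (n_samples x n_bands), `wavelengths`,
#'   `pigments` (data.frame Chla/Chlb/Chls/Cars in mg/L), `meta`
#'   (sample_id, nitrogen, position) and `truth`
#'   (per-pigment `informative_band_indices`, `pure_spectra`, plus the
#'   clean undistorted spectra for invariance tests).
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  wl <- sim_wavelengths(config)
  profs <- pure_profiles(config)
  pigs <- names(config$pigment_ranges)

  meta <- expand.grid(position = seq_along(config$leaf_positions),
                      level = seq_along(config$nitrogen_levels))
  meta <- meta[rep_len(seq_len(nrow(meta)), n), ]
  row.names(meta) <- NULL

  conc <- with_seed(child_seed(config$seed, "conc"), {
    out <- matrix(0, n, length(pigs), dimnames = list(NULL, pigs))
    driver <- nitrogen_position_driver(meta$level,
                                       length(config$nitrogen_levels),
                                       meta$position)
    # driver spans [0.55*0.85, 1.15]; normalise to [0, 1]
    d01 <- (driver - min(driver)) / (max(driver) - min(driver))
    for (pg in pigs) {
      r <- config$pigment_ranges[[pg]]
      val <- r[1] + (r[2] - r[1]) * (0.08 + 0.80 * d01 +
                                       stats::rnorm(n, 0, 0.06))
      out[, pg] <- pmin(pmax(val, r[1]), r[2])
    }
    out
  })
  # reported references = true concentrations + wet-chemistry error;
  # spectra below are driven by the true values
  reported <- with_seed(child_seed(config$seed, "reference_error"), {
    out <- conc
    for (pg in pigs) {
      r <- config$pigment_ranges[[pg]]
      out[, pg] <- conc[, pg] +
        stats::rnorm(n, 0, config$reference_error_sd * (r[2] - r[1]))
    }
    out
  })
  pigments <- as.data.frame(reported)
  if (all(c("Chla", "Chlb") %in% pigs)) {
    pigments$Chls <- pigments$Chla + pigments$Chlb
  }

  depth <- 0.10
  kappa <- vapply(pigs, function(pg) depth / config$pigment_ranges[[pg]][2],
                  numeric(1))
  clean <- matrix(rep(sim_baseline(wl), each = n), n, config$n_bands)
  for (pg in pigs) {
    clean <- clean - outer(conc[, pg] * kappa[[pg]], profs[[pg]]$profile)
  }
  spectra <- with_seed(child_seed(config$seed, "noise"), {
    noisy <- clean + matrix(stats::rnorm(n * config$n_bands, 0, config$noise_sd),
                            n, config$n_bands)
    gain <- 1 + stats::rnorm(n, 0, config$scatter_sd)
    offset <- stats::rnorm(n, 0, config$scatter_sd / 10)
    noisy * gain + offset
  })
  colnames(spectra) <- sprintf("wl_%.3f", wl)

  informative <- lapply(profs, `[[`, "band_indices")
  informative$Chls <- sort(union(informative$Chla, informative$Chlb))
  list(spectra = spectra,
       wavelengths = wl,
       pigments = pigments,
       meta = data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                         nitrogen = config$nitrogen_levels[meta$level],
                         position = config$leaf_positions[meta$position]),
       truth = list(informative_band_indices = informative,
                    pure_spectra = lapply(profs, `[[`, "profile"),
                    kappa = kappa,
                    true_concentrations = as.data.frame(conc),
                    clean_spectra = clean))
}

#' Generate a synthetic leaf cube from a concentration map
#'
#' Per-pixel forward model for visualisation round trips. The map gives
#' the named pigment's concentration (mg/L) per pixel; zero marks
#' background. The other generative pigments co-vary proportionally
#' (fixed mid-range stoichiometric ratios), mimicking the correlated
#' pigment pools of real leaves so that models trained on
#' [generate_dataset()] output invert cleanly. Background pixels carry a
#' flat low spectrum, and white/dark reference frames are emitted so the
#' raw cube round-trips through [correct_reflectance()].
#'
#' @param config a [sim_config()].
#' @param concentration_map numeric matrix of mg/L, non-negative; 0 =
#'   background.
#' @param pigment which pigment the map quantifies (default `"Chla"`).
#' @return list with `raw` (uncorrected [spectral_cube()]), `white`,
#'   `dark` (cols x bands reference frames), `reflectance` (corrected
#'   cube), `mask` (logical foreground matrix) and `truth` (the map and
#'   the co-varying pigment maps).
#' @export
generate_cube <- function(config, concentration_map, pigment = "Chla") {
  stopifnot(inherits(config, "sim_config"))
  cmap <- as.matrix(concentration_map)
  if (any(cmap < 0)) stop("concentration map must be non-negative")
  pigs <- names(config$pigment_ranges)
  if (!pigment %in% pigs) stop("unknown pigment")
  wl <- sim_wavelengths(config)
  profs <- pure_profiles(config)
  depth <- 0.10
  kappa <- vapply(pigs, function(pg) depth / config$pigment_ranges[[pg]][2],
                  numeric(1))
  mid <- vapply(pigs, function(pg) mean(config$pigment_ranges[[pg]]), numeric(1))
  ratio <- mid / mid[[pigment]]  # proportional co-variation

  nr <- nrow(cmap); nc <- ncol(cmap); nb <- config$n_bands
  mask <- cmap > 0
  base <- sim_baseline(wl)
  background <- rep(0.08, nb)

  arr <- array(0, c(nr, nc, nb))
  absorb <- matrix(0, nb, length(pigs))
  for (i in seq_along(pigs)) {
    absorb[, i] <- kappa[[pigs[i]]] * profs[[pigs[i]]]$profile * ratio[[pigs[i]]]
  }
  total_absorb <- rowSums(absorb)  # per band, per unit of mapped pigment
  noise_arr <- if (config$noise_sd > 0) {
    with_seed(child_seed(config$seed, "cube_noise"),
              array(stats::rnorm(nr * nc * nb, 0, config$noise_sd), c(nr, nc, nb)))
  } else NULL
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    arr[r, cc, ] <- if (mask[r, cc]) base - cmap[r, cc] * total_absorb else background
  }
  if (!is.null(noise_arr)) arr <- arr + noise_arr

  white <- matrix(0.95, nc, nb)
  dark <- matrix(0.02, nc, nb)
  raw <- arr * (0.95 - 0.02) + 0.02
  truth_maps <- stats::setNames(lapply(pigs, function(pg) cmap * ratio[[pg]]), pigs)
  truth_maps$Chls <- truth_maps$Chla + truth_maps$Chlb
  list(raw = spectral_cube(raw, wl),
       white = white, dark = dark,
       reflectance = spectral_cube(arr, wl),
       mask = mask,
       truth = list(pigment = pigment, maps = truth_maps))
}

#' Generate a planted-support recovery instance
#'
#' Benchmark data for wavelength-selection recall: `n_informative`
#' bands each carry an independent standard-normal factor (impulse
#' signal on exactly one band), the response is the sum of the factors
#' plus noise, and the rest of the spectrum is a smooth collinear
#' nuisance background plus i.i.d. noise. Unlike [generate_dataset()],
#' where one concentration scales a whole absorption profile (so a
#' parsimonious selector keeps only one band per profile), every
#' planted band here is independently informative: a selector that
#' works should recover essentially all of them.
#'
#' @param n_samples,n_bands dimensions (defaults 200, 646).
#' @param planted_indices band indices carrying signal; default 8 bands
#'   spread over the pigment windows.
#' @param signal amplitude of the per-band factor in reflectance units
#'   (default 0.05).
#' @param noise_y response noise sd (default 0.3; the signal variance
#'   is `length(planted_indices)`).
#' @param noise_sd reflectance noise sd (default 0.002).
#' @param seed integer seed.
#' @return list with `X`, `y`, `wavelengths`, `planted_indices`.
#' @export
generate_planted_support <- function(n_samples = 200, n_bands = 646,
                                     planted_indices = NULL,
                                     signal = 0.05, noise_y = 0.3,
                                     noise_sd = 0.002, seed = 1L) {
  wl <- seq(430, 900, length.out = n_bands)
  if (is.null(planted_indices)) {
    planted_indices <- vapply(c(445, 475, 505, 665, 691, 730, 805, 870),
                              function(w) which.min(abs(wl - w)), integer(1))
  }
  k <- length(planted_indices)
  with_seed(seed, {
    Z <- matrix(stats::rnorm(n_samples * k), n_samples)
    # uninformative but structured background: 30 random smooth
    # components, absent from the planted columns (those are
    # overwritten below so the planted set alone carries the signal)
    n_nuis <- 30
    centers <- stats::runif(n_nuis, 430, 900)
    widths <- stats::runif(n_nuis, 20, 80)
    nuis <- vapply(seq_len(n_nuis),
                   function(i) exp(-(wl - centers[i])^2 / (2 * widths[i]^2)),
                   numeric(n_bands))
    X <- matrix(0.4, n_samples, n_bands) +
      0.02 * matrix(stats::rnorm(n_samples * n_nuis), n_samples) %*% t(nuis)
    for (j in seq_len(k)) {
      X[, planted_indices[j]] <- 0.4 + signal * Z[, j]
    }
    X <- X + matrix(stats::rnorm(n_samples * n_bands, 0, noise_sd),
                    n_samples)
    y <- rowSums(Z) + stats::rnorm(n_samples, 0, noise_y)
    list(X = X, y = y, wavelengths = wl,
         planted_indices = sort(as.integer(planted_indices)))
  })
}

#' Write a synthetic dataset to CSV
#'
#' One row per sample: id, position, nitrogen, the reflectance columns
#' keyed by wavelength, then the four pigment columns.
#'
#' @param ds result of [generate_dataset()].
#' @param path output CSV path.
#' @export
write_dataset_csv <- function(ds, path) {
  df <- cbind(ds$meta, as.data.frame(ds$spectra), ds$pigments)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
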