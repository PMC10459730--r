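test_that("noise-free construction is exactly baseline minus conc x profile", {
  cfg <- sim_config(n_samples = 12, n_bands = 100,
                    pigment_ranges = list(Chla = c(3.37, 21.13)),
                    planted_bands = list(Chla = c(660)),
                    scatter_sd = 0, noise_sd = 0, reference_error_sd = 0,
                    seed = 2)
  ds <- generate_dataset(cfg)
  wl <- ds$wavelengths
  baseline <- 0.30 + 0.30 / (1 + exp(-(wl - 700) / 18))
  prof <- exp(-(wl - 660)^2 / (2 * 15^2))
  prof <- prof / max(prof)
  kappa <- 0.10 / 21.13
  for (i in c(1, 5, 12)) {
    expect_equal(unname(ds$spectra[i, ]),
                 baseline - ds$pigments$Chla[i] * kappa * prof,
                 tolerance = 1e-12)
  }
})

test_that("generation is bit-identical under a fixed seed and shapes are right", {
  cfg <- sim_config(n_samples = 50, n_bands = 80, seed = 77)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a, b)
  expect_equal(dim(a$spectra), c(50, 80))
  c2 <- generate_dataset(sim_config(n_samples = 50, n_bands = 80, seed = 78))
  expect_false(identical(a$spectra, c2$spectra))
})

test_that("default design: Chls identity, ranges, and the position ordering", {
  ds <- tiny_dataset()
  expect_equal(ds$pigments$Chls, ds$pigments$Chla + ds$pigments$Chlb)
  tc <- ds$truth$true_concentrations
  expect_true(all(tc$Chla >= 3.37 & tc$Chla <= 21.13))
  mu <- tapply(ds$pigments$Chla, ds$meta$position, mean)
  expect_gt(mu[["Upper"]], mu[["Middle"]])
  expect_gt(mu[["Middle"]], mu[["Lower"]])
  expect_true(all(ds$truth$informative_band_indices$Chla %in% 1:120))
  expect_error(sim_config(pigment_ranges = list(Chla = c(5, 2))), "min < max")
  expect_error(sim_config(n_samples = 0), "counts")
})

test_that("noise-free linear spectra give a perfect PLSR fit", {
  cfg <- sim_config(n_samples = 40, n_bands = 60, scatter_sd = 0,
                    noise_sd = 0, reference_error_sd = 0, seed = 4)
  ds <- generate_dataset(cfg)
  fit <- fit_plsr(ds$spectra, ds$pigments$Chla, 3)
  expect_equal(evaluate(fit, ds$spectra, ds$pigments$Chla)$R2, 1,
               tolerance = 1e-9)
})

test_that("cube generation: uniform map, empty mask, reference frames", {
  cfg <- sim_config(n_bands = 60, noise_sd = 0, scatter_sd = 0, seed = 5)
  cmap <- matrix(10, 6, 7)
  cmap[1, ] <- 0   # background stripe
  cb <- generate_cube(cfg, cmap)
  expect_s3_class(cb$raw, "spectral_cube")
  # all foreground pixels share one spectrum (noise off)
  fg <- which(cb$mask, arr.ind = TRUE)
  ref <- cb$reflectance$data[fg[1, 1], fg[1, 2], ]
  for (i in seq_len(nrow(fg))) {
    expect_equal(cb$reflectance$data[fg[i, 1], fg[i, 2], ], ref)
  }
  # raw cube corrects back to the reflectance cube through Eq-style frames
  corr <- correct_reflectance(cb$raw, cb$white, cb$dark)
  expect_equal(corr$data, cb$reflectance$data, tolerance = 1e-12)
  # empty map: background everywhere
  cb0 <- generate_cube(cfg, matrix(0, 3, 3))
  expect_true(all(abs(cb0$reflectance$data - 0.08) < 1e-12))
  expect_error(generate_cube(cfg, matrix(-1, 2, 2)), "non-negative")
})

test_that("planted-support instance: the planted set alone explains the response", {
  d <- generate_planted_support(n_samples = 100, n_bands = 150, seed = 8)
  fit <- fit_plsr(d$X[, d$planted_indices], d$y, length(d$planted_indices))
  r2 <- evaluate(fit, d$X[, d$planted_indices], d$y)$R2
  expect_gt(r2, 0.95)
  expect_identical(generate_planted_support(seed = 8)$X[1:3, 1:3],
                   generate_planted_support(seed = 8)$X[1:3, 1:3])
})

test_that("dataset CSV export has the documented layout", {
  ds <- generate_dataset(sim_config(n_samples = 5, n_bands = 10, seed = 6))
  td <- withr::local_tempdir()
  f <- file.path(td, "ds.csv")
  write_dataset_csv(ds, f)
  back <- read.csv(f)
  expect_equal(nrow(back), 5)
  expect_equal(ncol(back), 3 + 10 + 4)
  expect_equal(back$Chla, ds$pigments$Chla)
})
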