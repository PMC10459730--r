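# Shared fixture: noise-free cube with a two-level Chla map and a model
# trained on matching synthetic spectra.
viz_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- sim_config(n_samples = 80, n_bands = 120, noise_sd = 0,
                      scatter_sd = 0, reference_error_sd = 0, seed = 12)
    ds <- generate_dataset(cfg)
    model <- fit_pigment_model(ds$spectra, ds$pigments$Chla, ds$wavelengths,
                               recipe = "none", selector = "none",
                               seed = 1, pigment = "Chla")
    cmap <- matrix(0, 12, 16)
    cmap[3:10, 2:7] <- 5
    cmap[3:10, 9:15] <- 20
    cube <- generate_cube(cfg, cmap)
    cache <<- list(cfg = cfg, ds = ds, model = model, cmap = cmap,
                   cube = cube)
    cache
  }
})

test_that("leaf segmentation recovers the generator's mask exactly", {
  fx <- viz_fixture()
  # uniform 10 mg/L leaf: NDVI is comfortably above threshold everywhere
  uni <- matrix(0, 9, 9); uni[3:7, 2:8] <- 10
  cb <- generate_cube(fx$cfg, uni)
  mask <- segment_leaf(cb$reflectance)
  expect_equal(unname(mask), unname(uni > 0))
  expect_error(segment_leaf(cb$reflectance, threshold = 1.0), "empty")
  bg <- generate_cube(fx$cfg, matrix(0, 4, 4))
  expect_error(segment_leaf(bg$reflectance), "empty")
})

test_that("pixel inversion round-trips the two-level map (noise off)", {
  fx <- viz_fixture()
  mask <- fx$cube$mask   # generator mask: the 5 mg/L region sits below
                         # the default NDVI threshold (pale leaf)
  cm <- invert_pixels(fx$cube$reflectance, fx$model, mask)
  lo <- cm$values[fx$cmap == 5]
  hi <- cm$values[fx$cmap == 20]
  expect_equal(mean(lo), 5, tolerance = 1e-6)
  expect_equal(mean(hi), 20, tolerance = 1e-6)
  expect_true(all(is.na(cm$values[fx$cmap == 0])))

  # zero-coefficient model maps to its intercept everywhere
  m0 <- fx$model
  m0$plsr$coefficients[] <- 0
  m0$plsr$intercept <- 7.5
  cm0 <- invert_pixels(fx$cube$reflectance, m0, mask)
  expect_true(all(abs(cm0$values[mask] - 7.5) < 1e-12))

  # map mean over an ROI equals the prediction on the ROI mean spectrum
  # (linear recipe)
  px <- roi_pixels(roi_ellipse(c(4, 5), c(2, 2)), dim(mask))
  ms <- mean_spectrum(fx$cube$reflectance, px)
  roi_vals <- cm$values[cbind(px$y + 1, px$x + 1)]
  expect_equal(mean(roi_vals), unname(predict(fx$model, ms)),
               tolerance = 1e-9)
})

test_that("model wavelengths outside the cube axis are rejected", {
  fx <- viz_fixture()
  m <- fx$model
  m$wavelengths_selected[1] <- 1500
  m$band_indices <- m$band_indices[seq_along(m$wavelengths_selected)]
  expect_error(invert_pixels(fx$cube$reflectance, m, fx$cube$mask),
               "not present")
})

test_that("enhanced Lee filter branches on the coefficient of variation", {
  # constant image unchanged
  flat <- matrix(5, 6, 6)
  expect_equal(enhanced_lee(flat), flat)

  # mild spike lands in the homogeneous branch: window mean
  img0 <- matrix(10, 5, 5)
  img0[3, 3] <- 18
  expect_equal(enhanced_lee(img0)[3, 3], mean(img0[2:4, 2:4]))

  # strong spike: hand-computed intermediate (damped) branch
  img <- matrix(10, 5, 5)
  img[3, 3] <- 60
  out <- enhanced_lee(img, lee_params())
  win <- img[2:4, 2:4]
  m <- mean(win); ci <- sd(win) / m
  expect_true(ci > 0.52 && ci < 1.73)
  w <- exp(-1 * (ci - 0.52) / (1.73 - ci))
  expect_equal(out[3, 3], w * m + (1 - w) * 60, tolerance = 1e-12)
  expect_lt(out[3, 3], 60)  # attenuated toward the mean

  # heterogeneous window (CV >= 1.73): centre preserved
  img2 <- matrix(0.01, 5, 5)
  img2[3, 3] <- 30
  win2 <- img2[2:4, 2:4]
  expect_gte(sd(win2) / mean(win2), 1.73)
  expect_equal(enhanced_lee(img2)[3, 3], 30)

  # homogeneous interior is mean-preserving to tolerance
  set.seed(9)
  img3 <- matrix(10 + rnorm(100, 0, 0.1), 10, 10)
  out3 <- enhanced_lee(img3)
  expect_equal(mean(out3[3:8, 3:8]), mean(img3[3:8, 3:8]), tolerance = 0.01)

  # NA background is excluded and stays NA
  img4 <- matrix(c(NA, 10, 10, 10), 2, 2)
  out4 <- enhanced_lee(img4)
  expect_true(is.na(out4[1, 1]))
  expect_error(lee_params(window = 4), "odd")
})

test_that("pseudo-colour LUT hits the endpoints and inverts within 1/255", {
  rng <- c(0, 30)
  expect_equal(value_to_color(0, rng)[1, ], c(R = 0L, G = 0L, B = 255L))
  expect_equal(value_to_color(30, rng)[1, ], c(R = 255L, G = 0L, B = 0L))
  v <- seq(0, 30, length.out = 101)
  back <- color_to_value(value_to_color(v, rng), rng)
  expect_lt(max(abs(back - v)), 30 / 255)

  fx <- viz_fixture()
  cm <- invert_pixels(fx$cube$reflectance, fx$model, fx$cube$mask)
  td <- withr::local_tempdir()
  f <- file.path(td, "map.ppm")
  res <- render_pseudocolor(cm, f)
  expect_true(file.exists(f))
  lines <- readLines(f)
  expect_equal(lines[1], "P3")
  expect_equal(lines[2], sprintf("%d %d", ncol(cm$values), nrow(cm$values)))
  expect_equal(res$mean_concentration, mean(cm$values, na.rm = TRUE))
})
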