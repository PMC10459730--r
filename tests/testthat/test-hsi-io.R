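make_cube <- function(nr = 4, nc = 5, nb = 6, seed = 1) {
  set.seed(seed)
  spectral_cube(array(runif(nr * nc * nb), c(nr, nc, nb)),
                seq(430, 900, length.out = nb))
}

test_that("reflectance correction implements (R0 - Rb)/(Rw - Rb)", {
  cube <- make_cube()
  d <- dim(cube$data)
  Rw <- array(0.9, d); Rb <- array(0.1, d)

  expect_equal(correct_reflectance(spectral_cube(Rw, cube$wavelengths),
                                   Rw, Rb)$data,
               array(1, d))
  expect_equal(correct_reflectance(spectral_cube(Rb, cube$wavelengths),
                                   Rw, Rb)$data,
               array(0, d))
  R0 <- array(0.5, d)
  expect_equal(correct_reflectance(R0, Rw, Rb), array(0.5, d))

  # affine invariance under a common positive scale
  r1 <- correct_reflectance(cube$data, Rw, Rb)
  r2 <- correct_reflectance(3.7 * cube$data, 3.7 * Rw, 3.7 * Rb)
  expect_equal(r1, r2, tolerance = 1e-12)

  # per-column line references broadcast over rows
  wline <- matrix(0.9, d[2], d[3]); bline <- matrix(0.1, d[2], d[3])
  expect_equal(correct_reflectance(cube$data, wline, bline), r1)

  bline_bad <- bline; bline_bad[2, 3] <- 0.9
  expect_error(correct_reflectance(cube$data, wline, bline_bad),
               "degenerate reference.*col 2.*band 3")
})

test_that("ROI pixel enumeration matches brute-force evaluation of the inequality", {
  shape <- c(21, 21)
  # a = b = 1: centre plus 4 axis neighbours
  px <- roi_pixels(roi_ellipse(c(10, 10), c(1, 1)), shape)
  expect_equal(nrow(px), 5)
  expect_setequal(paste(px$x, px$y),
                  paste(c(10, 9, 11, 10, 10), c(9, 10, 10, 11, 10)))
  # a = b = 0.5: only the centre
  expect_equal(nrow(roi_pixels(roi_ellipse(c(10, 10), c(0.5, 0.5)), shape)), 1)

  # brute-force oracle over a grid of ellipses
  for (ab in list(c(2, 1), c(3, 2), c(1.5, 4))) {
    px <- roi_pixels(roi_ellipse(c(10, 10), ab), shape)
    grid <- expand.grid(xi = -10:10, yi = -10:10)
    inside <- grid[grid$xi^2 / ab[1]^2 + grid$yi^2 / ab[2]^2 <= 1, ]
    expect_equal(nrow(px), nrow(inside))
    expect_setequal(paste(px$x, px$y),
                    paste(inside$xi + 10, inside$yi + 10))
  }
  expect_equal(nrow(roi_pixels(roi_ellipse(c(10, 10), c(2, 1)), shape)), 7)

  # symmetry about the centre before clipping
  px <- roi_pixels(roi_ellipse(c(10, 10), c(4, 2.5)), shape)
  expect_setequal(paste(px$x - 10, px$y - 10),
                  paste(-(px$x - 10), -(px$y - 10)))

  # ordering: top-to-bottom then left-to-right
  expect_true(!is.unsorted(px$y))
  expect_false(is.unsorted(order(px$y, px$x)))

  # clipping and empty intersection
  edge <- roi_pixels(roi_ellipse(c(0, 0), c(2, 2)), shape)
  expect_true(all(edge$x >= 0 & edge$y >= 0))
  expect_error(roi_pixels(roi_ellipse(c(100, 100), c(2, 2)), shape),
               "does not intersect")
})

test_that("mean_spectrum is the arithmetic pixel mean and permutation-invariant", {
  cube <- make_cube()
  px <- roi_pixels(roi_ellipse(c(2, 2), c(1, 1)), dim(cube$data)[1:2])
  m1 <- mean_spectrum(cube, px)
  # direct oracle
  acc <- rowMeans(sapply(seq_len(nrow(px)), function(i) {
    cube$data[px$y[i] + 1, px$x[i] + 1, ]
  }))
  expect_equal(m1, acc)
  expect_equal(mean_spectrum(cube, px[sample(nrow(px)), ]), m1)

  # pooled three-ellipse harvest equals mean over the pooled multiset
  e <- list(roi_ellipse(c(1, 1), c(1, 1)), roi_ellipse(c(3, 2), c(1, 1)),
            roi_ellipse(c(2, 3), c(1, 1)))
  pooled <- do.call(rbind, lapply(e, roi_pixels, dim(cube$data)[1:2]))
  mp <- mean_spectrum(cube, pooled)
  oracle <- Reduce(`+`, lapply(seq_len(nrow(pooled)), function(i) {
    cube$data[pooled$y[i] + 1, pooled$x[i] + 1, ]
  })) / nrow(pooled)
  expect_equal(mp, oracle)
  expect_error(mean_spectrum(cube, pooled[0, ]), "empty")
})

test_that("ENVI cube I/O round-trips bit-identically across interleaves", {
  cube <- make_cube(4, 5, 6)
  td <- withr::local_tempdir()
  for (il in c("bsq", "bil", "bip")) {
    p <- file.path(td, paste0("cube_", il))
    write_cube(cube, p, interleave = il)
    back <- read_cube(paste0(p, ".hdr"))
    expect_identical(back$data, cube$data)
    expect_equal(back$wavelengths, cube$wavelengths)
  }

  # wavelength-window trimming at read time
  trimmed <- read_cube(file.path(td, "cube_bsq.hdr"),
                       wavelength_range = c(500, 800))
  keep <- cube$wavelengths >= 500 & cube$wavelengths <= 800
  expect_equal(trimmed$wavelengths, cube$wavelengths[keep])
  expect_identical(trimmed$data, cube$data[, , keep])

  # header/band mismatch is a format error
  hdr <- file.path(td, "cube_bsq.hdr")
  txt <- readLines(hdr)
  txt[grep("^bands", txt)] <- "bands = 7"
  writeLines(txt, hdr)
  expect_error(read_cube(hdr), "band count")
})
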