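#' Segment leaf foreground from a calibrated cube
#'
#' Band-ratio threshold in the NDVI style: pixels with
#' \eqn{(R_{800} - R_{670}) / (R_{800} + R_{670}) >} `threshold` are
#' foreground, then only the largest 4-connected component is kept
#' (removes stray specks).
#'
#' @param cube calibrated [spectral_cube()].
#' @param threshold ratio threshold (default 0.3).
#' @param red_wl,nir_wl wavelengths (nm) of the red and NIR bands;
#'   nearest bands are used.
#' @return logical matrix mask (TRUE = leaf).
#' @export
segment_leaf <- function(cube, threshold = 0.3, red_wl = 670, nir_wl = 800) {
  stopifnot(inherits(cube, "spectral_cube"))
  bred <- which.min(abs(cube$wavelengths - red_wl))
  bnir <- which.min(abs(cube$wavelengths - nir_wl))
  red <- cube$data[, , bred]
  nir <- cube$data[, , bnir]
  ratio <- (nir - red) / (nir + red)
  mask <- is.finite(ratio) & ratio > threshold
  if (!any(mask)) stop("empty foreground: no pixel exceeds the threshold")
  largest_component(mask)
}

# Largest 4-connected TRUE component of a logical matrix (flood fill).
largest_component <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nxt <- 0L
  best_lab <- 0L; best_n <- 0L
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    count <- 0L
    nr <- nrow(mask)
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      count <- count + 1L
      r <- (cur - 1L) %% nr + 1L
      cc <- (cur - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; c2 <- cc + d[2]
        if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= ncol(mask)) {
          pos <- (c2 - 1L) * nr + rr
          if (mask[pos] && lab[pos] == 0L) {
            lab[pos] <- nxt
            queue <- c(queue, pos)
          }
        }
      }
    }
    if (count > best_n) { best_n <- count; best_lab <- nxt }
  }
  lab == best_lab
}

#' Pixel-wise inversion of a fitted pigment model onto a cube
#'
#' Every foreground pixel spectrum is passed through the model's stored
#' preprocessing recipe, the model's wavelengths are matched to the
#' nearest cube bands (error if any falls beyond half a band spacing),
#' and the collapsed affine map produces a concentration in mg/L.
#' Background pixels are NA.
#'
#' @param cube calibrated [spectral_cube()].
#' @param model a `fitted_model` from [fit_pigment_model()].
#' @param mask logical foreground matrix (e.g. from [segment_leaf()]).
#' @return object of class `concentration_map`: list with `values`
#'   (matrix, NA = background), `pigment`, `display_range`.
#' @export
invert_pixels <- function(cube, model, mask) {
  stopifnot(inherits(cube, "spectral_cube"), inherits(model, "fitted_model"))
  d <- dim(cube$data)
  stopifnot(all(dim(mask) == d[1:2]))
  # match model wavelengths to cube bands
  spacing <- stats::median(diff(cube$wavelengths))
  idx <- vapply(model$wavelengths_selected, function(w) {
    j <- which.min(abs(cube$wavelengths - w))
    if (abs(cube$wavelengths[j] - w) > spacing / 2 + 1e-9) {
      stop(sprintf("model wavelength %.2f nm not present in cube axis", w))
    }
    j
  }, integer(1))

  fg <- which(mask)
  if (!length(fg)) stop("mask has no foreground")
  flat <- matrix(cube$data, d[1] * d[2], d[3])
  spec <- flat[fg, , drop = FALSE]
  spec <- apply_recipe(spec, model$recipe)
  vals <- drop(spec[, idx, drop = FALSE] %*% model$plsr$coefficients) +
    model$plsr$intercept
  out <- matrix(NA_real_, d[1], d[2])
  out[fg] <- vals
  structure(list(values = out, pigment = model$pigment,
                 display_range = c(0, 30)),
            class = "concentration_map")
}

#' Enhanced Lee filter parameters
#'
#' @param window odd window size (default 3).
#' @param damping damping coefficient (default 1).
#' @param homogeneity,heterogeneous coefficient-of-variation thresholds
#'   delimiting the homogeneous / intermediate / heterogeneous zones
#'   (defaults 0.52 and 1.73).
#' @export
lee_params <- function(window = 3, damping = 1,
                       homogeneity = 0.52, heterogeneous = 1.73) {
  if (window %% 2 == 0) stop("window must be odd")
  if (!(homogeneity > 0 && homogeneity < heterogeneous)) {
    stop("need 0 < homogeneity < heterogeneous")
  }
  structure(list(window = as.integer(window), damping = damping,
                 homogeneity = homogeneity, heterogeneous = heterogeneous),
            class = "lee_params")
}

#' Enhanced Lee despeckling of a concentration map
#'
#' Per window the coefficient of variation \eqn{C_i = s/\bar x} decides
#' the branch: homogeneous (\eqn{C_i \le} homogeneity) returns the
#' window mean; heterogeneous (\eqn{C_i \ge} heterogeneous) preserves
#' the centre pixel; in between a damped weight
#' \eqn{W = e^{-d (C_i - C_u)/(C_{max} - C_i)}} blends
#' \eqn{W \bar x + (1 - W) x_c}, sliding from mean to centre as the
#' window grows more heterogeneous. Background (NA) pixels are excluded
#' from every window and left NA.
#'
#' @param map a `concentration_map` (or bare matrix with NA background).
#' @param params a [lee_params()].
#' @return filtered object of the same type.
#' @export
enhanced_lee <- function(map, params = lee_params()) {
  is_map <- inherits(map, "concentration_map")
  vals <- if (is_map) map$values else as.matrix(map)
  half <- (params$window - 1L) %/% 2L
  nr <- nrow(vals); nc <- ncol(vals)
  out <- vals
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    xc <- vals[r, cc]
    if (is.na(xc)) next
    win <- vals[max(1, r - half):min(nr, r + half),
                max(1, cc - half):min(nc, cc + half)]
    win <- win[!is.na(win)]
    m <- mean(win)
    if (length(win) < 2 || m == 0) next
    ci <- stats::sd(win) / m
    out[r, cc] <- if (ci <= params$homogeneity) {
      m
    } else if (ci >= params$heterogeneous) {
      xc
    } else {
      w <- exp(-params$damping * (ci - params$homogeneity) /
                 (params$heterogeneous - ci))
      w * m + (1 - w) * xc
    }
  }
  if (is_map) { map$values <- out; map } else out
}

#' Linear blue-to-red pseudo-colour lookup
#'
#' Values are clipped to `display_range` and mapped linearly: range
#' minimum is pure blue (0, 0, 255), range maximum pure red
#' (255, 0, 0). The red channel alone inverts the mapping to within
#' 1/255 of the range.
#'
#' @param values numeric vector.
#' @param display_range `c(min, max)`.
#' @return integer matrix, columns R, G, B.
#' @export
value_to_color <- function(values, display_range = c(0, 30)) {
  t <- (values - display_range[1]) / diff(display_range)
  t <- pmin(pmax(t, 0), 1)
  cbind(R = as.integer(round(255 * t)), G = 0L,
        B = as.integer(round(255 * (1 - t))))
}

#' Invert the pseudo-colour lookup
#'
#' @param rgb integer matrix with R, G, B columns from [value_to_color()].
#' @inheritParams value_to_color
#' @export
color_to_value <- function(rgb, display_range = c(0, 30)) {
  display_range[1] + (rgb[, 1] / 255) * diff(display_range)
}

#' Render a concentration map as a pseudo-colour image
#'
#' Writes a plain-text PPM (P3) image: linear blue-to-red over
#' `display_range`, background white. Optionally annotates (in the
#' return value) the mean concentration over the foreground.
#'
#' @param map a `concentration_map`.
#' @param out_path output `.ppm` path.
#' @param display_range overrides the map's range if given.
#' @return invisibly, a list with `path` and `mean_concentration`.
#' @export
render_pseudocolor <- function(map, out_path, display_range = NULL) {
  stopifnot(inherits(map, "concentration_map"))
  rng <- display_range %||% map$display_range
  if (rng[1] >= rng[2]) stop("display range min must be < max")
  vals <- map$values
  nr <- nrow(vals); nc <- ncol(vals)
  rgbm <- value_to_color(as.vector(vals), rng)
  rgbm[is.na(vals), ] <- 255L  # background white
  lines <- c("P3", sprintf("%d %d", nc, nr), "255")
  # PPM is row-major top-to-bottom; R matrices are column-major
  body <- apply(matrix(seq_len(nr * nc), nr, nc), 1, function(rowpos) {
    paste(t(rgbm[rowpos, , drop = FALSE]), collapse = " ")
  })
  writeLines(c(lines, body), out_path)
  invisible(list(path = out_path,
                 mean_concentration = mean(vals, na.rm = TRUE)))
}
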