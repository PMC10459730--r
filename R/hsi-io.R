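#' Construct a hyperspectral cube
#'
#' A light container for a rows x cols x bands reflectance raster with a
#' strictly increasing wavelength axis (nm).
#'
#' @param data 3-D numeric array, rows x cols x bands.
#' @param wavelengths numeric vector, one per band, strictly increasing.
#' @export
spectral_cube <- function(data, wavelengths) {
  data <- as.array(data)
  if (length(dim(data)) != 3) stop("data must be a 3-D array")
  if (dim(data)[3] != length(wavelengths)) {
    stop("band count does not match wavelength list length")
  }
  if (any(diff(wavelengths) <= 0)) stop("wavelength axis must be strictly increasing")
  structure(list(data = data, wavelengths = as.numeric(wavelengths)),
            class = "spectral_cube")
}

#' @export
dim.spectral_cube <- function(x) dim(x$data)

as_cube_array <- function(x) if (inherits(x, "spectral_cube")) x$data else as.array(x)

# Broadcast a reference frame to cube shape. Accepted shapes: full cube
# (rows x cols x bands), a per-column line reference (cols x bands,
# replicated over rows), or a single spectrum (bands).
broadcast_frame <- function(frame, dims, what) {
  f <- as_cube_array(frame)
  if (length(dim(f)) == 3 && all(dim(f) == dims)) return(f)
  if (is.matrix(f) && nrow(f) == dims[2] && ncol(f) == dims[3]) {
    return(aperm(array(rep(t(f), dims[1]), c(dims[3], dims[2], dims[1])), c(3, 2, 1)))
  }
  if (is.null(dim(f)) && length(f) == dims[3]) {
    return(aperm(array(f, c(dims[3], dims[1], dims[2])), c(2, 3, 1)))
  }
  stop(sprintf("%s frame shape is not conformable with the cube", what))
}

#' White/dark reflectance correction
#'
#' Converts a raw cube to relative reflectance with the standard
#' two-point calibration \eqn{R = (R_0 - R_b) / (R_w - R_b)} elementwise.
#' Values are not clipped: corrected reflectance may fall slightly
#' outside [0, 1] (e.g. specular pixels) and downstream code tolerates
#' that.
#'
#' @param R0 raw cube (`spectral_cube` or 3-D array).
#' @param Rw,Rb white and dark reference frames: a full cube, a
#'   cols x bands line reference, or a single spectrum.
#' @return corrected cube, same class as `R0`.
#' @export
correct_reflectance <- function(R0, Rw, Rb) {
  raw <- as_cube_array(R0)
  dims <- dim(raw)
  W <- broadcast_frame(Rw, dims, "white")
  B <- broadcast_frame(Rb, dims, "dark")
  denom <- W - B
  if (any(denom == 0)) {
    bad <- which(denom == 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "degenerate reference: Rw = Rb at pixel (row %d, col %d), band %d",
      bad[1], bad[2], bad[3]))
  }
  R <- (raw - B) / denom
  if (inherits(R0, "spectral_cube")) spectral_cube(R, R0$wavelengths) else R
}

#' Elliptical region-of-interest descriptor
#'
#' @param center pixel coordinates `c(x, y)` (0-based column, row).
#' @param semi_axes `c(a, b)`: X and Y semi-axis lengths in pixels, > 0.
#' @param step `c(dx, dy)` grid spacing, >= 1 (default 1, 1).
#' @export
roi_ellipse <- function(center, semi_axes, step = c(1, 1)) {
  stopifnot(length(center) == 2, length(semi_axes) == 2)
  if (any(semi_axes <= 0)) stop("semi-axes must be positive")
  if (any(step < 1)) stop("step must be >= 1")
  structure(list(center = as.numeric(center), semi_axes = as.numeric(semi_axes),
                 step = as.numeric(step)), class = "roi_ellipse")
}

#' Enumerate pixels inside an elliptical ROI
#'
#' Integer grid offsets `(xi, yi)` at the ellipse's step spacing
#' satisfying \eqn{x_i^2/a^2 + y_i^2/b^2 \le 1}, translated to absolute
#' 0-based `(x, y)` coordinates, ordered top-to-bottom then
#' left-to-right, and clipped to the image bounds.
#'
#' @param ellipse an [roi_ellipse()].
#' @param image_shape `c(rows, cols)`.
#' @return data.frame with integer columns `x` (col) and `y` (row).
#' @export
roi_pixels <- function(ellipse, image_shape) {
  stopifnot(inherits(ellipse, "roi_ellipse"), length(image_shape) == 2)
  a <- ellipse$semi_axes[1]; b <- ellipse$semi_axes[2]
  dx <- ellipse$step[1]; dy <- ellipse$step[2]
  xi <- seq(-floor(a / dx) * dx, floor(a / dx) * dx, by = dx)
  yi <- seq(-floor(b / dy) * dy, floor(b / dy) * dy, by = dy)
  grid <- expand.grid(x = xi, y = yi)  # x varies fastest: left-to-right
  grid <- grid[grid$x^2 / a^2 + grid$y^2 / b^2 <= 1, , drop = FALSE]
  grid <- grid[order(grid$y, grid$x), , drop = FALSE]
  abs_x <- round(grid$x + ellipse$center[1])
  abs_y <- round(grid$y + ellipse$center[2])
  keep <- abs_x >= 0 & abs_x < image_shape[2] & abs_y >= 0 & abs_y < image_shape[1]
  if (!any(keep)) stop("ROI does not intersect the image")
  data.frame(x = as.integer(abs_x[keep]), y = as.integer(abs_y[keep]))
}

#' Mean spectrum over a pixel list
#'
#' Arithmetic mean reflectance per band over the listed pixels; the
#' standard reduction of a harvested ROI (or several pooled ROIs) to one
#' sample spectrum.
#'
#' @param cube `spectral_cube` or 3-D array.
#' @param pixels data.frame with 0-based `x`, `y` columns (as from
#'   [roi_pixels()]); rows may repeat (pooled multisets are averaged with
#'   multiplicity).
#' @return numeric vector, one mean reflectance per band.
#' @export
mean_spectrum <- function(cube, pixels) {
  arr <- as_cube_array(cube)
  if (nrow(pixels) == 0) stop("empty pixel list")
  d <- dim(arr)
  if (any(pixels$x < 0 | pixels$x >= d[2] | pixels$y < 0 | pixels$y >= d[1])) {
    stop("pixel out of bounds")
  }
  acc <- numeric(d[3])
  for (i in seq_len(nrow(pixels))) {
    acc <- acc + arr[pixels$y[i] + 1L, pixels$x[i] + 1L, ]
  }
  acc / nrow(pixels)
}

# ---- ENVI-style cube I/O ---------------------------------------------------

parse_envi_header <- function(header_path) {
  txt <- readLines(header_path, warn = FALSE)
  joined <- paste(txt, collapse = "\n")
  get_field <- function(name) {
    m <- regmatches(joined, regexpr(
      paste0("(?mi)^\\s*", name, "\\s*=\\s*([^\\n{]+)"), joined, perl = TRUE))
    if (!length(m)) return(NULL)
    trimws(sub(paste0("(?i).*", name, "\\s*=\\s*"), "", m, perl = TRUE))
  }
  get_block <- function(name) {
    m <- regmatches(joined, regexpr(
      paste0("(?si)", name, "\\s*=\\s*\\{([^}]*)\\}"), joined, perl = TRUE))
    if (!length(m)) return(NULL)
    inner <- sub(paste0("(?si).*", name, "\\s*=\\s*\\{"), "", m, perl = TRUE)
    inner <- sub("\\}$", "", inner)
    as.numeric(strsplit(inner, "[,\\s]+")[[1]][nzchar(strsplit(inner, "[,\\s]+")[[1]])])
  }
  list(samples = as.integer(get_field("samples")),
       lines = as.integer(get_field("lines")),
       bands = as.integer(get_field("bands")),
       data_type = as.integer(get_field("data type") %||% "5"),
       interleave = tolower(get_field("interleave") %||% "bsq"),
       byte_order = as.integer(get_field("byte order") %||% "0"),
       wavelength = get_block("wavelength"))
}

#' Read an ENVI-style hyperspectral cube
#'
#' Supports BSQ, BIL and BIP interleaves and IEEE float data types 4
#' (32-bit) and 5 (64-bit); the wavelength block is required. Bands can
#' be trimmed to a wavelength window at read time (e.g. 430-900 nm to
#' drop noisy sensor edges).
#'
#' @param header_path path to the `.hdr` file; the raster is the same
#'   path without the `.hdr` extension (or with `.dat`).
#' @param wavelength_range optional `c(min, max)` nm window; bands outside
#'   are dropped.
#' @return a [spectral_cube()].
#' @export
read_cube <- function(header_path, wavelength_range = NULL) {
  h <- parse_envi_header(header_path)
  if (is.null(h$wavelength)) stop("header is missing wavelength metadata")
  if (is.na(h$bands) || length(h$wavelength) != h$bands) {
    stop("header band count does not match wavelength list length")
  }
  if (!h$interleave %in% c("bsq", "bil", "bip")) {
    stop(sprintf("unsupported interleave '%s'", h$interleave))
  }
  raster_path <- sub("\\.hdr$", "", header_path)
  if (!file.exists(raster_path)) raster_path <- paste0(raster_path, ".dat")
  if (!file.exists(raster_path)) stop("raster file not found next to header")
  size <- if (h$data_type == 4) 4L else if (h$data_type == 5) 8L else
    stop("unsupported data type (only IEEE float 4/5)")
  n <- h$samples * h$lines * h$bands
  endian <- if (h$byte_order == 1) "big" else "little"
  vals <- readBin(raster_path, what = "double", n = n, size = size, endian = endian)
  if (length(vals) != n) stop("raster shorter than header dimensions imply")
  # unfold to rows x cols x bands
  arr <- switch(h$interleave,
    bsq = aperm(array(vals, c(h$samples, h$lines, h$bands)), c(2, 1, 3)),
    bil = aperm(array(vals, c(h$samples, h$bands, h$lines)), c(3, 1, 2)),
    bip = aperm(array(vals, c(h$bands, h$samples, h$lines)), c(3, 2, 1)))
  wl <- h$wavelength
  if (!is.null(wavelength_range)) {
    keep <- wl >= wavelength_range[1] & wl <= wavelength_range[2]
    if (!any(keep)) stop("no bands inside wavelength_range")
    arr <- arr[, , keep, drop = FALSE]
    wl <- wl[keep]
  }
  spectral_cube(arr, wl)
}

#' Write an ENVI-style hyperspectral cube
#'
#' 64-bit IEEE floats so write-then-read round-trips bit-identically.
#'
#' @param cube a [spectral_cube()].
#' @param path raster path; the header is written to `paste0(path, ".hdr")`.
#' @param interleave `"bsq"`, `"bil"` or `"bip"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(cube, path, interleave = c("bsq", "bil", "bip")) {
  stopifnot(inherits(cube, "spectral_cube"))
  interleave <- match.arg(interleave)
  d <- dim(cube$data)
  vals <- switch(interleave,
    bsq = as.vector(aperm(cube$data, c(2, 1, 3))),
    bil = as.vector(aperm(cube$data, c(2, 3, 1))),
    bip = as.vector(aperm(cube$data, c(3, 2, 1))))
  writeBin(vals, path, size = 8L, endian = "little")
  hdr <- c(
    "ENVI",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    "data type = 5",
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    paste0("wavelength = {", paste(format(cube$wavelengths, trim = TRUE),
                                   collapse = ", "), "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}
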