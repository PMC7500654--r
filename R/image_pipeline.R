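#' Read a cross-section micro-image
#'
#' Reads an 8-bit RGB raster (PNG, TIFF or JPEG) into the plain array format
#' used throughout the package: a numeric array of dimension `h x w x 3` with
#' channel values on the 0--255 scale. Alpha channels are stripped and
#' single-channel (grayscale) images are promoted to RGB by channel
#' replication, so downstream code can always assume three channels.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff`, `.jpg`/`.jpeg` file.
#' @return Numeric array `h x w x 3`, values in `[0, 255]`.
#' @export
read_micro_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path)) {
    stop("cannot read image: file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- tryCatch(
    switch(ext,
      png  = png::readPNG(path),
      tif  = ,
      tiff = tiff::readTIFF(path),
      jpg  = ,
      jpeg = {
        if (!requireNamespace("jpeg", quietly = TRUE)) {
          stop("the 'jpeg' package is required to read JPEG files")
        }
        jpeg::readJPEG(path)
      },
      stop("unsupported image format: '.", ext, "'")
    ),
    error = function(e) {
      stop("failed to read image '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  as_micro_image(raw * 255)
}

#' Coerce a pixel array to the package's RGB convention
#'
#' Accepts an `h x w` matrix (gray) or `h x w x c` array with `c` in
#' `{1, 2, 3, 4}` (gray, gray+alpha, RGB, RGBA) and returns an `h x w x 3`
#' numeric array on the 0--255 scale.
#'
#' @param x Numeric matrix or array, values in `[0, 255]`.
#' @return Numeric array `h x w x 3`.
#' @export
as_micro_image <- function(x) {
  if (is.matrix(x)) {
    x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  }
  if (!is.array(x) || length(dim(x)) != 3L) {
    stop("expected an h x w x channels pixel array", call. = FALSE)
  }
  nc <- dim(x)[3L]
  if (nc == 1L) {
    x <- array(rep(x[, , 1L], 3L), dim = c(dim(x)[1:2], 3L))
  } else if (nc == 2L) {                       # gray + alpha
    x <- array(rep(x[, , 1L], 3L), dim = c(dim(x)[1:2], 3L))
  } else if (nc == 4L) {                       # drop alpha
    x <- x[, , 1:3, drop = FALSE]
  } else if (nc != 3L) {
    stop("unsupported channel count: ", nc, call. = FALSE)
  }
  if (any(dim(x)[1:2] < 1L)) stop("empty image", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

#' Convert an RGB image to grayscale
#'
#' Standard luma weighting `0.299 R + 0.587 G + 0.114 B`. Gray values are kept
#' at full floating-point precision (no integer rounding) because the
#' threshold statistics downstream chain real arithmetic.
#'
#' @param image Numeric array `h x w x 3`, values in `[0, 255]`.
#' @return Numeric matrix `h x w` of gray levels in `[0, 255]`.
#' @export
rgb_to_gray <- function(image) {
  image <- as_micro_image(image)
  g <- 0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
  dim(g) <- dim(image)[1:2]
  g
}

#' Automatic gray threshold: mean plus standard deviation
#'
#' Computes the mean gray level `mu`, the population standard deviation
#' `sigma` (divisor `m * n`, the pixel count, not `m * n - 1`) and the
#' automatic threshold `tau = mu + sigma` used to binarize a slide or strip.
#'
#' @param gray Numeric matrix of gray levels.
#' @return One-row tibble with columns `mu`, `sigma`, `tau`.
#' @export
threshold_stats <- function(gray) {
  if (length(gray) == 0L) stop("empty image", call. = FALSE)
  v <- as.numeric(gray)
  mu <- mean(v)
  sigma <- sqrt(mean((v - mu)^2))   # population divisor
  tibble::tibble(mu = mu, sigma = sigma, tau = mu + sigma)
}

#' Binarize a grayscale image at an automatic threshold
#'
#' Pixels strictly below the threshold become 0 (black, tracheid wall);
#' pixels at or above it become 255 (white, lumen). The boundary value
#' `x == tau` maps to white.
#'
#' @param gray Numeric matrix of gray levels.
#' @param stats Threshold: either the tibble from [threshold_stats()] or a
#'   single numeric `tau`. Defaults to the statistics of `gray` itself.
#' @return Numeric matrix over `{0, 255}` with the dimensions of `gray`.
#' @export
binarize_image <- function(gray, stats = threshold_stats(gray)) {
  tau <- if (is.data.frame(stats)) stats$tau[[1L]] else as.numeric(stats)[[1L]]
  out <- ifelse(gray < tau, 0, 255)
  dim(out) <- dim(gray)
  out
}

#' Crop an image into equal-width vertical strips
#'
#' Splits a slide into `count` full-height strips of equal width
#' `floor(W / count)`, ordered left to right. When the width is not an exact
#' multiple of `count`, the remaining `W %% count` rightmost columns are
#' discarded so that all strips are the same size.
#'
#' @param image Numeric array `h x w x 3` (or gray matrix, promoted).
#' @param count Number of strips (default 20).
#' @return Tibble with columns `strip_index` (1-based, left to right) and
#'   `image` (list of `h x strip_width x 3` arrays). The strip width is
#'   attached as attribute `strip_width`.
#' @export
crop_subimages <- function(image, count = 20L) {
  image <- as_micro_image(image)
  count <- as.integer(count)
  if (count < 1L) stop("count must be >= 1", call. = FALSE)
  W <- dim(image)[2L]
  if (W < count) {
    stop("image width (", W, ") smaller than strip count (", count, ")",
         call. = FALSE)
  }
  sw <- W %/% count
  strips <- purrr::map(seq_len(count), function(i) {
    cols <- ((i - 1L) * sw + 1L):(i * sw)
    image[, cols, , drop = FALSE]
  })
  out <- tibble::tibble(strip_index = seq_len(count), image = strips)
  attr(out, "strip_width") <- sw
  out
}
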