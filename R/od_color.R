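#' 8-bit RGB image object
#'
#' Light container for an 8-bit, 3-channel raster together with the incident
#' luminous intensity \code{I0} used by the Beer-Lambert transform. This is
#' the external currency of the package: every reader returns one and every
#' adapter emits one.
#'
#' @param pixels Integer array of dimension \code{height x width x 3}, values
#'   in \code{[0, 255]}.
#' @param I0 Incident luminous intensity; 255 for 8-bit images.
#' @return An object of class \code{"rgb_image"}.
#' @export
rgb_image <- function(pixels, I0 = 255) {
  pixels <- validate_pixels(pixels)
  structure(list(pixels = pixels, I0 = I0), class = "rgb_image")
}

validate_pixels <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L) {
    stop("`pixels` must be a height x width x 3 array", call. = FALSE)
  }
  if (dim(pixels)[3] != 3L) {
    stop("image must have exactly 3 channels, got ", dim(pixels)[3],
         " (alpha channels are not supported)", call. = FALSE)
  }
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255)) {
    stop("channel values must lie in [0, 255]", call. = FALSE)
  }
  if (any(pixels != round(pixels))) {
    stop("channel values must be integers (8-bit raster)", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  pixels
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<rgb_image> %d x %d pixels, 3 channels, I0 = %g\n",
              d[1], d[2], x$I0))
  invisible(x)
}

#' @rdname rgb_image
#' @param x Object to test.
#' @export
is_rgb_image <- function(x) inherits(x, "rgb_image")

#' Convert an RGB image to optical-density space
#'
#' Applies the Beer-Lambert transform \code{OD = -log(I / I0)} per channel.
#' Pixels are flattened row-major (pixel \code{(i, j)} maps to column
#' \code{(i - 1) * width + j}) into a channel-first \code{3 x d} matrix; this
#' layout is fixed so that stain intensity indices are reproducible.
#' Zero-valued channels are clipped to \code{clip_floor} before the log so
#' the OD stays finite.
#'
#' @param image An [rgb_image()].
#' @param clip_floor Positive lower clip applied to pixel values before the
#'   log; must be in \code{(0, 1]}. Default 1.
#' @return An object of class \code{"od_image"}: list with \code{od}
#'   (\code{3 x d} non-negative matrix), \code{shape} (\code{c(height,
#'   width)}), \code{background_mask} (logical length-\code{d}, all
#'   \code{FALSE} until [mask_background()] is applied), \code{I0}, and
#'   \code{source_pixels} (the input raster, kept so masked pixels can be
#'   restored verbatim on reconstruction).
#' @export
rgb_to_od <- function(image, clip_floor = 1) {
  stopifnot(is_rgb_image(image))
  if (!is.numeric(clip_floor) || length(clip_floor) != 1L ||
      clip_floor <= 0 || clip_floor > 1) {
    stop("`clip_floor` must be a scalar in (0, 1]", call. = FALSE)
  }
  px <- image$pixels
  h <- dim(px)[1]; w <- dim(px)[2]
  d <- h * w
  od <- matrix(0, nrow = 3L, ncol = d)
  for (ch in 1:3) {
    v <- t(px[, , ch])            # row-major pixel order
    od[ch, ] <- -log(pmax(as.vector(v), clip_floor) / image$I0)
  }
  structure(
    list(od = od, shape = c(h, w), background_mask = rep(FALSE, d),
         I0 = image$I0, source_pixels = px),
    class = "od_image"
  )
}

#' @export
print.od_image <- function(x, ...) {
  cat(sprintf("<od_image> %d x %d pixels (%d background-masked), I0 = %g\n",
              x$shape[1], x$shape[2], sum(x$background_mask), x$I0))
  invisible(x)
}

#' Convert optical densities back to an 8-bit RGB image
#'
#' Inverts the Beer-Lambert transform: \code{I = round(I0 * exp(-OD))},
#' clamped to \code{[0, 255]}. For any 8-bit image with all channel values
#' at or above the clip floor, \code{od_to_rgb(rgb_to_od(x))} reproduces
#' \code{x} exactly.
#'
#' @param od_image An \code{od_image}, or a bare \code{3 x d} OD matrix in
#'   which case \code{shape} must be supplied.
#' @param I0 Incident intensity (default taken from the object, else 255).
#' @param shape Optional \code{c(height, width)} override.
#' @return An [rgb_image()].
#' @export
od_to_rgb <- function(od_image, I0 = NULL, shape = NULL) {
  if (inherits(od_image, "od_image")) {
    od <- od_image$od
    if (is.null(shape)) shape <- od_image$shape
    if (is.null(I0)) I0 <- od_image$I0
  } else {
    od <- od_image
    if (is.null(shape)) stop("`shape` required for a bare OD matrix", call. = FALSE)
    if (is.null(I0)) I0 <- 255
  }
  if (!is.matrix(od) || nrow(od) != 3L) {
    stop("OD data must be a 3 x d matrix", call. = FALSE)
  }
  if (anyNA(od) || any(!is.finite(od))) {
    stop("OD values must be finite", call. = FALSE)
  }
  if (any(od < 0)) {
    stop("OD values must be non-negative", call. = FALSE)
  }
  h <- shape[1]; w <- shape[2]
  px <- array(0L, dim = c(h, w, 3L))
  for (ch in 1:3) {
    v <- round(I0 * exp(-od[ch, ]))
    v <- pmin(pmax(v, 0), 255)
    px[, , ch] <- t(matrix(v, nrow = w, ncol = h))  # undo row-major flatten
  }
  rgb_image(px, I0 = I0)
}

#' Mask near-white background pixels in OD space
#'
#' Flags pixels whose Euclidean OD norm is at or below \code{threshold} as
#' background. Background (unstained, near-white) pixels sit near the OD
#' origin; they are excluded from stain estimation but restored verbatim in
#' reconstructed outputs. A pixel exactly at the threshold is assigned to
#' background (deterministic tie rule). Idempotent for a fixed threshold.
#'
#' @param od_image An \code{od_image}.
#' @param threshold Positive OD-norm threshold; default 0.3.
#' @return The \code{od_image} with \code{background_mask} set.
#' @export
mask_background <- function(od_image, threshold = 0.3) {
  stopifnot(inherits(od_image, "od_image"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("`threshold` must be a positive scalar", call. = FALSE)
  }
  norms <- sqrt(colSums(od_image$od^2))
  od_image$background_mask <- norms <= threshold
  od_image
}

#' Count of foreground (tissue) pixels
#' @param od_image An \code{od_image} after [mask_background()].
#' @return Integer count of unmasked pixels.
#' @export
n_foreground <- function(od_image) {
  sum(!od_image$background_mask)
}

# ---- raster file I/O --------------------------------------------------------

image_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = "png",
         tif = , tiff = "tiff",
         jpg = , jpeg = "jpeg",
         stop("unsupported image format: .", ext,
              " (supported: png, tif/tiff, jpg/jpeg)", call. = FALSE))
}

#' Read an 8-bit RGB image file
#'
#' Supports PNG, TIFF and JPEG. Images with an alpha channel or fewer than
#' three channels are rejected.
#'
#' @param path File path; format is inferred from the extension.
#' @param I0 Incident intensity recorded on the returned object.
#' @return An [rgb_image()].
#' @export
read_rgb_image <- function(path, I0 = 255) {
  fmt <- image_format(path)
  arr <- switch(fmt,
    png  = png::readPNG(path),
    tiff = tiff::readTIFF(path),
    jpeg = read_jpeg_array(path)
  )
  if (length(dim(arr)) == 2L) {
    stop("grayscale image: 3 channels required", call. = FALSE)
  }
  if (dim(arr)[3] == 4L) {
    stop("image has an alpha channel; flatten to RGB first", call. = FALSE)
  }
  rgb_image(round(arr * 255), I0 = I0)
}

#' Write an 8-bit RGB image file
#'
#' @param image An [rgb_image()].
#' @param path Output path; format inferred from the extension.
#' @return The path, invisibly.
#' @export
write_rgb_image <- function(image, path) {
  stopifnot(is_rgb_image(image))
  fmt <- image_format(path)
  arr <- image$pixels / 255
  switch(fmt,
    png  = png::writePNG(arr, target = path),
    tiff = tiff::writeTIFF(arr, where = path, bits.per.sample = 8L),
    jpeg = write_jpeg_array(arr, path)
  )
  invisible(path)
}

read_jpeg_array <- function(path) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("JPEG support requires the EBImage package", call. = FALSE)
  }
  img <- EBImage::readImage(path)
  a <- EBImage::imageData(img)
  # EBImage stores width x height x channel; transpose to height x width
  aperm(a, c(2L, 1L, 3L))
}

write_jpeg_array <- function(arr, path) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("JPEG support requires the EBImage package", call. = FALSE)
  }
  EBImage::writeImage(EBImage::Image(aperm(arr, c(2L, 1L, 3L)),
                                     colormode = "Color"),
                      path, quality = 95)
  invisible(path)
}
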