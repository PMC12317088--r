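# Single-channel images are plain numeric matrices: rows are image rows
# (v, the y coordinate), columns are image columns (u, the x coordinate).
# Public pixel coordinates are 0-based: pixel (u, v) lives at
# matrix[v + 1, u + 1].

#' Validate a single-channel image
#'
#' Checks that `image` is a non-empty numeric matrix with only finite
#' intensities, and returns it (cast to double) so calls can be chained.
#'
#' @param image A numeric matrix of intensities.
#' @param arg Name used in error messages.
#' @return The validated image matrix (double storage mode).
#' @export
as_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop_validation(sprintf("`%s` must be a numeric matrix", arg))
  }
  if (nrow(image) < 1L || ncol(image) < 1L) {
    stop_validation(sprintf("`%s` must have at least one row and column", arg))
  }
  if (!all(is.finite(image))) {
    stop_validation(sprintf("`%s` contains non-finite intensities", arg))
  }
  storage.mode(image) <- "double"
  image
}

#' Load a 2D image from disk
#'
#' Reads PNG, TIFF or the package's raw `.r2d` array container into a
#' numeric intensity matrix. Colour input is collapsed to a single channel
#' with Rec. 709 luminance weights (0.2126 R + 0.7152 G + 0.0722 B) when
#' `convert_gray` is `TRUE`; the alpha channel, if any, is dropped.
#'
#' @param path Path to a `.png`, `.tif`/`.tiff` or `.r2d` file.
#' @param convert_gray Collapse colour input to luminance (default `TRUE`).
#' @return A numeric intensity matrix.
#' @seealso [write_image()], [load_channel_stack()]
#' @export
load_image <- function(path, convert_gray = TRUE) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = tryCatch(png::readPNG(path), error = function(e) {
      stop_io(sprintf("cannot read PNG '%s': %s", path, conditionMessage(e)))
    }),
    tif = ,
    tiff = tryCatch(tiff::readTIFF(path), error = function(e) {
      stop_io(sprintf("cannot read TIFF '%s': %s", path, conditionMessage(e)))
    }),
    r2d = read_r2d(path),
    stop_io(sprintf("unsupported image format '.%s' (%s)", ext, path))
  )
  if (is.list(arr)) arr <- arr[[1L]]  # first page of a multi-page TIFF
  if (length(dim(arr)) == 3L) {
    nc <- dim(arr)[3L]
    if (convert_gray && nc >= 3L) {
      arr <- 0.2126 * arr[, , 1L] + 0.7152 * arr[, , 2L] + 0.0722 * arr[, , 3L]
    } else {
      arr <- arr[, , 1L]
    }
  }
  as_image(as.matrix(arr), arg = path)
}

#' Write a 2D image to disk
#'
#' Writes PNG (8-bit), TIFF (16-bit by default) or the raw `.r2d`
#' container. PNG/TIFF encoders expect intensities in `[0, 1]`; with
#' `normalize = TRUE` (default) the image is min-max rescaled first. The
#' `.r2d` container stores doubles losslessly.
#'
#' @param image Numeric intensity matrix.
#' @param path Output path; format chosen from the extension.
#' @param normalize Min-max rescale to `[0, 1]` before encoding
#'   (ignored for `.r2d`).
#' @param bits Bits per sample for TIFF output (8 or 16).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, normalize = TRUE, bits = 16L) {
  image <- as_image(image)
  ext <- tolower(tools::file_ext(path))
  if (ext == "r2d") {
    return(write_r2d(image, path))
  }
  if (normalize) image <- normalize_intensity(image)
  if (min(image) < 0 || max(image) > 1) {
    stop_validation("PNG/TIFF output requires intensities in [0, 1]; use normalize = TRUE")
  }
  switch(ext,
    png = png::writePNG(image, path),
    tif = ,
    tiff = tiff::writeTIFF(image, path, bits.per.sample = as.integer(bits)),
    stop_io(sprintf("unsupported output format '.%s'", ext))
  )
  invisible(path)
}

# raw array container: magic "R2D1", int32 nrow, int32 ncol,
# doubles in column-major order; little-endian throughout
read_r2d <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(magic, "R2D1")) stop_io(sprintf("'%s' is not an r2d raster", path))
  dims <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  if (any(dims < 1L)) stop_validation("r2d raster has non-positive dimensions")
  vals <- readBin(con, "double", prod(dims), size = 8L, endian = "little")
  matrix(vals, nrow = dims[1L], ncol = dims[2L])
}

write_r2d <- function(image, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("R2D1", con, eos = NULL, useBytes = TRUE)
  writeBin(c(nrow(image), ncol(image)), con, size = 4L, endian = "little")
  writeBin(as.vector(image), con, size = 8L, endian = "little")
  invisible(path)
}

#' Clip intensity hotspots at a quantile
#'
#' Replaces every intensity strictly above the `quantile` quantile of the
#' image by that quantile value, leaving all other pixels untouched. This
#' tames the isolated very-bright pixels typical of mass-spectrometry
#' imaging. The quantile uses the linear-interpolation convention
#' (`stats::quantile()` type 7). The operation is idempotent.
#'
#' @param image Numeric intensity matrix.
#' @param quantile Quantile in `(0, 1]`; default 0.99.
#' @return The clipped image.
#' @export
hotspot_clip <- function(image, quantile = 0.99) {
  image <- as_image(image)
  if (!is.numeric(quantile) || length(quantile) != 1L ||
      quantile <= 0 || quantile > 1) {
    stop_validation("`quantile` must be a single number in (0, 1]")
  }
  q <- stats::quantile(as.vector(image), probs = quantile, names = FALSE, type = 7)
  image[image > q] <- q
  image
}

#' Rotate an image by quarter turns
#'
#' Rotates by `k` quarter turns; `k = +1` is counter-clockwise. Dimensions
#' swap when `k` is odd and four quarter turns restore the input exactly.
#'
#' @param image Numeric intensity matrix.
#' @param k Integer number of quarter turns (may be negative).
#' @return The rotated image.
#' @export
rotate90 <- function(image, k = 1L) {
  image <- as_image(image)
  k <- as.integer(k) %% 4L
  for (i in seq_len(k)) {
    image <- t(image)[ncol(image):1L, , drop = FALSE]
  }
  image
}

#' Min-max normalize intensities to [0, 1]
#'
#' Affine rescale so the minimum maps to 0 and the maximum to 1. A
#' constant image (zero dynamic range) maps to all zeros.
#'
#' @param image Numeric intensity matrix.
#' @return The rescaled image.
#' @export
normalize_intensity <- function(image) {
  image <- as_image(image)
  rng <- range(image)
  if (rng[2L] == rng[1L]) {
    return(matrix(0, nrow(image), ncol(image)))
  }
  (image - rng[1L]) / (rng[2L] - rng[1L])
}
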