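# Registration-quality metrics: Dice overlap and Hausdorff distance on
# binary annotation masks, and histogram mutual information on intensity
# images.

as_mask <- function(mask, arg = "mask") {
  if (is.matrix(mask) && is.numeric(mask)) mask <- mask > 0
  if (!is.matrix(mask) || !is.logical(mask)) {
    stop_validation(sprintf("`%s` must be a logical (or 0/1 numeric) matrix", arg))
  }
  mask
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop_validation(sprintf(
      "shapes differ: %d x %d vs %d x %d", nrow(a), ncol(a), nrow(b), ncol(b)
    ))
  }
}

#' Dice overlap coefficient
#'
#' `2 |A intersect B| / (|A| + |B|)`: 1 for identical masks, 0 for
#' disjoint ones.
#'
#' @param a,b Binary masks (logical or 0/1 matrices) of the same shape.
#' @return Scalar in `[0, 1]`.
#' @export
dice <- function(a, b) {
  a <- as_mask(a, "a")
  b <- as_mask(b, "b")
  check_same_shape(a, b)
  na <- sum(a)
  nb <- sum(b)
  if (na + nb == 0L) stop_validation("both masks are empty")
  2 * sum(a & b) / (na + nb)
}

#' Hausdorff distance between binary masks
#'
#' Symmetric Hausdorff distance `max(h(A, B), h(B, A))`, with `h` the
#' directed max-min Euclidean distance over foreground pixel coordinates,
#' computed on the full point sets (no percentile robustification).
#' Reported in pixels, or in physical units when `pixel_size` (e.g.
#' micrometres per pixel) is given.
#'
#' @param a,b Binary masks of the same shape, each with at least one
#'   foreground pixel.
#' @param pixel_size Physical size of one pixel (default 1 = pixels).
#' @return Non-negative scalar.
#' @export
hausdorff <- function(a, b, pixel_size = 1.0) {
  a <- as_mask(a, "a")
  b <- as_mask(b, "b")
  check_same_shape(a, b)
  pa <- which(a, arr.ind = TRUE)
  pb <- which(b, arr.ind = TRUE)
  if (nrow(pa) == 0L || nrow(pb) == 0L) {
    stop_validation("both masks need at least one foreground pixel")
  }
  directed <- function(p, q) {
    # chunk rows of p so the cross-distance matrix stays modest
    chunk <- max(1L, floor(4e6 / nrow(q)))
    worst <- 0
    for (s in seq(1L, nrow(p), by = chunk)) {
      idx <- s:min(s + chunk - 1L, nrow(p))
      d2 <- outer(rowSums(p[idx, , drop = FALSE]^2), rep(1, nrow(q))) +
        outer(rep(1, length(idx)), rowSums(q^2)) -
        2 * tcrossprod(p[idx, , drop = FALSE], q)
      worst <- max(worst, max(apply(d2, 1L, min)))
    }
    sqrt(max(worst, 0))
  }
  max(directed(pa, pb), directed(pb, pa)) * pixel_size
}

#' Histogram mutual information between two images
#'
#' Mutual information of the joint intensity histogram with `bins`
#' equal-width bins per axis spanning each image's min-max range.
#' Reported in nats (natural logarithm). A constant image on either side
#' carries zero marginal entropy, so the function warns and returns 0.
#'
#' @param a,b Numeric intensity matrices of the same shape.
#' @param bins Number of histogram bins per axis (>= 2, default 32).
#' @return Non-negative scalar (nats).
#' @export
mutual_information <- function(a, b, bins = 32L) {
  a <- as_image(a, "a")
  b <- as_image(b, "b")
  check_same_shape(a, b)
  bins <- as.integer(bins)
  if (bins < 2L) stop_validation("`bins` must be at least 2")
  if (diff(range(a)) == 0 || diff(range(b)) == 0) {
    warn("constant image: mutual information is 0 (zero marginal entropy)")
    return(0)
  }
  bin_of <- function(x) {
    r <- range(x)
    pmin(floor((x - r[1L]) / (r[2L] - r[1L]) * bins), bins - 1L) + 1L
  }
  ia <- bin_of(a)
  ib <- bin_of(b)
  joint <- tabulate((ia - 1L) * bins + ib, nbins = bins * bins)
  p <- joint / sum(joint)
  pa <- rowsum(p, rep(seq_len(bins), each = bins))[, 1L]
  pb <- rowsum(p, rep(seq_len(bins), times = bins))[, 1L]
  nz <- p > 0
  pr <- rep(pa, each = bins)[nz] * rep(pb, times = bins)[nz]
  max(sum(p[nz] * log(p[nz] / pr)), 0)
}

#' Entropy of an image's intensity histogram
#'
#' Marginal Shannon entropy (nats) with the same binning convention as
#' [mutual_information()]; `mutual_information(a, a)` equals this.
#'
#' @inheritParams mutual_information
#' @param image Numeric intensity matrix.
#' @return Non-negative scalar (nats).
#' @export
histogram_entropy <- function(image, bins = 32L) {
  image <- as_image(image)
  bins <- as.integer(bins)
  if (diff(range(image)) == 0) return(0)
  r <- range(image)
  idx <- pmin(floor((image - r[1L]) / (r[2L] - r[1L]) * bins), bins - 1L) + 1L
  p <- tabulate(idx, nbins = bins)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Evaluation report for a registered pair
#'
#' Computes Dice and Hausdorff on the masks and, when intensity images
#' are supplied, mutual information between them.
#'
#' @param fixed_mask,registered_mask Binary masks of the same shape.
#' @param fixed_image,registered_image Optional intensity images for the
#'   mutual-information entry.
#' @param bins Histogram bins for mutual information.
#' @param pixel_size Physical pixel size for the Hausdorff entry.
#' @return A one-row tibble: `dice`, `hausdorff`, `mutual_information`
#'   (NA without images), `bins`, `pixel_size`.
#' @export
evaluate_registration <- function(fixed_mask, registered_mask,
                                  fixed_image = NULL, registered_image = NULL,
                                  bins = 32L, pixel_size = 1.0) {
  mi <- NA_real_
  if (!is.null(fixed_image) && !is.null(registered_image)) {
    mi <- mutual_information(fixed_image, registered_image, bins = bins)
  }
  tibble::tibble(
    dice = dice(fixed_mask, registered_mask),
    hausdorff = hausdorff(fixed_mask, registered_mask, pixel_size = pixel_size),
    mutual_information = mi,
    bins = as.integer(bins),
    pixel_size = pixel_size
  )
}
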