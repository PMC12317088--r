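# Hierarchical average-pooling descriptor. A square working window of side
# W around each pixel is partitioned, layer by layer, into 2^(l-1) equal
# blocks; each block contributes its mean intensity. The single
# whole-window (layer 1) mean is removed from the concatenated vector and
# subtracted from every remaining entry, so the descriptor captures
# intensity *variation* within the window and is exactly invariant to a
# constant offset. Descriptor length for L layers is 2^L - 2.

#' Pyramid descriptor configuration
#'
#' @param window Side W of the square working window, in pixels.
#' @param layers Number of pooling layers L (>= 2); layer l holds
#'   2^(l-1) blocks, so the descriptor has 2^L - 2 entries.
#' @param min_distance Distance-regulation radius D in pixels: every
#'   selected keypoint must lie strictly farther than D from all earlier
#'   selections. Defaults to `window / 2`.
#' @param max_features Cap N on the number of selected keypoints.
#' @return A `pyramid_config` list.
#' @export
pyramid_config <- function(window = 32L, layers = 4L,
                           min_distance = window / 2, max_features = 500L) {
  window <- as.integer(window)
  layers <- as.integer(layers)
  if (window < 2L) stop_validation("`window` must be at least 2")
  if (layers < 2L) stop_validation("`layers` must be at least 2")
  finest <- pool_grid(layers)
  if (window < max(finest)) {
    stop_validation(sprintf(
      "`window` = %d too small for %d layers (finest split is %d x %d)",
      window, layers, finest[1L], finest[2L]
    ))
  }
  if (!is.numeric(min_distance) || min_distance <= 0) {
    stop_validation("`min_distance` must be positive")
  }
  max_features <- as.integer(max_features)
  if (max_features < 3L) stop_validation("`max_features` must be at least 3")
  structure(
    list(window = window, layers = layers,
         min_distance = as.numeric(min_distance), max_features = max_features),
    class = "pyramid_config"
  )
}

#' @export
print.pyramid_config <- function(x, ...) {
  cat(sprintf(
    "<pyramid_config> window %d px, %d layers (descriptor length %d), D = %g px, N = %d\n",
    x$window, x$layers, 2^x$layers - 2L, x$min_distance, x$max_features
  ))
  invisible(x)
}

# block grid (rows, cols) for layer l: 1x1, 1x2, 2x2, 4x2, 4x4, ...;
# after the first column split, splitting continues on whichever axis is
# currently coarser so blocks stay near-square
pool_grid <- function(l) {
  if (l == 1L) return(c(1L, 1L))
  nr <- 1L
  nc <- 2L
  if (l > 2L) {
    for (s in 3L:l) {
      if (nr <= nc) nr <- nr * 2L else nc <- nc * 2L
    }
  }
  c(nr, nc)
}

# per-layer block extents within a W-wide window, 1-based inclusive,
# row-major block order; boundaries round equal fractions so blocks may
# differ by one pixel when W is not divisible
pool_blocks <- function(window, layers) {
  blocks <- vector("list", 2^layers - 1L)
  k <- 0L
  for (l in seq_len(layers)) {
    g <- pool_grid(l)
    rb <- round(seq(0, window, length.out = g[1L] + 1L))
    cb <- round(seq(0, window, length.out = g[2L] + 1L))
    for (i in seq_len(g[1L])) {
      for (j in seq_len(g[2L])) {
        k <- k + 1L
        blocks[[k]] <- c(layer = l,
                         r0 = rb[i] + 1L, r1 = rb[i + 1L],
                         c0 = cb[j] + 1L, c1 = cb[j + 1L])
      }
    }
  }
  do.call(rbind, blocks)
}

# window extent around a 0-based center: rows (v - lo)..(v + hi)
window_offsets <- function(window) {
  lo <- window %/% 2L
  c(lo = lo, hi = window - 1L - lo)
}

#' Pooled descriptor at one pixel
#'
#' Computes the hierarchical average-pooling descriptor for the working
#' window centred at `center`. Blocks are ordered layer by layer
#' (row-major within a layer); the layer-1 whole-window mean is removed
#' and subtracted from the remaining entries.
#'
#' @param image Numeric intensity matrix.
#' @param center Pixel coordinates `c(u, v)` (0-based column, row).
#' @param config A [pyramid_config()].
#' @return Numeric descriptor of length `2^layers - 2`.
#' @export
descriptor_at <- function(image, center, config = pyramid_config()) {
  image <- as_image(image)
  u <- as.integer(center[[1L]])
  v <- as.integer(center[[2L]])
  off <- window_offsets(config$window)
  r0 <- v - off[["lo"]] + 1L   # 1-based top row of the window
  c0 <- u - off[["lo"]] + 1L
  if (r0 < 1L || c0 < 1L ||
      r0 + config$window - 1L > nrow(image) ||
      c0 + config$window - 1L > ncol(image)) {
    stop_validation(sprintf(
      "window of side %d at (u=%d, v=%d) exceeds the %d x %d image",
      config$window, u, v, nrow(image), ncol(image)
    ))
  }
  win <- image[r0:(r0 + config$window - 1L), c0:(c0 + config$window - 1L), drop = FALSE]
  bl <- pool_blocks(config$window, config$layers)
  means <- vapply(seq_len(nrow(bl)), function(k) {
    mean(win[bl[k, "r0"]:bl[k, "r1"], bl[k, "c0"]:bl[k, "c1"]])
  }, numeric(1L))
  means[-1L] - means[1L]
}

#' Dense feature-magnitude map
#'
#' Evaluates the pooled descriptor at every interior pixel (optionally on
#' a stride) and stores its Euclidean norm. Bright areas mark regions of
#' high local intensity variation; a border of width `ceiling(window / 2)`
#' is excluded because the working window would not fit. Computed with
#' integral images, so it is exact and deterministic.
#'
#' @param image Numeric intensity matrix, strictly larger than the working
#'   window in both dimensions.
#' @param config A [pyramid_config()].
#' @param stride Evaluation stride in pixels (default 1 = every pixel);
#'   recorded in the result.
#' @return A `magnitude_map`: list with `values` (matrix, zero outside the
#'   evaluated positions), `border_width`, `stride` and `config`.
#' @export
magnitude_map <- function(image, config = pyramid_config(), stride = 1L) {
  image <- as_image(image)
  h <- nrow(image)
  w <- ncol(image)
  if (h <= config$window || w <= config$window) {
    stop_validation(sprintf(
      "image (%d x %d) must be larger than the working window (%d)",
      h, w, config$window
    ))
  }
  stride <- as.integer(stride)
  if (stride < 1L) stop_validation("`stride` must be >= 1")
  bw <- as.integer(ceiling(config$window / 2))
  off <- window_offsets(config$window)

  # 0-based valid centers
  vs <- seq.int(bw, h - 1L - bw, by = stride)
  us <- seq.int(bw, w - 1L - bw, by = stride)

  # summed-area table: S[i + 1, j + 1] = sum(image[1:i, 1:j])
  S <- matrix(0, h + 1L, w + 1L)
  S[-1L, -1L] <- t(apply(apply(image, 2L, cumsum), 1L, cumsum))

  r_top <- vs - off[["lo"]] + 1L  # 1-based top row of each window
  c_left <- us - off[["lo"]] + 1L

  bl <- pool_blocks(config$window, config$layers)
  block_mean <- function(k) {
    a <- bl[k, "r0"]; b <- bl[k, "r1"]
    ca <- bl[k, "c0"]; cb <- bl[k, "c1"]
    area <- (b - a + 1L) * (cb - ca + 1L)
    (S[r_top + b, c_left + cb, drop = FALSE] -
       S[r_top + a - 1L, c_left + cb, drop = FALSE] -
       S[r_top + b, c_left + ca - 1L, drop = FALSE] +
       S[r_top + a - 1L, c_left + ca - 1L, drop = FALSE]) / area
  }

  m1 <- block_mean(1L)
  sq <- matrix(0, length(vs), length(us))
  for (k in 2L:nrow(bl)) {
    d <- block_mean(k) - m1
    sq <- sq + d * d
  }

  values <- matrix(0, h, w)
  values[vs + 1L, us + 1L] <- sqrt(sq)
  structure(
    list(values = values, border_width = bw, stride = stride, config = config),
    class = "magnitude_map"
  )
}

#' @export
print.magnitude_map <- function(x, ...) {
  cat(sprintf(
    "<magnitude_map> %d x %d, border %d px, stride %d, max magnitude %.4g\n",
    nrow(x$values), ncol(x$values), x$border_width, x$stride, max(x$values)
  ))
  invisible(x)
}
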