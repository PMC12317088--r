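# Multichannel stacks (e.g. one MALDI ion image per m/z value) are stored
# as h x w x n_channels arrays; collapse_channels() reduces them to the
# single registration channel the pipeline consumes.

#' Construct a channel stack
#'
#' @param channels A 3D numeric array (height x width x n_channels), or a
#'   list of same-shaped matrices.
#' @param labels Optional character vector of channel labels (e.g. m/z
#'   values), one per channel.
#' @return A `channel_stack`: the array with a `labels` attribute.
#' @export
channel_stack <- function(channels, labels = NULL) {
  if (is.list(channels)) {
    dims <- unique(lapply(channels, dim))
    if (length(dims) != 1L) stop_validation("all channels must share height/width")
    channels <- array(unlist(channels), dim = c(dims[[1L]], length(channels)))
  }
  if (!is.array(channels) || length(dim(channels)) != 3L) {
    stop_validation("`channels` must be a height x width x n_channels array")
  }
  if (dim(channels)[3L] < 1L) stop_validation("need at least one channel")
  if (!all(is.finite(channels))) stop_validation("non-finite channel intensities")
  if (!is.null(labels) && length(labels) != dim(channels)[3L]) {
    stop_validation("`labels` must have one entry per channel")
  }
  structure(channels, labels = labels, class = c("channel_stack", "array"))
}

#' Load a multi-page TIFF as a channel stack
#'
#' @param path Path to a (possibly multi-page) TIFF file.
#' @return A [channel_stack()].
#' @export
load_channel_stack <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE), error = function(e) {
    stop_io(sprintf("cannot read TIFF '%s': %s", path, conditionMessage(e)))
  })
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    as.matrix(p)
  })
  channel_stack(pages)
}

# registry of embedding methods; each entry is function(x, seed) -> numeric
# vector with one value per pixel, where x is the n_pixels x n_channels
# matrix of channel intensities
the_embeddings <- new.env(parent = emptyenv())

#' Register a channel-embedding method
#'
#' Embedding methods collapse an n-channel pixel stack to one value per
#' pixel. A method is a `function(x, seed)` taking the n_pixels x
#' n_channels matrix and returning a numeric vector of length
#' `nrow(x)`. Stochastic methods must honour `seed` so runs are
#' reproducible.
#'
#' @param name Method identifier.
#' @param fn The embedding function.
#' @return `name`, invisibly.
#' @export
register_embedding <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = the_embeddings)
  invisible(name)
}

#' Collapse a channel stack to a single registration channel
#'
#' Reduces a multichannel stack (e.g. per-ion mass-spectrometry images) to
#' one single-channel image that the registration pipeline can consume.
#' Built-in methods:
#'
#' * `"mean"` (default): per-pixel arithmetic mean across channels —
#'   deterministic and bit-stable.
#' * `"pc1"`: per-pixel projection onto the first principal direction of
#'   the channel covariance, sign-fixed so the dominant loading is
#'   positive — deterministic.
#'
#' Further methods (e.g. stochastic manifold embeddings) can be plugged in
#' with [register_embedding()]; they receive `seed` and must be
#' reproducible for a fixed seed.
#'
#' @param stack A [channel_stack()] or 3D array.
#' @param method Embedding method identifier.
#' @param seed Integer seed forwarded to stochastic methods.
#' @return A numeric intensity matrix of the stack's height/width.
#' @export
collapse_channels <- function(stack, method = "mean", seed = 0L) {
  if (!inherits(stack, "channel_stack")) stack <- channel_stack(stack)
  if (!exists(method, envir = the_embeddings, inherits = FALSE)) {
    stop_config(sprintf(
      "unknown embedding method '%s' (registered: %s)",
      method, paste(ls(the_embeddings), collapse = ", ")
    ))
  }
  d <- dim(stack)
  x <- matrix(as.vector(stack), nrow = d[1L] * d[2L], ncol = d[3L])
  fn <- get(method, envir = the_embeddings)
  out <- fn(x, seed)
  if (length(out) != d[1L] * d[2L]) {
    stop_config(sprintf("embedding '%s' returned %d values for %d pixels",
                        method, length(out), d[1L] * d[2L]))
  }
  as_image(matrix(out, nrow = d[1L], ncol = d[2L]))
}

register_embedding("mean", function(x, seed) rowMeans(x))

register_embedding("pc1", function(x, seed) {
  if (ncol(x) == 1L) return(x[, 1L])
  xc <- sweep(x, 2L, colMeans(x))
  v <- svd(xc, nu = 0L, nv = 1L)$v[, 1L]
  if (v[which.max(abs(v))] < 0) v <- -v
  as.vector(xc %*% v)
})
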