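# Distance-regulated keypoint selection from a feature-magnitude map.
# Candidates are visited in descending magnitude (ties broken by row-major
# scan order, so runs are reproducible); a candidate is accepted only if
# its minimum Euclidean distance to every earlier acceptance exceeds D,
# enforced by masking a disc of radius D around each accepted point.

#' Select keypoints from a magnitude map
#'
#' Greedy selection in descending magnitude under distance regulation:
#' each accepted keypoint must lie strictly farther than
#' `config$min_distance` from all previously accepted ones, and at most
#' `config$max_features` points are returned. Zero-magnitude pixels
#' (constant neighbourhoods and the excluded border) are never selected.
#'
#' @param map A [magnitude_map()] computed with `config`.
#' @param image The image the map was computed from (used to attach
#'   descriptors).
#' @param config The same [pyramid_config()] used for the map.
#' @return A `keypoints` tibble with columns `u`, `v` (0-based pixel
#'   coordinates), `magnitude`, and a `descriptor` list-column, ordered by
#'   decreasing magnitude.
#' @export
select_keypoints <- function(map, image, config = pyramid_config()) {
  if (!inherits(map, "magnitude_map")) {
    stop_validation("`map` must be a magnitude_map")
  }
  if (!identical(map$config, config)) {
    stop_validation("`config` differs from the one the map was computed with")
  }
  image <- as_image(image)
  vals <- map$values
  h <- nrow(vals)
  w <- ncol(vals)
  D <- config$min_distance
  N <- config$max_features

  cand <- which(vals > 0)
  if (length(cand) == 0L) {
    return(new_keypoints(tibble::tibble(
      u = integer(), v = integer(), magnitude = numeric(),
      descriptor = list()
    ), config))
  }
  rows <- ((cand - 1L) %% h) + 1L        # 1-based
  cols <- ((cand - 1L) %/% h) + 1L
  ord <- order(-vals[cand], rows, cols)  # magnitude desc, then scan order
  rows <- rows[ord]
  cols <- cols[ord]

  # disc stencil of radius D (offsets with dr^2 + dc^2 <= D^2)
  rad <- floor(D)
  offs <- expand.grid(dr = -rad:rad, dc = -rad:rad)
  offs <- offs[offs$dr^2 + offs$dc^2 <= D^2, , drop = FALSE]

  masked <- matrix(FALSE, h, w)
  sel_r <- integer(0)
  sel_c <- integer(0)
  for (i in seq_along(rows)) {
    r <- rows[i]
    cc <- cols[i]
    if (masked[r, cc]) next
    sel_r <- c(sel_r, r)
    sel_c <- c(sel_c, cc)
    if (length(sel_r) >= N) break
    mr <- r + offs$dr
    mc <- cc + offs$dc
    ok <- mr >= 1L & mr <= h & mc >= 1L & mc <= w
    masked[cbind(mr[ok], mc[ok])] <- TRUE
  }

  u <- sel_c - 1L
  v <- sel_r - 1L
  desc <- lapply(seq_along(u), function(i) {
    descriptor_at(image, c(u[i], v[i]), config)
  })
  kp <- tibble::tibble(
    u = as.integer(u), v = as.integer(v),
    magnitude = vapply(desc, function(d) sqrt(sum(d^2)), numeric(1L)),
    descriptor = desc
  )
  new_keypoints(kp, config)
}

new_keypoints <- function(tbl, config) {
  class(tbl) <- c("keypoints", class(tbl))
  attr(tbl, "config") <- config
  tbl
}

#' Detect keypoints in one image
#'
#' Convenience wrapper: computes the [magnitude_map()] and runs
#' [select_keypoints()].
#'
#' @inheritParams magnitude_map
#' @return A `keypoints` tibble (see [select_keypoints()]).
#' @export
detect_keypoints <- function(image, config = pyramid_config(), stride = 1L) {
  image <- as_image(image)
  map <- magnitude_map(image, config, stride = stride)
  select_keypoints(map, image, config)
}

# n x d descriptor matrix from a keypoints tibble
descriptor_matrix <- function(keypoints) {
  if (nrow(keypoints) == 0L) return(matrix(numeric(0), 0L, 0L))
  do.call(rbind, keypoints$descriptor)
}

#' Write keypoints to CSV
#'
#' Columns `u`, `v`, `magnitude` followed by one column per descriptor
#' entry (`d1`, `d2`, ...).
#'
#' @param keypoints A `keypoints` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_keypoints_csv <- function(keypoints, path) {
  d <- descriptor_matrix(keypoints)
  if (nrow(keypoints) > 0L) colnames(d) <- paste0("d", seq_len(ncol(d)))
  out <- cbind(
    data.frame(u = keypoints$u, v = keypoints$v, magnitude = keypoints$magnitude),
    as.data.frame(d)
  )
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
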