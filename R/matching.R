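# Feature matching between modalities. Rows of the correlation matrix are
# moving-image descriptors, columns fixed-image descriptors; each entry is
# their Euclidean distance. A Lowe-style ratio test accepts a row's best
# match iff best <= 0.75 * second-best (boundary equality accepted), and a
# robust perspective-consistency consensus removes positionally
# inconsistent pairs before the affine fit.

#' Descriptor correlation (distance) matrix
#'
#' Entry `(i, j)` is the Euclidean distance between moving descriptor `i`
#' and fixed descriptor `j`.
#'
#' @param moving,fixed `keypoints` tibbles with equal-length descriptors.
#' @return An `n_moving` x `n_fixed` numeric matrix.
#' @export
correlation_matrix <- function(moving, fixed) {
  A <- descriptor_matrix(moving)
  B <- descriptor_matrix(fixed)
  if (nrow(A) == 0L || nrow(B) == 0L) {
    stop_validation("both keypoint sets must be non-empty")
  }
  if (ncol(A) != ncol(B)) {
    stop_validation(sprintf("descriptor lengths differ (%d vs %d)", ncol(A), ncol(B)))
  }
  d2 <- outer(rowSums(A^2), rep(1, nrow(B))) +
    outer(rep(1, nrow(A)), rowSums(B^2)) - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

new_match_set <- function(tbl, stage) {
  class(tbl) <- c("match_set", class(tbl))
  attr(tbl, "stage") <- stage
  tbl
}

#' Ratio-test matching
#'
#' For each moving feature (row of `H`) the distances are sorted
#' ascending and the best fixed match is accepted iff
#' `best <= ratio * second_best` (equality counts as a true match). With
#' `dedupe = TRUE` (default) a fixed keypoint claimed by several moving
#' keypoints keeps only the smallest-distance pair, so each index appears
#' at most once on either side.
#'
#' @param H Correlation matrix from [correlation_matrix()] (needs at
#'   least two columns so a second-best exists).
#' @param ratio Acceptance threshold (default 0.75).
#' @param dedupe Resolve duplicate fixed targets by smallest distance.
#' @return A `match_set` tibble (`moving`, `fixed`, `distance`) with
#'   stage `"ratio_filtered"`.
#' @export
ratio_test_match <- function(H, ratio = 0.75, dedupe = TRUE) {
  if (!is.matrix(H) || ncol(H) < 2L) {
    stop_validation("ratio test needs at least two fixed features (columns)")
  }
  if (ratio <= 0) stop_validation("`ratio` must be positive")
  best_j <- max.col(-H, ties.method = "first")
  n <- nrow(H)
  best <- H[cbind(seq_len(n), best_j)]
  second <- vapply(seq_len(n), function(i) min(H[i, -best_j[i]]), numeric(1L))
  keep <- best <= second * ratio
  out <- tibble::tibble(
    moving = which(keep),
    fixed = best_j[keep],
    distance = best[keep]
  )
  if (dedupe && nrow(out) > 0L) {
    out <- out[order(out$distance), ]
    out <- out[!duplicated(out$fixed), ]
    out <- out[order(out$moving), ]
  }
  new_match_set(out, "ratio_filtered")
}

# homography from >= 4 point pairs by normalized DLT; returns NULL when
# the configuration is degenerate
fit_homography <- function(src, dst) {
  norm_pts <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2L, ctr)^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else return(NULL)
    T <- matrix(c(s, 0, 0, 0, s, 0, -s * ctr[1L], -s * ctr[2L], 1), 3L, 3L)
    list(p = cbind(p, 1) %*% t(T), T = T)
  }
  ns <- norm_pts(src)
  nd <- norm_pts(dst)
  if (is.null(ns) || is.null(nd)) return(NULL)
  n <- nrow(src)
  A <- matrix(0, 2L * n, 9L)
  for (i in seq_len(n)) {
    x <- ns$p[i, ]
    xp <- nd$p[i, 1L]
    yp <- nd$p[i, 2L]
    A[2L * i - 1L, ] <- c(-x, 0, 0, 0, xp * x)
    A[2L * i, ] <- c(0, 0, 0, -x, yp * x)
  }
  sv <- svd(A, nu = 0L, nv = 9L)
  if (sv$d[8L] < 1e-10 * sv$d[1L]) return(NULL)  # rank-deficient sample
  H <- matrix(sv$v[, 9L], 3L, 3L, byrow = TRUE)
  H <- solve(nd$T) %*% H %*% ns$T
  if (abs(H[3L, 3L]) < 1e-12) return(NULL)
  H / H[3L, 3L]
}

project_homography <- function(H, pts) {
  p <- cbind(pts, 1) %*% t(H)
  p[, 1:2, drop = FALSE] / p[, 3L]
}

# TRUE when any three of the points are (near-)collinear
sample_degenerate <- function(p, tol = 1e-6) {
  n <- nrow(p)
  cmb <- utils::combn(n, 3L)
  for (k in seq_len(ncol(cmb))) {
    a <- p[cmb[1L, k], ]
    b <- p[cmb[2L, k], ]
    cc <- p[cmb[3L, k], ]
    area <- abs((b[1L] - a[1L]) * (cc[2L] - a[2L]) -
                  (cc[1L] - a[1L]) * (b[2L] - a[2L]))
    if (area < tol) return(TRUE)
  }
  FALSE
}

#' Perspective-consistency filtering of matches
#'
#' Matched features on two planes of the same scene should be related by
#' a plane-to-plane perspective transform. A seeded random-sample
#' consensus fits homographies to minimal 4-pair samples and keeps the
#' model with the most pairs whose reprojection error is below
#' `threshold`; only those inlier pairs are returned. One refinement pass
#' refits the homography on the inliers and recollects them.
#'
#' @param matches A ratio-filtered `match_set`.
#' @param moving,fixed `keypoints` tibbles the match indices refer to.
#' @param threshold Inlier reprojection threshold in pixels (default 3).
#' @param iterations Number of consensus samples (default 2000).
#' @param seed RNG seed (default 0) so runs are reproducible.
#' @return A `match_set` with stage `"geometry_filtered"` (a subset of
#'   the input pairs) carrying the fitted homography as attribute
#'   `"homography"`.
#' @export
geometry_filter <- function(matches, moving, fixed,
                            threshold = 3, iterations = 2000L, seed = 0L) {
  if (nrow(matches) < 4L) {
    stop_insufficient_matches(sprintf(
      "perspective filtering needs at least 4 pairs (got %d)", nrow(matches)
    ))
  }
  src <- cbind(moving$u[matches$moving], moving$v[matches$moving])
  dst <- cbind(fixed$u[matches$fixed], fixed$v[matches$fixed])
  n <- nrow(src)

  best_inl <- NULL
  best_score <- -Inf
  withr::with_seed(seed, {
    for (it in seq_len(iterations)) {
      s <- sample.int(n, 4L)
      if (sample_degenerate(src[s, , drop = FALSE]) ||
          sample_degenerate(dst[s, , drop = FALSE])) next
      H <- fit_homography(src[s, , drop = FALSE], dst[s, , drop = FALSE])
      if (is.null(H)) next
      err <- sqrt(rowSums((project_homography(H, src) - dst)^2))
      inl <- which(err < threshold)
      score <- length(inl) - mean(err[inl]) / (10 * threshold)
      if (length(inl) > 0L && score > best_score) {
        best_score <- score
        best_inl <- inl
      }
    }
  })
  if (is.null(best_inl) || length(best_inl) < 3L) {
    stop_degenerate_geometry("consensus failed: matched pairs admit no perspective model")
  }
  # refinement: refit on the inliers and recollect
  H <- fit_homography(src[best_inl, , drop = FALSE], dst[best_inl, , drop = FALSE])
  if (!is.null(H)) {
    err <- sqrt(rowSums((project_homography(H, src) - dst)^2))
    inl <- which(err < threshold)
    if (length(inl) >= length(best_inl)) best_inl <- inl
  }
  out <- matches[sort(best_inl), , drop = FALSE]
  out <- new_match_set(tibble::as_tibble(out), "geometry_filtered")
  attr(out, "homography") <- H
  out
}
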