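# End-to-end feature-based registration: preprocess both images, detect
# keypoints, match descriptors with the ratio test, filter by perspective
# consistency, and fit the affine transform on the surviving inliers.
#
# Two pipeline-level robustness devices wrap the core matcher:
#
# * Rotation-hypothesis search. The pooled descriptor is computed in an
#   axis-aligned window, so it degrades as the residual rotation between
#   the images grows. Analogous to pre-rotating modality pairs acquired
#   90 degrees apart, the pipeline scans a small set of coarse rotation
#   hypotheses, scores each by a fast robust-consensus inlier count, and
#   keeps the best; the final transform composes the winning pre-rotation
#   with the fitted residual.
# * Warp refinement. After the coarse fit the moving image is resampled
#   into the fixed frame and matched again; at near-identity residual the
#   descriptor's rotation/scale biases vanish, so the composed transform
#   converges to sub-pixel accuracy. Each refinement ends with a guided
#   spatial re-match (nearest projected keypoint within the inlier gate)
#   so the least-squares fit averages over as many true pairs as possible.

# fast robust affine consensus on point pairs (3-point minimal samples);
# used for hypothesis scoring and refinement, not as the spec'd
# perspective filter
affine_ransac <- function(src, dst, threshold = 3, iterations = 300L, seed = 0L) {
  n <- nrow(src)
  if (n < 3L) return(NULL)
  best_inl <- NULL
  withr::with_seed(seed, {
    for (it in seq_len(iterations)) {
      s <- sample.int(n, 3L)
      p <- src[s, , drop = FALSE]
      area <- abs((p[2L, 1L] - p[1L, 1L]) * (p[3L, 2L] - p[1L, 2L]) -
                    (p[3L, 1L] - p[1L, 1L]) * (p[2L, 2L] - p[1L, 2L]))
      if (area < 1e-6) next
      A <- tryCatch(solve(cbind(p, 1), dst[s, , drop = FALSE]),
                    error = function(e) NULL)
      if (is.null(A)) next
      err <- sqrt(rowSums((cbind(src, 1) %*% A - dst)^2))
      inl <- which(err < threshold)
      if (length(inl) > length(best_inl)) best_inl <- inl
    }
  })
  best_inl
}

# nearest-fixed-keypoint re-matching under a current transform estimate,
# followed by a least-squares refit; iterated to convergence
guided_refit <- function(M, kp_moving, kp_fixed, gate = 3, passes = 3L) {
  fl <- cbind(kp_fixed$u, kp_fixed$v)
  ml <- cbind(kp_moving$u, kp_moving$v)
  pairs <- NULL
  for (i in seq_len(passes)) {
    proj <- transform_points(M, ml)
    d2 <- outer(rowSums(proj^2), rep(1, nrow(fl))) +
      outer(rep(1, nrow(proj)), rowSums(fl^2)) - 2 * tcrossprod(proj, fl)
    j <- max.col(-d2)
    dd <- sqrt(pmax(d2[cbind(seq_len(nrow(proj)), j)], 0))
    keep <- which(dd <= gate)
    if (length(keep) < 3L) break
    cand <- tibble::tibble(moving = keep, fixed = j[keep], distance = dd[keep])
    cand <- cand[order(cand$distance), ]
    cand <- cand[!duplicated(cand$fixed), ]
    if (nrow(cand) < 3L) break
    M2 <- tryCatch(estimate_affine(cand, kp_moving, kp_fixed),
                   error = function(e) NULL)
    if (is.null(M2)) break
    M <- M2
    pairs <- cand
  }
  list(M = M, pairs = pairs)
}

# subpixel correspondence polish used in the warp-refinement passes:
# around each matched pair the fixed-side position is adjusted to the
# normalized-cross-correlation peak of the local patches (quadratic
# interpolation of the peak for subpixel precision). NCC tolerates the
# monotone intensity remaps between modalities; for an inverted-contrast
# pair the moving patch is sign-flipped first.
ncc_refine <- function(fx, mv, src, dst, patch = 12L, search = 3L,
                       flip = FALSE) {
  h <- nrow(fx)
  w <- ncol(fx)
  out <- dst + 0
  score <- rep(NA_real_, nrow(src))
  sgn <- if (flip) -1 else 1
  parab <- function(m1, m0, p1) {
    den <- 2 * (m1 - 2 * m0 + p1)
    d <- if (abs(den) < 1e-12) 0 else (m1 - p1) / den
    if (!is.finite(d) || abs(d) > 1) 0 else d
  }
  for (i in seq_len(nrow(src))) {
    pu <- src[i, 1L]; pv <- src[i, 2L]
    qu <- dst[i, 1L]; qv <- dst[i, 2L]
    if (pu - patch < 0 || pv - patch < 0 ||
        pu + patch > w - 1 || pv + patch > h - 1) next
    if (qu - patch - search < 0 || qv - patch - search < 0 ||
        qu + patch + search > w - 1 || qv + patch + search > h - 1) next
    A <- sgn * mv[(pv - patch):(pv + patch) + 1L, (pu - patch):(pu + patch) + 1L]
    A <- A - mean(A)
    na <- sqrt(sum(A * A))
    if (na == 0) next
    sc <- matrix(-Inf, 2L * search + 1L, 2L * search + 1L)
    for (dv in -search:search) {
      for (du in -search:search) {
        B <- fx[(qv + dv - patch):(qv + dv + patch) + 1L,
                (qu + du - patch):(qu + du + patch) + 1L]
        B <- B - mean(B)
        nb <- sqrt(sum(B * B))
        if (nb == 0) next
        sc[dv + search + 1L, du + search + 1L] <- sum(A * B) / (na * nb)
      }
    }
    k <- which(sc == max(sc), arr.ind = TRUE)[1L, ]
    bv <- k[1L]; bu <- k[2L]
    score[i] <- sc[bv, bu]
    if (bv == 1L || bv == nrow(sc) || bu == 1L || bu == ncol(sc)) next
    out[i, ] <- c(
      qu + (bu - search - 1L) + parab(sc[bv, bu - 1L], sc[bv, bu], sc[bv, bu + 1L]),
      qv + (bv - search - 1L) + parab(sc[bv - 1L, bu], sc[bv, bu], sc[bv + 1L, bu])
    )
  }
  list(dst = out, score = score)
}

# plain least-squares affine on coordinate pairs
ls_affine <- function(src, dst) {
  X <- cbind(src, 1)
  qx <- qr(X)
  if (qx$rank < 3L) return(NULL)
  B <- qr.coef(qx, dst)
  affine_transform(rbind(t(B), c(0, 0, 1)))
}

# trimmed least squares: refit after discarding pairs whose residual
# exceeds 2x the median residual (floored at half a pixel), repeated
# twice; guards the final fit against residual mismatches
ls_affine_trimmed <- function(src, dst) {
  M <- ls_affine(src, dst)
  if (is.null(M)) return(NULL)
  keep <- seq_len(nrow(src))
  for (i in 1:2) {
    r <- sqrt(rowSums((transform_points(M, src[keep, , drop = FALSE]) -
                         dst[keep, , drop = FALSE])^2))
    cut <- max(2 * stats::median(r), 0.5)
    k2 <- keep[r <= cut]
    if (length(k2) < max(6L, length(keep) %/% 2L) ||
        length(k2) == length(keep)) break
    keep <- k2
    M2 <- ls_affine(src[keep, , drop = FALSE], dst[keep, , drop = FALSE])
    if (is.null(M2)) break
    M <- M2
  }
  attr(M, "kept") <- keep
  M
}

# drop keypoints whose working window overlaps resampling fill (pixels
# that map outside the source image when a hypothesis or refinement warp
# is applied); features detected on the artificial fill edge would
# otherwise be spatially re-matched to real structure and bias the fit
filter_fill_keypoints <- function(kp, valid, window) {
  if (nrow(kp) == 0L) return(kp)
  inv <- 1 - valid
  h <- nrow(inv)
  w <- ncol(inv)
  S <- matrix(0, h + 1L, w + 1L)
  S[-1L, -1L] <- t(apply(apply(inv, 2L, cumsum), 1L, cumsum))
  lo <- window %/% 2L
  hi <- window - 1L - lo
  r0 <- kp$v - lo + 1L
  r1 <- kp$v + hi + 1L
  c0 <- kp$u - lo + 1L
  c1 <- kp$u + hi + 1L
  cnt <- S[cbind(r1 + 1L, c1 + 1L)] - S[cbind(r0, c1 + 1L)] -
    S[cbind(r1 + 1L, c0)] + S[cbind(r0, c0)]
  kp[cnt == 0, , drop = FALSE]
}

# pairing-independent global alignment score: mutual information between
# the fixed image and a warped moving image over the valid (non-fill)
# pixels; used to select among refinement passes so a pass that drifts
# into a wrong correspondence basin cannot win
mi_score <- function(fx, mv_w, valid, bins = 32L) {
  av <- fx[valid]
  bv <- mv_w[valid]
  if (length(av) < 100L || diff(range(av)) == 0 || diff(range(bv)) == 0) {
    return(-Inf)
  }
  bin <- function(x) {
    r <- range(x)
    pmin(floor((x - r[1L]) / (r[2L] - r[1L]) * bins), bins - 1L) + 1L
  }
  ia <- bin(av)
  ib <- bin(bv)
  p <- tabulate((ia - 1L) * bins + ib, nbins = bins * bins)
  p <- p / sum(p)
  pa <- rowsum(p, rep(seq_len(bins), each = bins))[, 1L]
  pb <- rowsum(p, rep(seq_len(bins), times = bins))[, 1L]
  nz <- p > 0
  sum(p[nz] * log(p[nz] / (rep(pa, each = bins)[nz] * rep(pb, times = bins)[nz])))
}

rotation_about_center <- function(angle, shape) {
  make_affine(rotation = angle,
              center = c((shape[2L] - 1) / 2, (shape[1L] - 1) / 2))
}

flip_descriptors <- function(kp) {
  kp$descriptor <- lapply(kp$descriptor, function(d) -d)
  kp
}

# unit-norm descriptor copies for matching: a monotone intensity remap is
# locally affine, and the pooled descriptor is already offset-free, so
# dividing by the norm removes the remaining local gain difference
# between modalities; Euclidean distance on unit vectors is then a
# monotone function of cosine similarity
unitize_descriptors <- function(kp) {
  kp$descriptor <- lapply(kp$descriptor, function(d) {
    n <- sqrt(sum(d^2))
    if (n > 0) d / n else d
  })
  kp
}

#' Register a moving image onto a fixed image
#'
#' Runs the full feature-based pipeline: preprocessing (hotspot clipping
#' at `clip_quantile` then min-max normalization, on working copies),
#' dense pooled-descriptor keypoint detection in both images, ratio-test
#' matching on descriptor distances, perspective-consistency filtering,
#' and a least-squares affine fit, followed by warp-refinement passes
#' (see Details). The returned warped image resamples the original
#' moving input.
#'
#' @details
#' Because the pooled descriptor is linear in intensity, a
#' contrast-inverted modality negates every descriptor while leaving the
#' magnitude map — and hence keypoint detection — unchanged. With
#' `polarity = "auto"` (default) matching is attempted with the moving
#' descriptors as-is and negated, and the polarity yielding the larger
#' consensus wins (ties go to `"direct"`).
#'
#' The axis-aligned descriptor also degrades with residual rotation, so
#' the angles in `rotation_search` are tried as coarse pre-rotations of
#' the moving image and scored by consensus inlier count; the scan stops
#' early once a hypothesis explains a clear majority of its candidate
#' matches. `refine` warp-refinement passes then re-register the
#' current warped moving image onto the fixed image and compose the
#' residual, which removes the descriptor's small rotation/scale biases.
#' Set `rotation_search = 0` and `refine = 0` for the bare single-pass
#' pipeline.
#'
#' @param fixed,moving Numeric intensity matrices.
#' @param config A [pyramid_config()].
#' @param ratio Ratio-test threshold (default 0.75).
#' @param threshold,iterations,seed Perspective-consensus parameters, see
#'   [geometry_filter()].
#' @param preprocess Apply hotspot clipping + normalization before
#'   feature detection (default `TRUE`).
#' @param clip_quantile Hotspot-clipping quantile.
#' @param rotate_moving Quarter turns applied to the moving image before
#'   registration (signed; for modality pairs acquired 90 degrees
#'   apart). The returned transform maps the *rotated* moving frame and
#'   the rotation is recorded in the result.
#' @param polarity `"auto"`, `"direct"` or `"inverted"` descriptor
#'   polarity for the moving image.
#' @param rotation_search Numeric vector of coarse rotation hypotheses
#'   in degrees, tried in order.
#' @param refine Number of warp-refinement passes (default 2).
#' @return A `registration` object (list) with elements `transform`,
#'   `warped`, `keypoints_fixed`, `keypoints_moving`, `matches_ratio`,
#'   `matches_geometry`, `matches_refined`, `projection_error`, `rmse`,
#'   `polarity`, `coarse_rotation`, `rotate_moving` and `config`.
#' @export
register_images <- function(fixed, moving, config = pyramid_config(),
                            ratio = 0.75, threshold = 3, iterations = 2000L,
                            seed = 0L, preprocess = TRUE,
                            clip_quantile = 0.99, rotate_moving = 0L,
                            polarity = c("auto", "direct", "inverted"),
                            rotation_search = c(0, -10, 10, -20, 20, -30, 30),
                            refine = 3L) {
  polarity <- match.arg(polarity)
  fixed <- as_image(fixed, "fixed")
  moving <- as_image(moving, "moving")
  if (rotate_moving != 0L) moving <- rotate90(moving, rotate_moving)

  prep <- function(img) {
    if (!preprocess) return(img)
    normalize_intensity(hotspot_clip(img, clip_quantile))
  }
  fx <- prep(fixed)
  mv <- prep(moving)

  kp_fixed <- detect_keypoints(fx, config)
  if (nrow(kp_fixed) < 3L) {
    stop_insufficient_matches("too few keypoints detected in the fixed image")
  }
  fx_desc <- unitize_descriptors(kp_fixed)

  polarities <- switch(polarity, auto = c(FALSE, TRUE),
                       direct = FALSE, inverted = TRUE)

  match_one <- function(kp_mov, flip) {
    km <- unitize_descriptors(kp_mov)
    if (flip) km <- flip_descriptors(km)
    H <- correlation_matrix(km, fx_desc)
    rt <- ratio_test_match(H, ratio = ratio)
    if (nrow(rt) < 4L) return(NULL)
    src <- cbind(kp_mov$u[rt$moving], kp_mov$v[rt$moving])
    dst <- cbind(kp_fixed$u[rt$fixed], kp_fixed$v[rt$fixed])
    inl <- affine_ransac(src, dst, threshold = threshold,
                         iterations = 300L, seed = seed)
    if (length(inl) < 3L) return(NULL)
    list(ratio = rt, score = length(inl), n_pairs = nrow(rt))
  }

  # coarse rotation-hypothesis scan
  hyps <- list()
  ones <- matrix(1, nrow(mv), ncol(mv))
  for (a in rotation_search) {
    R <- rotation_about_center(a, dim(mv))
    mv_a <- if (a == 0) mv else warp_image(mv, R, out_shape = dim(mv))
    kp_a <- tryCatch(detect_keypoints(mv_a, config), error = function(e) NULL)
    if (!is.null(kp_a) && a != 0) {
      valid_a <- warp_image(ones, R, out_shape = dim(mv),
                            interpolation = "nearest")
      kp_a <- filter_fill_keypoints(kp_a, valid_a, config$window)
    }
    if (is.null(kp_a) || nrow(kp_a) < 3L) next
    strong <- FALSE
    for (flip in polarities) {
      m <- match_one(kp_a, flip)
      if (is.null(m)) next
      hyps[[length(hyps) + 1L]] <- list(
        angle = a, R = R, kp_moving = kp_a, flip = flip,
        ratio = m$ratio, score = m$score, n_pairs = m$n_pairs
      )
      if (m$score >= 30L && m$score >= 0.6 * m$n_pairs) strong <- TRUE
    }
    if (strong) break
  }
  if (length(hyps) == 0L) {
    stop_insufficient_matches(
      "no consistent match set found in any rotation hypothesis or polarity"
    )
  }
  hyps <- hyps[order(-vapply(hyps, function(h) h$score, integer(1L)))]

  # full perspective-consistency filter on hypotheses in score order
  best <- NULL
  for (h in hyps) {
    gf <- tryCatch(
      geometry_filter(h$ratio, h$kp_moving, kp_fixed, threshold = threshold,
                      iterations = iterations, seed = seed),
      poolreg_insufficient_matches_error = function(e) NULL,
      poolreg_degenerate_geometry_error = function(e) NULL
    )
    if (!is.null(gf) && nrow(gf) >= 3L) {
      best <- h
      best$geometry <- gf
      break
    }
  }
  if (is.null(best)) {
    stop_degenerate_geometry(
      "perspective-consistency filtering failed for every rotation hypothesis"
    )
  }

  M_res <- estimate_affine(best$geometry, best$kp_moving, kp_fixed)
  M <- affine_transform(unclass(M_res) %*% unclass(best$R))
  # last_fit: the most recent local fit (transform, pairs, keypoints in
  # the frame the fit was made in) — used for the reported residual
  last_fit <- list(M = M_res, pairs = best$geometry, kp = best$kp_moving)
  refined <- guided_refit(M_res, best$kp_moving, kp_fixed, gate = threshold)
  matches_refined <- refined$pairs
  if (!is.null(refined$pairs)) {
    M <- affine_transform(unclass(refined$M) %*% unclass(best$R))
    last_fit <- list(M = refined$M, pairs = refined$pairs, kp = best$kp_moving)
  }

  # warp-refinement passes: re-register the warped moving image and
  # compose the residual
  # refinement iterates from the current transform, but every candidate
  # (including the coarse fit itself) is scored by the pairing-independent
  # mutual-information criterion and the best-scoring transform wins
  n_refine <- max(0L, as.integer(refine))
  best_state <- NULL
  if (n_refine > 0L) {
    valid0 <- warp_image(ones, M, out_shape = dim(fx), interpolation = "nearest") > 0.5
    best_state <- list(M = M, score = mi_score(fx, warp_image(mv, M, dim(fx)), valid0),
                       fit = last_fit)
  }
  for (pass in seq_len(n_refine)) {
    mv_w <- warp_image(mv, M, out_shape = dim(fx))
    kp_w <- tryCatch(detect_keypoints(mv_w, config), error = function(e) NULL)
    if (!is.null(kp_w)) {
      valid_w <- warp_image(ones, M, out_shape = dim(fx),
                            interpolation = "nearest")
      kp_w <- filter_fill_keypoints(kp_w, valid_w, config$window)
    }
    if (is.null(kp_w) || nrow(kp_w) < 3L) break
    m <- match_one(kp_w, best$flip)
    if (is.null(m)) break
    src <- cbind(kp_w$u[m$ratio$moving], kp_w$v[m$ratio$moving])
    dst <- cbind(kp_fixed$u[m$ratio$fixed], kp_fixed$v[m$ratio$fixed])
    inl <- affine_ransac(src, dst, threshold = threshold,
                         iterations = 300L, seed = seed)
    if (length(inl) < 3L) break
    dM <- tryCatch(
      estimate_affine(m$ratio[inl, , drop = FALSE], kp_w, kp_fixed),
      error = function(e) NULL
    )
    if (is.null(dM)) break
    # early passes accept a wider spatial gate so the re-match covers the
    # whole frame before the fit is tightened
    gate <- if (pass < n_refine) 2 * threshold else threshold
    g <- guided_refit(dM, kp_w, kp_fixed, gate = gate)
    if (is.null(g$pairs)) break
    # subpixel polish of the fixed-side correspondence positions, with
    # correlation verification: pairs whose local patches cannot be
    # aligned (low NCC peak) are dropped before the final fit
    src_g <- cbind(kp_w$u[g$pairs$moving], kp_w$v[g$pairs$moving])
    dst_g <- cbind(kp_fixed$u[g$pairs$fixed], kp_fixed$v[g$pairs$fixed])
    nr <- ncc_refine(fx, mv_w, src_g, dst_g, flip = best$flip)
    keep_g <- is.na(nr$score) | nr$score >= 0.2
    if (sum(keep_g) >= 3L) {
      pairs_g <- g$pairs[keep_g, , drop = FALSE]
      M_loc <- ls_affine_trimmed(src_g[keep_g, , drop = FALSE],
                                 nr$dst[keep_g, , drop = FALSE]) %||% g$M
    } else {
      pairs_g <- g$pairs
      M_loc <- ls_affine_trimmed(src_g, nr$dst) %||% g$M
    }
    M <- affine_transform(unclass(M_loc) %*% unclass(M))
    valid_n <- warp_image(ones, M, out_shape = dim(fx),
                          interpolation = "nearest") > 0.5
    score <- mi_score(fx, warp_image(mv, M, dim(fx)), valid_n)
    if (score > best_state$score) {
      best_state <- list(M = M, score = score,
                         fit = list(M = M_loc, pairs = pairs_g, kp = kp_w))
    }
  }
  if (!is.null(best_state)) {
    M <- best_state$M
    if (!is.null(best_state$fit$pairs)) {
      matches_refined <- best_state$fit$pairs
      last_fit <- best_state$fit
    }
  }

  res <- cbind(kp_fixed$u[last_fit$pairs$fixed], kp_fixed$v[last_fit$pairs$fixed]) -
    transform_points(last_fit$M,
                     cbind(last_fit$kp$u[last_fit$pairs$moving],
                           last_fit$kp$v[last_fit$pairs$moving]))
  norms <- sqrt(rowSums(res^2))
  perr <- sum(norms)

  warped <- warp_image(moving, M, out_shape = dim(fixed))

  structure(
    list(
      transform = M,
      warped = warped,
      keypoints_fixed = kp_fixed,
      keypoints_moving = best$kp_moving,
      matches_ratio = best$ratio,
      matches_geometry = best$geometry,
      matches_refined = matches_refined,
      projection_error = perr,
      rmse = sqrt(mean(norms^2)),
      polarity = if (best$flip) "inverted" else "direct",
      coarse_rotation = best$angle,
      rotate_moving = as.integer(rotate_moving),
      config = config,
      params = list(ratio = ratio, threshold = threshold,
                    iterations = iterations, seed = seed,
                    preprocess = preprocess, clip_quantile = clip_quantile,
                    rotation_search = rotation_search, refine = refine)
    ),
    class = "registration"
  )
}

#' @export
print.registration <- function(x, ...) {
  p <- affine_params(x$transform)
  cat(sprintf(
    paste0("<registration> %d/%d keypoints (fixed/moving), %d ratio-test pairs, ",
           "%d inliers, %d refined pairs (%s polarity, coarse rotation %g deg)\n",
           "  rotation %.2f deg, scale (%.3f, %.3f), translation (%.1f, %.1f), ",
           "mean residual %.3f px\n"),
    nrow(x$keypoints_fixed), nrow(x$keypoints_moving),
    nrow(x$matches_ratio), nrow(x$matches_geometry),
    if (is.null(x$matches_refined)) 0L else nrow(x$matches_refined),
    x$polarity, x$coarse_rotation,
    p$rotation, p$scale_x, p$scale_y, p$tx, p$ty, x$rmse
  ))
  invisible(x)
}

#' Tidy a registration fit
#'
#' @param x A `registration` object.
#' @param ... Unused.
#' @return A tibble of pose parameters (`term`, `estimate`).
#' @export
tidy.registration <- function(x, ...) {
  tidy(x$transform)
}

#' One-row summary of a registration fit
#'
#' @param x A `registration` object.
#' @param ... Unused.
#' @return A one-row tibble with keypoint/match counts, the residual
#'   projection error and mean residual, and the chosen descriptor
#'   polarity and coarse rotation.
#' @export
glance.registration <- function(x, ...) {
  tibble::tibble(
    n_keypoints_fixed = nrow(x$keypoints_fixed),
    n_keypoints_moving = nrow(x$keypoints_moving),
    n_ratio = nrow(x$matches_ratio),
    n_inliers = nrow(x$matches_geometry),
    n_refined = if (is.null(x$matches_refined)) 0L else nrow(x$matches_refined),
    projection_error = x$projection_error,
    rmse = x$rmse,
    polarity = x$polarity,
    coarse_rotation = x$coarse_rotation
  )
}

#' Write registration artifacts
#'
#' Writes the warped image (16-bit TIFF), the transform JSON (with config
#' echo and per-stage match counts) and the matched-pair CSV.
#'
#' @param reg A `registration` object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return `dir`, invisibly.
#' @export
write_registration <- function(reg, dir, prefix = "registration") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image(reg$warped, file.path(dir, paste0(prefix, "_warped.tif")))
  write_transform_json(
    reg$transform, file.path(dir, paste0(prefix, "_transform.json")),
    extra = list(
      config = unclass(reg$config),
      params = reg$params,
      polarity = reg$polarity,
      coarse_rotation = reg$coarse_rotation,
      rotate_moving = reg$rotate_moving,
      n_keypoints = c(fixed = nrow(reg$keypoints_fixed),
                      moving = nrow(reg$keypoints_moving)),
      n_matches = c(ratio = nrow(reg$matches_ratio),
                    geometry = nrow(reg$matches_geometry)),
      projection_error = reg$projection_error,
      rmse = reg$rmse
    )
  )
  m <- reg$matches_geometry
  write.csv(
    data.frame(
      moving_u = reg$keypoints_moving$u[m$moving],
      moving_v = reg$keypoints_moving$v[m$moving],
      fixed_u = reg$keypoints_fixed$u[m$fixed],
      fixed_v = reg$keypoints_fixed$v[m$fixed],
      distance = m$distance
    ),
    file.path(dir, paste0(prefix, "_matches.csv")), row.names = FALSE
  )
  invisible(dir)
}
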