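# 2D affine transforms as 3x3 homogeneous matrices with last row
# (0, 0, 1), acting on column vectors (u, v, 1)^T of 0-based pixel
# coordinates: fixed = M %*% moving. (The row-vector convention p . M
# seen elsewhere is the transpose of this; both minimize the same
# projection error.)

#' Construct an affine transform
#'
#' @param matrix A 3x3 homogeneous matrix with last row (0, 0, 1), or a
#'   2x3 matrix (linear part and translation) which is completed.
#' @return An `affine_transform` (3x3 matrix).
#' @export
affine_transform <- function(matrix = diag(3)) {
  if (is.matrix(matrix) && all(dim(matrix) == c(2L, 3L))) {
    matrix <- rbind(matrix, c(0, 0, 1))
  }
  if (!is.matrix(matrix) || !all(dim(matrix) == c(3L, 3L))) {
    stop_validation("`matrix` must be 3x3 (or 2x3)")
  }
  if (!isTRUE(all.equal(matrix[3L, ], c(0, 0, 1)))) {
    stop_validation("last row of an affine matrix must be (0, 0, 1)")
  }
  matrix[3L, ] <- c(0, 0, 1)
  structure(matrix, class = c("affine_transform", "matrix"))
}

#' Build an affine transform from pose parameters
#'
#' Composes scale, shear and rotation about a centre point, followed by a
#' translation: `M = T(translation) . C . R(rotation) . Sh(shear) .
#' S(scale) . C^-1` where `C` shifts the origin to `center`.
#'
#' @param rotation Rotation angle in degrees (counter-clockwise in (u, v)
#'   coordinates).
#' @param scale Isotropic scale factor (> 0), or length-2 `(sx, sy)`.
#' @param translation Length-2 translation `(tx, ty)` in pixels.
#' @param shear Horizontal shear coefficient.
#' @param center Length-2 centre of rotation/scaling `(cu, cv)`.
#' @return An `affine_transform`.
#' @export
make_affine <- function(rotation = 0, scale = 1, translation = c(0, 0),
                        shear = 0, center = c(0, 0)) {
  if (any(scale <= 0)) stop_validation("`scale` must be positive")
  if (length(scale) == 1L) scale <- c(scale, scale)
  th <- rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3L, 3L)
  S <- diag(c(scale, 1))
  Sh <- diag(3)
  Sh[1L, 2L] <- shear
  C <- diag(3)
  C[1:2, 3L] <- center
  Ci <- diag(3)
  Ci[1:2, 3L] <- -center
  Tt <- diag(3)
  Tt[1:2, 3L] <- translation
  affine_transform(Tt %*% C %*% R %*% Sh %*% S %*% Ci)
}

#' Apply an affine transform to points
#'
#' @param M An `affine_transform`.
#' @param pts An n x 2 matrix (or length-2 vector) of `(u, v)` points.
#' @return An n x 2 matrix of transformed points.
#' @export
transform_points <- function(M, pts) {
  pts <- rbind_points(pts)
  out <- cbind(pts, 1) %*% t(unclass(M))
  out[, 1:2, drop = FALSE]
}

rbind_points <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 2L, byrow = TRUE)
  storage.mode(pts) <- "double"
  pts
}

#' Invert an affine transform
#'
#' @param M An `affine_transform`.
#' @return The inverse `affine_transform`.
#' @export
invert_affine <- function(M) {
  A <- unclass(M)[1:2, 1:2]
  if (abs(det(A)) < .Machine$double.eps) {
    stop_validation("transform is singular and cannot be inverted")
  }
  affine_transform(solve(unclass(M)))
}

#' Estimate the affine transform from matched keypoints
#'
#' Least-squares fit of the 2D affine map taking moving keypoint
#' locations to fixed keypoint locations over the matched pairs,
#' minimizing the summed Euclidean projection error. Solved by QR
#' (orthogonal) decomposition rather than normal equations for stability
#' on near-collinear configurations.
#'
#' @param matches A match tibble with `moving` and `fixed` index columns
#'   (see [ratio_test_match()] / [geometry_filter()]).
#' @param moving,fixed `keypoints` tibbles the indices refer to.
#' @return An `affine_transform` with attributes `projection_error` (the
#'   summed residual), `rmse` and `n_pairs`.
#' @export
estimate_affine <- function(matches, moving, fixed) {
  if (nrow(matches) < 3L) {
    stop_degenerate_geometry("need at least 3 matched pairs for an affine fit")
  }
  src <- cbind(moving$u[matches$moving], moving$v[matches$moving])
  dst <- cbind(fixed$u[matches$fixed], fixed$v[matches$fixed])
  X <- cbind(src, 1)
  qx <- qr(X)
  if (qx$rank < 3L) {
    stop_degenerate_geometry("matched moving points are collinear; affine is rank-deficient")
  }
  B <- qr.coef(qx, dst)   # 3 x 2: columns are (a, b, t) for u' and v'
  M <- affine_transform(rbind(t(B)[, c(1L, 2L, 3L)], c(0, 0, 1)))
  res <- dst - transform_points(M, src)
  norms <- sqrt(rowSums(res^2))
  attr(M, "projection_error") <- sum(norms)
  attr(M, "rmse") <- sqrt(mean(norms^2))
  attr(M, "n_pairs") <- nrow(matches)
  M
}

#' Summed projection error of a transform over matched pairs
#'
#' Sum over matched pairs of the Euclidean distance between each fixed
#' keypoint and the transformed moving keypoint. Zero iff every pair maps
#' exactly.
#'
#' @inheritParams estimate_affine
#' @param M An `affine_transform`.
#' @return Non-negative scalar.
#' @export
projection_error <- function(M, matches, moving, fixed) {
  if (nrow(matches) < 1L) stop_validation("match set is empty")
  src <- cbind(moving$u[matches$moving], moving$v[matches$moving])
  dst <- cbind(fixed$u[matches$fixed], fixed$v[matches$fixed])
  res <- dst - transform_points(M, src)
  sum(sqrt(rowSums(res^2)))
}

# clamped bilinear sample of img at 0-based coords (x = col, y = row);
# positions outside the image get `fill`
bilinear_sample <- function(img, x, y, fill = 0) {
  h <- nrow(img)
  w <- ncol(img)
  inside <- x >= 0 & x <= w - 1 & y >= 0 & y <= h - 1
  x0 <- floor(x)
  y0 <- floor(y)
  fx <- x - x0
  fy <- y - y0
  cl <- function(r, cc) {
    r <- pmin(pmax(r, 0), h - 1)
    cc <- pmin(pmax(cc, 0), w - 1)
    img[cbind(r + 1, cc + 1)]
  }
  val <- (1 - fx) * (1 - fy) * cl(y0, x0) +
    fx * (1 - fy) * cl(y0, x0 + 1) +
    (1 - fx) * fy * cl(y0 + 1, x0) +
    fx * fy * cl(y0 + 1, x0 + 1)
  val[!inside] <- fill
  val
}

nearest_sample <- function(img, x, y, fill = 0) {
  h <- nrow(img)
  w <- ncol(img)
  xr <- round(x)
  yr <- round(y)
  inside <- xr >= 0 & xr <= w - 1 & yr >= 0 & yr <= h - 1
  val <- rep(fill, length(x))
  val[inside] <- img[cbind(yr[inside] + 1, xr[inside] + 1)]
  val
}

#' Warp a moving image into the fixed frame
#'
#' Resamples by inverse mapping: each output pixel `(u, v)` is filled
#' from the moving image at `M^-1 (u, v)`. Bilinear interpolation by
#' default; use `"nearest"` for binary masks so they stay binary.
#'
#' @param moving Numeric intensity matrix.
#' @param M The `affine_transform` taking moving coordinates to fixed
#'   coordinates (must be invertible).
#' @param out_shape Output `(rows, cols)`; defaults to `dim(moving)`.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @param fill Value for pixels that map outside the moving image.
#' @return The warped image matrix of shape `out_shape`.
#' @export
warp_image <- function(moving, M, out_shape = dim(moving),
                       interpolation = c("bilinear", "nearest"), fill = 0) {
  moving <- as_image(moving)
  interpolation <- match.arg(interpolation)
  Mi <- invert_affine(M)
  h <- out_shape[1L]
  w <- out_shape[2L]
  u <- rep(0:(w - 1L), each = h)
  v <- rep(0:(h - 1L), times = w)
  src <- transform_points(Mi, cbind(u, v))
  vals <- if (interpolation == "bilinear") {
    bilinear_sample(moving, src[, 1L], src[, 2L], fill = fill)
  } else {
    nearest_sample(moving, src[, 1L], src[, 2L], fill = fill)
  }
  matrix(vals, nrow = h, ncol = w)
}

#' Decompose an affine transform into pose parameters
#'
#' Returns rotation (degrees), per-axis scales, shear and translation of
#' the linear part via the standard QR-like decomposition
#' `A = R(theta) . Shear . Scale`.
#'
#' @param M An `affine_transform`.
#' @return A named list.
#' @export
affine_params <- function(M) {
  A <- unclass(M)[1:2, 1:2]
  sx <- sqrt(A[1L, 1L]^2 + A[2L, 1L]^2)
  theta <- atan2(A[2L, 1L], A[1L, 1L])
  msy <- A[1L, 2L] * cos(theta) + A[2L, 2L] * sin(theta)
  sy_ <- A[2L, 2L] * cos(theta) - A[1L, 2L] * sin(theta)
  list(
    rotation = theta * 180 / pi,
    scale_x = sx,
    scale_y = sy_,
    shear = if (sy_ != 0) msy / sy_ else NA_real_,
    tx = unclass(M)[1L, 3L],
    ty = unclass(M)[2L, 3L]
  )
}

#' @export
print.affine_transform <- function(x, ...) {
  p <- affine_params(x)
  cat(sprintf(
    "<affine_transform> rotation %.3f deg, scale (%.4f, %.4f), shear %.4f, translation (%.2f, %.2f)\n",
    p$rotation, p$scale_x, p$scale_y, p$shear, p$tx, p$ty
  ))
  print(unclass(x))
  invisible(x)
}

#' Tidy an affine transform
#'
#' @param x An `affine_transform`.
#' @param ... Unused.
#' @return A tibble with one row per pose parameter (`term`, `estimate`).
#' @export
tidy.affine_transform <- function(x, ...) {
  p <- affine_params(x)
  tibble::tibble(term = names(p), estimate = unlist(p, use.names = FALSE))
}

#' Serialize a transform (and provenance) to JSON
#'
#' @param M An `affine_transform`.
#' @param path Output path.
#' @param extra Named list of extra provenance fields (config echo, match
#'   counts, seed, ...).
#' @return `path`, invisibly.
#' @export
write_transform_json <- function(M, path, extra = list()) {
  obj <- c(list(
    matrix = lapply(seq_len(3L), function(i) unname(unclass(M)[i, ])),
    package = "poolreg",
    version = as.character(utils::packageVersion("poolreg"))
  ), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a transform from JSON
#'
#' @param path Path written by [write_transform_json()].
#' @return An `affine_transform`.
#' @export
read_transform_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- obj$matrix
  if (!is.matrix(m)) m <- matrix(unlist(m), nrow = 3L, byrow = TRUE)
  affine_transform(m)
}
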