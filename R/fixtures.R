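# Synthetic modality-shifted image pairs with known ground-truth affine
# transforms, so every pipeline stage is testable without external data.
# The fixed image is a smooth blob "tissue" plus band-limited texture;
# the moving image samples the fixed content through the inverse of the
# ground-truth transform, then passes through a monotone intensity remap
# (simulating a modality change), additive Gaussian noise and optional
# salt hotspots (exercising hotspot clipping).

#' Fixture generator configuration
#'
#' @param seed Integer RNG seed; generation is bit-reproducible for a
#'   fixed seed.
#' @param shape Image shape `(rows, cols)`, at least 64 x 64.
#' @param n_blobs Number of Gaussian tissue blobs.
#' @param texture_scale Relative amplitude of the band-limited texture
#'   component (0 = blobs only).
#' @param rotation,scale,translation,shear Ground-truth transform
#'   parameters (degrees, factor, pixels `(tx, ty)`, coefficient); the
#'   transform scales and shears, rotates about the image centre, then
#'   translates.
#' @param intensity_remap One of `"identity"`, `"gamma"` (power 0.6),
#'   `"inverted"` (1 - x) or `"piecewise"` (increasing 3-segment linear
#'   map); all are monotone so structure is preserved while absolute
#'   intensities differ across the simulated modalities.
#' @param noise_sigma Additive Gaussian noise standard deviation as a
#'   fraction of the moving image's dynamic range.
#' @param hotspot_fraction Fraction of moving pixels replaced by bright
#'   salt hotspots (3x the maximum intensity).
#' @param mask Also generate aligned binary tissue masks.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(seed = 1L, shape = c(256L, 256L), n_blobs = 10L,
                           texture_scale = 0.3,
                           rotation = 0, scale = 1, translation = c(0, 0),
                           shear = 0,
                           intensity_remap = c("identity", "gamma",
                                               "inverted", "piecewise"),
                           noise_sigma = 0, hotspot_fraction = 0,
                           mask = TRUE) {
  if (any(shape < 64L)) stop_validation("`shape` must be at least 64 x 64")
  if (noise_sigma < 0) stop_validation("`noise_sigma` must be >= 0")
  if (scale <= 0) stop_validation("`scale` must be positive")
  structure(
    list(seed = as.integer(seed), shape = as.integer(shape),
         n_blobs = as.integer(n_blobs), texture_scale = texture_scale,
         rotation = rotation, scale = scale,
         translation = as.numeric(translation), shear = shear,
         intensity_remap = match.arg(intensity_remap),
         noise_sigma = noise_sigma, hotspot_fraction = hotspot_fraction,
         mask = isTRUE(mask)),
    class = "fixture_config"
  )
}

apply_remap <- function(x, method) {
  switch(method,
    identity = x,
    gamma = x^0.6,
    inverted = 1 - x,
    piecewise = {
      # increasing 3-segment linear map: [0,.3]->[0,.15],
      # [.3,.6]->[.15,.75], [.6,1]->[.75,1]
      ifelse(x < 0.3, 0.5 * x,
             ifelse(x < 0.6, 0.15 + 2 * (x - 0.3), 0.75 + 0.625 * (x - 0.6)))
    },
    stop_config(sprintf("unknown intensity remap '%s'", method))
  )
}

#' Generate a modality-shifted fixture pair
#'
#' The ground-truth transform `truth` maps moving-image coordinates into
#' fixed-image coordinates, so registering `moving` onto `fixed` should
#' recover it. With the identity transform, identity remap and zero
#' noise, `moving` equals `fixed` pixel-exactly.
#'
#' @param config A [fixture_config()].
#' @return A `fixture_pair` list: `fixed`, `moving` (intensity matrices),
#'   `truth` (the `affine_transform`), `fixed_mask`, `moving_mask`
#'   (logical matrices or `NULL`), and the `config`.
#' @export
generate_pair <- function(config = fixture_config()) {
  if (!inherits(config, "fixture_config")) stop_validation("need a fixture_config")
  h <- config$shape[1L]
  w <- config$shape[2L]
  withr::with_seed(config$seed, {
    Y <- matrix(rep(0:(h - 1L), times = w), h, w)   # v (row) coordinate
    X <- matrix(rep(0:(w - 1L), each = h), h, w)    # u (col) coordinate

    blobs <- matrix(0, h, w)
    for (k in seq_len(config$n_blobs)) {
      cx <- runif(1L, 0.15 * w, 0.85 * w)
      cy <- runif(1L, 0.15 * h, 0.85 * h)
      sg <- runif(1L, 0.04, 0.12) * min(h, w)
      amp <- runif(1L, 0.5, 1)
      blobs <- blobs + amp * exp(-((X - cx)^2 + (Y - cy)^2) / (2 * sg^2))
    }

    # band-limited texture: coarse white noise bilinearly upsampled
    gh <- max(2L, h %/% 8L)
    gw <- max(2L, w %/% 8L)
    coarse <- matrix(runif(gh * gw), gh, gw)
    texture <- matrix(
      bilinear_sample(coarse,
                      as.vector(X) / (w - 1) * (gw - 1),
                      as.vector(Y) / (h - 1) * (gh - 1)),
      h, w
    )

    fixed <- normalize_intensity(blobs + config$texture_scale * texture)

    truth <- make_affine(
      rotation = config$rotation, scale = config$scale,
      translation = config$translation, shear = config$shear,
      center = c((w - 1) / 2, (h - 1) / 2)
    )

    # moving(p) = fixed(truth(p)): sample fixed content through truth
    src <- transform_points(truth, cbind(as.vector(X), as.vector(Y)))
    moving <- matrix(bilinear_sample(fixed, src[, 1L], src[, 2L]), h, w)
    moving <- apply_remap(moving, config$intensity_remap)

    if (config$noise_sigma > 0) {
      moving <- moving + rnorm(length(moving),
                               sd = config$noise_sigma * diff(range(moving)))
    }
    if (config$hotspot_fraction > 0) {
      n_hot <- max(1L, round(config$hotspot_fraction * length(moving)))
      idx <- sample.int(length(moving), n_hot)
      moving[idx] <- 3 * max(moving)
    }

    fixed_mask <- moving_mask <- NULL
    if (config$mask) {
      fixed_mask <- blobs > 0.2 * max(blobs)
      moving_mask <- matrix(
        nearest_sample(fixed_mask + 0, src[, 1L], src[, 2L]) > 0.5, h, w
      )
    }

    structure(
      list(fixed = fixed, moving = moving, truth = truth,
           fixed_mask = fixed_mask, moving_mask = moving_mask,
           config = config),
      class = "fixture_pair"
    )
  })
}

#' Write a fixture pair to disk
#'
#' Writes the fixed/moving images as 16-bit TIFF, masks as PNG, and the
#' ground-truth transform (with the generating parameters) as JSON.
#'
#' @param pair A `fixture_pair`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return The directory, invisibly.
#' @export
write_fixture_pair <- function(pair, dir, prefix = "case") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_image(pair$fixed, file.path(dir, paste0(prefix, "_fixed.tif")))
  write_image(pair$moving, file.path(dir, paste0(prefix, "_moving.tif")))
  if (!is.null(pair$fixed_mask)) {
    write_image(pair$fixed_mask + 0, file.path(dir, paste0(prefix, "_fixed_mask.png")),
                normalize = FALSE)
    write_image(pair$moving_mask + 0, file.path(dir, paste0(prefix, "_moving_mask.png")),
                normalize = FALSE)
  }
  write_transform_json(pair$truth, file.path(dir, paste0(prefix, "_truth.json")),
                       extra = list(fixture_config = unclass(pair$config)))
  invisible(dir)
}

#' Maximum corner displacement between two transforms
#'
#' Maximum Euclidean displacement, over the four frame corners, between
#' the two transforms' images of the corner — the per-case registration
#' error measure used by [recovery_suite()].
#'
#' @param M,truth `affine_transform`s to compare.
#' @param shape Frame shape `(rows, cols)`.
#' @return Non-negative scalar (pixels).
#' @export
corner_error <- function(M, truth, shape) {
  h <- shape[1L]
  w <- shape[2L]
  corners <- rbind(c(0, 0), c(w - 1, 0), c(0, h - 1), c(w - 1, h - 1))
  d <- transform_points(M, corners) - transform_points(truth, corners)
  max(sqrt(rowSums(d^2)))
}

#' Transform-recovery benchmark suite
#'
#' Runs the full registration pipeline on `n_cases` generated fixture
#' pairs spanning rotations up to 30 degrees, scales 0.9-1.1,
#' translations up to 15% of the frame, the four intensity remaps, and
#' noise levels 0 / 2% / 5% of the dynamic range (cycled across cases).
#'
#' @param n_cases Number of cases (default 20).
#' @param seed Suite seed; case seeds and transform draws derive from it.
#' @param shape Frame shape.
#' @param config Pipeline [pyramid_config()].
#' @param verbose Print per-case progress.
#' @return A tibble with one row per case: the drawn transform
#'   parameters, `corner_error` (max corner displacement of the recovered
#'   vs. true transform, pixels; `Inf` when registration failed),
#'   `dice_before` / `dice_after` (mask overlap before and after applying
#'   the recovered transform), and match counts per stage.
#' @export
recovery_suite <- function(n_cases = 20L, seed = 0L, shape = c(256L, 256L),
                           config = pyramid_config(), verbose = FALSE) {
  if (n_cases < 1L) stop_validation("`n_cases` must be >= 1")
  remaps <- c("identity", "gamma", "inverted", "piecewise")
  noises <- c(0, 0.02, 0.05)
  params <- withr::with_seed(seed, {
    tibble::tibble(
      case = seq_len(n_cases),
      rotation = runif(n_cases, -30, 30),
      scale = runif(n_cases, 0.9, 1.1),
      tx = runif(n_cases, -0.15, 0.15) * shape[2L],
      ty = runif(n_cases, -0.15, 0.15) * shape[1L],
      remap = remaps[(seq_len(n_cases) - 1L) %% 4L + 1L],
      noise = noises[(seq_len(n_cases) - 1L) %% 3L + 1L],
      case_seed = sample.int(2^20, n_cases)
    )
  })
  res <- purrr::pmap(params, function(case, rotation, scale, tx, ty, remap,
                                      noise, case_seed) {
    cfg <- fixture_config(
      seed = case_seed, shape = shape, rotation = rotation, scale = scale,
      translation = c(tx, ty), intensity_remap = remap, noise_sigma = noise,
      hotspot_fraction = if (noise > 0) 2e-4 else 0
    )
    pair <- generate_pair(cfg)
    reg <- tryCatch(
      register_images(pair$fixed, pair$moving, config = config),
      error = function(e) NULL
    )
    if (is.null(reg)) {
      out <- tibble::tibble(
        corner_error = Inf, dice_before = NA_real_, dice_after = NA_real_,
        n_ratio = NA_integer_, n_inliers = NA_integer_,
        polarity = NA_character_
      )
    } else {
      warped_mask <- warp_image(pair$moving_mask + 0, reg$transform,
                                out_shape = dim(pair$fixed),
                                interpolation = "nearest") > 0.5
      out <- tibble::tibble(
        corner_error = corner_error(reg$transform, pair$truth, shape),
        dice_before = dice(pair$fixed_mask, pair$moving_mask),
        dice_after = dice(pair$fixed_mask, warped_mask),
        n_ratio = nrow(reg$matches_ratio),
        n_inliers = nrow(reg$matches_geometry),
        polarity = reg$polarity
      )
    }
    if (verbose) {
      message(sprintf(
        "case %2d: rot %+6.1f scale %.3f remap %-9s noise %.2f -> corner %.2f px",
        case, rotation, scale, remap, noise, out$corner_error
      ))
    }
    out
  })
  dplyr::bind_cols(params, dplyr::bind_rows(res))
}
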