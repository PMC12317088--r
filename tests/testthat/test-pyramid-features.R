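test_that("descriptor has length 2^L - 2 and matches the scalar-loop oracle", {
  withr::with_seed(10, {
    img <- matrix(runif(64 * 64), 64, 64)
    for (L in 2:4) {
      cfg <- pyramid_config(window = 16L, layers = L, min_distance = 4)
      d <- descriptor_at(img, c(20L, 24L), cfg)
      expect_length(d, 2^L - 2L)
      expect_equal(d, oracle_descriptor(img, 20, 24, 16, L), tolerance = 1e-12)
    }
  })
})

test_that("the 4x4 window with values 1..16 reproduces hand-computed block means", {
  img <- matrix(0, 12, 12)
  img[5:8, 5:8] <- matrix(1:16, 4, 4, byrow = TRUE)
  cfg <- pyramid_config(window = 4L, layers = 3L, min_distance = 2)
  # center so the window is exactly rows/cols 5:8 (0-based center (6, 6))
  d <- descriptor_at(img, c(6L, 6L), cfg)
  expect_equal(d, oracle_descriptor(img, 6, 6, 4, 3), tolerance = 1e-12)
  # layer 2 halves of 1..16 row-major: left mean 7.5, right mean 9.5;
  # whole-window mean 8.5 is subtracted
  expect_equal(d[1:2], c(-1, 1))
})

test_that("descriptor is exactly invariant to constant offsets and zero on flats", {
  cfg <- pyramid_config(window = 8L, layers = 3L, min_distance = 2)
  flat <- matrix(4.2, 20, 20)
  expect_identical(descriptor_at(flat, c(10L, 10L), cfg),
                   rep(0, 2^3 - 2))
  withr::with_seed(11, {
    for (i in 1:10) {
      img <- matrix(runif(400), 20, 20)
      c0 <- runif(1, -50, 50)
      expect_lt(max(abs(descriptor_at(img, c(10L, 10L), cfg) -
                          descriptor_at(img + c0, c(10L, 10L), cfg))), 1e-12)
    }
  })
})

test_that("out-of-bounds windows raise a validation error", {
  cfg <- pyramid_config(window = 8L, layers = 2L, min_distance = 2)
  img <- matrix(0, 10, 10)
  expect_error(descriptor_at(img, c(1L, 5L), cfg),
               class = "poolreg_validation_error")
  expect_error(magnitude_map(matrix(0, 6, 6), cfg),
               class = "poolreg_validation_error")
})

test_that("averaging damps i.i.d. pixel noise in the descriptor", {
  cfg <- pyramid_config(window = 16L, layers = 4L, min_distance = 4)
  sigma <- 0.5
  withr::with_seed(12, {
    pert <- replicate(100, {
      img <- matrix(runif(32 * 32), 32, 32)
      noisy <- img + matrix(rnorm(32 * 32, sd = sigma), 32, 32)
      d0 <- descriptor_at(img, c(16L, 16L), cfg)
      d1 <- descriptor_at(noisy, c(16L, 16L), cfg)
      sqrt(mean((d1 - d0)^2))
    })
  })
  expect_lt(mean(pert), sigma)
})

test_that("magnitude map equals pointwise descriptor norms and is deterministic", {
  withr::with_seed(13, img <- matrix(runif(50 * 40), 50, 40))
  cfg <- pyramid_config(window = 12L, layers = 3L, min_distance = 4)
  map <- magnitude_map(img, cfg)
  expect_equal(dim(map$values), dim(img))
  bw <- map$border_width
  expect_equal(bw, as.integer(ceiling(cfg$window / 2)))
  # border exclusion zone is zero
  expect_true(all(map$values[seq_len(bw), ] == 0))
  expect_true(all(map$values[, seq_len(bw)] == 0))
  # interior values match per-pixel recomputation
  for (pt in list(c(10L, 12L), c(20L, 30L), c(33L, 8L))) {
    d <- descriptor_at(img, pt, cfg)
    expect_equal(map$values[pt[2L] + 1L, pt[1L] + 1L], sqrt(sum(d^2)),
                 tolerance = 1e-12)
  }
  expect_identical(magnitude_map(img, cfg)$values, map$values)
  # constant image: all-zero valid region
  expect_true(all(magnitude_map(matrix(1, 40, 40), cfg)$values == 0))
})

test_that("the magnitude map peaks near the edge of an isolated blob", {
  # a smooth Gaussian blob: intensity variation is maximal around its
  # flank, not at the flat top or the flat background
  h <- 64L
  y <- matrix(rep(0:(h - 1L), times = h), h, h)
  x <- t(y)
  img <- exp(-((x - 32)^2 + (y - 32)^2) / (2 * 8^2))
  cfg <- pyramid_config(window = 16L, layers = 3L, min_distance = 4)
  map <- magnitude_map(img, cfg)
  peak <- which(map$values == max(map$values), arr.ind = TRUE)[1L, ]
  r <- sqrt((peak[1L] - 1L - 32)^2 + (peak[2L] - 1L - 32)^2)
  expect_lt(r, 8 + cfg$window / 2)   # within a window radius of the flank
  expect_gt(max(map$values), 0)
})

test_that("keypoint selection respects distance regulation and the cap", {
  cfg <- pyramid_config(window = 8L, layers = 3L, min_distance = 5,
                        max_features = 10L)
  withr::with_seed(14, {
    for (i in 1:5) {
      img <- matrix(runif(60 * 60), 60, 60)
      kp <- detect_keypoints(img, cfg)
      expect_lte(nrow(kp), 10L)
      expect_gt(nrow(kp), 1L)
      dmin <- min(dist(cbind(kp$u, kp$v)))
      expect_gt(dmin, cfg$min_distance)
      # magnitudes non-increasing in selection order
      expect_true(all(diff(kp$magnitude) <= 1e-12))
      # loc inside the valid region
      bw <- ceiling(cfg$window / 2)
      expect_true(all(kp$u >= bw & kp$u < 60 - bw))
      expect_true(all(kp$v >= bw & kp$v < 60 - bw))
      # magnitude equals the descriptor norm
      expect_equal(kp$magnitude,
                   vapply(kp$descriptor, function(d) sqrt(sum(d^2)), numeric(1)))
    }
  })
})

test_that("selection takes single peaks and breaks ties deterministically", {
  cfg <- pyramid_config(window = 8L, layers = 2L, min_distance = 5,
                        max_features = 10L)
  withr::with_seed(15, img <- matrix(runif(900), 30, 30))

  vals <- matrix(0, 30, 30)
  vals[15, 15] <- 1
  kp <- select_keypoints(make_map(vals, cfg), img, cfg)
  expect_equal(nrow(kp), 1L)
  expect_equal(c(kp$u, kp$v), c(14L, 14L))

  # two equal maxima 3 px apart with D = 5: exactly one survives, the
  # first in row-major scan order
  vals2 <- matrix(0, 30, 30)
  vals2[12, 15] <- 0.7
  vals2[15, 15] <- 0.7
  kp2 <- select_keypoints(make_map(vals2, cfg), img, cfg)
  expect_equal(nrow(kp2), 1L)
  expect_equal(kp2$v, 11L)  # row 12 comes first in scan order
})
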