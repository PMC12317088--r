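test_that("correlation matrix holds pairwise descriptor distances", {
  a <- make_keypoints(1, 1, list(c(0, 0)))
  expect_equal(correlation_matrix(a, a), matrix(0, 1, 1))

  b <- make_keypoints(2, 2, list(c(3, 4)))
  expect_equal(correlation_matrix(a, b), matrix(5, 1, 1))

  withr::with_seed(20, {
    A <- matrix(rnorm(5 * 14), 5, 14)
    B <- matrix(rnorm(7 * 14), 7, 14)
  })
  ka <- make_keypoints(seq_len(5), seq_len(5), asplit(A, 1))
  kb <- make_keypoints(seq_len(7), seq_len(7), asplit(B, 1))
  expect_equal(correlation_matrix(ka, kb), oracle_distance_matrix(A, B),
               tolerance = 1e-12)

  kc <- make_keypoints(1, 1, list(c(1, 2, 3)))
  expect_error(correlation_matrix(a, kc), class = "poolreg_validation_error")
})

test_that("ratio test accepts iff best <= ratio * second-best (boundary included)", {
  H <- rbind(
    c(1.0, 2.0, 9),         # 1.0 <= 0.75 * 2.0: accepted
    c(1.0, 1.2, 9),         # 1.0 >  0.75 * 1.2: rejected
    c(0.75, 1.0, 9),        # 0.75 == 0.75 * 1.0 exactly: boundary, accepted
    c(0.75 + 1e-9, 1.0, 9)  # just above the boundary: rejected
  )
  m <- ratio_test_match(H, ratio = 0.75, dedupe = FALSE)
  expect_setequal(m$moving, c(1L, 3L))
  expect_identical(attr(m, "stage"), "ratio_filtered")
  # with deduplication the shared best column keeps only the closest row
  md <- ratio_test_match(H, ratio = 0.75)
  expect_identical(md$moving, 3L)

  expect_error(ratio_test_match(matrix(1, 3, 1)),
               class = "poolreg_validation_error")
})

test_that("accepted rows shrink monotonically as the ratio tightens", {
  withr::with_seed(21, H <- matrix(runif(40 * 25, 0.1, 2), 40, 25))
  prev <- NULL
  for (r in c(0.9, 0.75, 0.6, 0.4)) {
    acc <- ratio_test_match(H, ratio = r, dedupe = FALSE)$moving
    if (!is.null(prev)) expect_true(all(acc %in% prev))
    prev <- acc
  }
})

test_that("duplicate fixed targets resolve to the closest pair", {
  H <- rbind(
    c(0.10, 1.0, 1.0),
    c(0.20, 1.0, 1.0),  # same best column as row 1, larger distance
    c(1.0, 1.0, 0.05)
  )
  m <- ratio_test_match(H, ratio = 0.75)
  expect_false(any(duplicated(m$fixed)))
  expect_true(all(c(1L, 3L) %in% m$moving))
  expect_false(2L %in% m$moving)
})

test_that("perspective filtering keeps consistent pairs and drops gross outliers", {
  M <- make_affine(rotation = 8, scale = 1.04, translation = c(5, -3))
  withr::with_seed(22, {
    src <- cbind(runif(10, 10, 200), runif(10, 10, 200))
  })
  dst <- transform_points(M, src)
  km <- make_keypoints(round(src[, 1]), round(src[, 2]),
                       rep(list(c(1, 0)), 10))
  kf <- make_keypoints(round(dst[, 1]), round(dst[, 2]),
                       rep(list(c(1, 0)), 10))
  matches <- make_matches(10)

  # all-consistent input survives intact
  out <- geometry_filter(matches, km, kf, threshold = 3, seed = 0)
  expect_equal(nrow(out), 10L)
  expect_identical(attr(out, "stage"), "geometry_filtered")

  # swap the fixed targets of two pairs top-to-bottom: exactly those two
  # are rejected, the 8 consistent pairs survive
  swapped <- matches
  swapped$fixed[c(1L, 2L)] <- swapped$fixed[c(2L, 1L)]
  out2 <- geometry_filter(swapped, km, kf, threshold = 3, seed = 0)
  expect_setequal(out2$moving, 3:10)
  # output is a subset of the input pairs
  expect_true(all(out2$moving %in% swapped$moving))
})

test_that("perspective filtering rejects degenerate geometry", {
  km <- make_keypoints(c(0, 10, 20, 30), c(0, 10, 20, 30),
                       rep(list(c(1, 0)), 4))   # collinear
  kf <- km
  expect_error(geometry_filter(make_matches(4), km, kf),
               class = "poolreg_degenerate_geometry_error")
  expect_error(geometry_filter(make_matches(3), km, kf),
               class = "poolreg_insufficient_matches_error")
})

test_that("affine estimation recovers exact and noisy generators", {
  # identity on three exact pairs
  km <- make_keypoints(c(0, 50, 20), c(0, 10, 60), rep(list(c(1, 0)), 3))
  M <- estimate_affine(make_matches(3), km, km)
  expect_equal(unclass(M), diag(3), tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(attr(M, "projection_error"), 0, tolerance = 1e-10)

  # known generator, no noise: recovered within 1e-8
  gen <- make_affine(rotation = 10, scale = 1.05, translation = c(7, -3))
  withr::with_seed(23, src <- cbind(runif(12, 0, 200), runif(12, 0, 200)))
  dst <- transform_points(gen, src)
  km2 <- make_keypoints(src[, 1], src[, 2], rep(list(c(1, 0)), 12))
  kf2 <- make_keypoints(dst[, 1], dst[, 2], rep(list(c(1, 0)), 12))
  M2 <- estimate_affine(make_matches(12), km2, kf2)
  expect_equal(unclass(M2), unclass(gen), tolerance = 1e-8, ignore_attr = TRUE)

  # Gaussian coordinate noise sigma = 0.5 px, n = 50: corner error < 1 px
  withr::with_seed(24, {
    src3 <- cbind(runif(50, 0, 255), runif(50, 0, 255))
    dst3 <- transform_points(gen, src3) + matrix(rnorm(100, sd = 0.5), 50, 2)
  })
  km3 <- make_keypoints(src3[, 1], src3[, 2], rep(list(c(1, 0)), 50))
  kf3 <- make_keypoints(dst3[, 1], dst3[, 2], rep(list(c(1, 0)), 50))
  M3 <- estimate_affine(make_matches(50), km3, kf3)
  expect_lt(corner_error(M3, gen, c(256, 256)), 1)

  # collinear moving points are rank-deficient
  kc <- make_keypoints(c(0, 10, 20, 30), c(0, 10, 20, 30),
                       rep(list(c(1, 0)), 4))
  expect_error(estimate_affine(make_matches(4), kc, kf2[1:4, ]),
               class = "poolreg_degenerate_geometry_error")
})

test_that("projection error sums Euclidean residuals", {
  km <- make_keypoints(c(0, 50, 20), c(0, 10, 60), rep(list(c(1, 0)), 3))
  I3 <- affine_transform(diag(3))
  expect_equal(projection_error(I3, make_matches(3), km, km), 0)

  kf <- make_keypoints(3, 4, list(c(1, 0)))
  k0 <- make_keypoints(0, 0, list(c(1, 0)))
  expect_equal(projection_error(I3, make_matches(1), k0, kf), 5)

  withr::with_seed(25, {
    src <- cbind(runif(8, 0, 100), runif(8, 0, 100))
    dst <- cbind(runif(8, 0, 100), runif(8, 0, 100))
  })
  km2 <- make_keypoints(src[, 1], src[, 2], rep(list(c(1, 0)), 8))
  kf2 <- make_keypoints(dst[, 1], dst[, 2], rep(list(c(1, 0)), 8))
  manual <- sum(sqrt(rowSums((dst - src)^2)))
  expect_equal(projection_error(I3, make_matches(8), km2, kf2), manual,
               tolerance = 1e-12)

  expect_error(projection_error(I3, make_matches(0), km2, kf2),
               class = "poolreg_validation_error")
})

test_that("warping inverts exactly for identity and integer translations", {
  withr::with_seed(26, img <- matrix(runif(40 * 30), 40, 30))
  I3 <- affine_transform(diag(3))
  expect_identical(warp_image(img, I3, interpolation = "nearest"), img)
  expect_equal(warp_image(img, I3), img, tolerance = 1e-12)

  Tr <- affine_transform(matrix(c(1, 0, 5, 0, 1, 0), 2, 3, byrow = TRUE))
  shifted <- warp_image(img, Tr, interpolation = "nearest")
  expect_equal(shifted[, 6:30], img[, 1:25])
  expect_true(all(shifted[, 1:5] == 0))

  expect_error(
    warp_image(img, affine_transform(matrix(c(1, 1, 0, 1, 1, 0), 2, 3,
                                            byrow = TRUE))),
    class = "poolreg_validation_error"
  )
})

test_that("bilinear warp round trip is accurate on smooth images", {
  pair <- generate_pair(fixture_config(seed = 30, shape = c(96L, 96L),
                                       n_blobs = 6L, texture_scale = 0))
  img <- pair$fixed
  M <- make_affine(rotation = 7, scale = 1.03, translation = c(3, -2),
                   center = c(47.5, 47.5))
  round_trip <- warp_image(warp_image(img, M, dim(img)), invert_affine(M),
                           dim(img))
  interior <- 20:76
  mad <- mean(abs(round_trip[interior, interior] - img[interior, interior]))
  expect_lt(mad, 0.02 * diff(range(img)))
})

test_that("affine transforms serialize to JSON and back", {
  tmp <- withr::local_tempdir()
  M <- make_affine(rotation = 12, scale = 0.97, translation = c(4.5, -1.25),
                   shear = 0.02, center = c(100, 120))
  p <- file.path(tmp, "transform.json")
  write_transform_json(M, p, extra = list(note = "test"))
  expect_equal(unclass(read_transform_json(p)), unclass(M), tolerance = 1e-12)

  td <- tidy(M)
  expect_named(td, c("term", "estimate"))
  expect_equal(td$estimate[td$term == "rotation"], 12, tolerance = 1e-8)
})
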