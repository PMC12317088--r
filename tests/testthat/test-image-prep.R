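test_that("PNG and TIFF images load as grayscale float matrices", {
  tmp <- withr::local_tempdir()

  p1 <- file.path(tmp, "const.png")
  png::writePNG(matrix(1, 2, 2), p1)
  img <- load_image(p1)
  expect_true(is.matrix(img))
  expect_equal(dim(img), c(2L, 2L))
  expect_true(all(img == img[1L, 1L]))

  # RGB with R = G = B collapses to that common value
  p2 <- file.path(tmp, "gray-rgb.png")
  g <- matrix(seq(0, 1, length.out = 12), 3, 4)
  png::writePNG(array(rep(g, 3), dim = c(3, 4, 3)), p2)
  expect_equal(load_image(p2), g, tolerance = 0.003)  # 8-bit PNG quantization

  # 16-bit TIFF round trip is exact on 16-bit-representable values
  p3 <- file.path(tmp, "roundtrip.tif")
  vals <- matrix(sample(0:65535, 64), 8, 8) / 65535
  write_image(vals, p3, normalize = FALSE, bits = 16L)
  expect_equal(load_image(p3), vals, tolerance = 1e-12)

  expect_error(load_image(file.path(tmp, "missing.png")),
               class = "poolreg_io_error")
})

test_that("raw r2d raster container round-trips doubles exactly", {
  tmp <- withr::local_tempdir()
  p <- file.path(tmp, "arr.r2d")
  m <- matrix(rnorm(35), 5, 7)
  write_image(m, p)
  expect_identical(load_image(p), m)
})

test_that("hotspot clipping replaces only values above the quantile", {
  # constant image: nothing exceeds any quantile
  const <- matrix(3.5, 10, 10)
  expect_equal(hotspot_clip(const, 0.99), const)

  # 99 pixels at 1.0 plus one at 1000: the type-7 0.99 quantile of the
  # sorted 100 values is x[99] + 0.01 * (x[100] - x[99]) = 10.99
  x <- matrix(c(rep(1, 99), 1000), 10, 10)
  clipped <- hotspot_clip(x, 0.99)
  expect_equal(max(clipped), 10.99)
  expect_equal(sum(clipped == 1), 99L)

  # quantile 1 maps the max to itself
  expect_equal(hotspot_clip(x, 1), x)
})

test_that("hotspot clipping is idempotent when the quantile is attained", {
  # with the linear-interpolation quantile, (n - 1) * p + 1 integer makes
  # the quantile an order statistic, and clipping is then exactly
  # idempotent; re-clipping never raises any intensity in general
  withr::with_seed(1, {
    for (i in 1:5) {
      img <- matrix(rexp(401), 401, 1)   # (401 - 1) * 0.95 + 1 = 381
      once <- hotspot_clip(img, 0.95)
      expect_equal(hotspot_clip(once, 0.95), once)
      general <- hotspot_clip(matrix(rexp(400), 20, 20), 0.95)
      expect_true(all(hotspot_clip(general, 0.95) <= general))
    }
  })
})

test_that("quarter-turn rotation swaps dimensions and is 4-periodic", {
  m <- matrix(1:6, 2, 3)
  expect_identical(rotate90(m, 0L), m + 0)
  expect_equal(dim(rotate90(m, 1L)), c(3L, 2L))
  expect_identical(rotate90(m, 4L), m + 0)
  expect_identical(rotate90(rotate90(m, 1L), -1L), m + 0)
  # k = +1 is counter-clockwise: the top-right pixel moves to top-left
  m2 <- matrix(c(1, 3, 2, 4), 2, 2)  # rows: (1 2) / (3 4)
  expect_identical(rotate90(m2, 1L), matrix(c(2, 1, 4, 3), 2, 2))
})

test_that("channel collapse reproduces a per-pixel oracle and is pluggable", {
  one <- matrix(runif(20), 4, 5)
  expect_equal(collapse_channels(channel_stack(list(one))), one)
  expect_equal(collapse_channels(channel_stack(list(one, one))), one)

  withr::with_seed(2, {
    stack <- channel_stack(array(runif(48), dim = c(4, 4, 3)))
  })
  out <- collapse_channels(stack, "mean")
  expected <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) expected[i, j] <- mean(stack[i, j, ])
  expect_equal(out, expected)

  # pc1 is deterministic and shape-preserving
  expect_identical(collapse_channels(stack, "pc1"),
                   collapse_channels(stack, "pc1"))

  register_embedding("sum", function(x, seed) rowSums(x))
  expect_equal(collapse_channels(stack, "sum"), 3 * out)

  expect_error(collapse_channels(stack, "no-such-method"),
               class = "poolreg_config_error")
})

test_that("intensity normalization maps to [0, 1] with a degenerate rule", {
  expect_equal(normalize_intensity(matrix(7, 3, 3)), matrix(0, 3, 3))
  m <- matrix(c(10, 15, 20, 12), 2, 2)
  out <- normalize_intensity(m)
  expect_equal(out[2L, 1L], 0.5)
  expect_equal(range(out), c(0, 1))
})

test_that("invalid images are rejected with validation errors", {
  expect_error(as_image(matrix(c(1, NA), 1, 2)),
               class = "poolreg_validation_error")
  expect_error(hotspot_clip(matrix(1, 2, 2), quantile = 0),
               class = "poolreg_validation_error")
  expect_error(channel_stack(list(matrix(1, 2, 2), matrix(1, 3, 3))),
               class = "poolreg_validation_error")
})
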