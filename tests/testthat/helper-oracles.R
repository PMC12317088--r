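# Independent scalar-loop oracles. These re-derive each quantity from
# first principles (explicit loops, no shared code with the package
# internals) so descriptor, distance and metric implementations are
# checked against a second, dumb-but-obvious route.

# block grid shapes per layer: 1x1, 1x2, 2x2, 4x2, then keep splitting
# the currently-coarser axis
oracle_grid <- function(l) {
  if (l == 1) return(c(1, 1))
  if (l == 2) return(c(1, 2))
  nr <- 1; nc <- 2
  for (s in 3:l) if (nr <= nc) nr <- nr * 2 else nc <- nc * 2
  c(nr, nc)
}

# pooled descriptor at 0-based (u, v) by explicit per-pixel loops
oracle_descriptor <- function(img, u, v, window, layers) {
  lo <- window %/% 2
  r0 <- v - lo + 1
  c0 <- u - lo + 1
  win <- img[r0:(r0 + window - 1), c0:(c0 + window - 1)]
  vals <- c()
  for (l in 1:layers) {
    g <- oracle_grid(l)
    rb <- round(seq(0, window, length.out = g[1] + 1))
    cb <- round(seq(0, window, length.out = g[2] + 1))
    for (i in 1:g[1]) {
      for (j in 1:g[2]) {
        s <- 0; n <- 0
        for (r in (rb[i] + 1):rb[i + 1]) {
          for (cc in (cb[j] + 1):cb[j + 1]) {
            s <- s + win[r, cc]
            n <- n + 1
          }
        }
        vals <- c(vals, s / n)
      }
    }
  }
  vals[-1] - vals[1]
}

# all-pairs Euclidean distances by double loop
oracle_distance_matrix <- function(A, B) {
  out <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) {
    for (j in seq_len(nrow(B))) {
      out[i, j] <- sqrt(sum((A[i, ] - B[j, ])^2))
    }
  }
  out
}

# symmetric Hausdorff distance by explicit max-min loops over foreground
# coordinates
oracle_hausdorff <- function(a, b) {
  pa <- which(a, arr.ind = TRUE)
  pb <- which(b, arr.ind = TRUE)
  directed <- function(p, q) {
    worst <- 0
    for (i in seq_len(nrow(p))) {
      best <- Inf
      for (j in seq_len(nrow(q))) {
        best <- min(best, sqrt(sum((p[i, ] - q[j, ])^2)))
      }
      worst <- max(worst, best)
    }
    worst
  }
  max(directed(pa, pb), directed(pb, pa))
}

# keypoints tibble from raw parts, for tests that construct
# configurations directly
make_keypoints <- function(u, v, descriptors) {
  poolreg:::new_keypoints(
    tibble::tibble(
      u = as.numeric(u), v = as.numeric(v),
      magnitude = vapply(descriptors, function(d) sqrt(sum(d^2)), numeric(1)),
      descriptor = descriptors
    ),
    pyramid_config()
  )
}

# a match tibble covering all supplied keypoints 1:1
make_matches <- function(n, stage = "ratio_filtered") {
  poolreg:::new_match_set(
    tibble::tibble(moving = seq_len(n), fixed = seq_len(n),
                   distance = rep(0, n)),
    stage
  )
}

# synthetic magnitude map wrapping a raw value matrix
make_map <- function(values, config) {
  structure(
    list(values = values, border_width = as.integer(ceiling(config$window / 2)),
         stride = 1L, config = config),
    class = "magnitude_map"
  )
}
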