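# Programmatic fixtures shared across the suite. Everything is generated
# in code under fixed seeds; no data files.

# n_per points around each row of `centers` (k x d), Gaussian with the given
# per-coordinate sd. Returns the pixel matrix and 0-based ground truth.
make_blob_data <- function(centers, n_per, sd, seed) {
  set.seed(seed)
  k <- nrow(centers)
  X <- do.call(rbind, lapply(seq_len(k), function(j) {
    sweep(matrix(rnorm(n_per * ncol(centers), sd = sd), n_per, ncol(centers)),
          2, centers[j, ], `+`)
  }))
  list(X = X, truth = rep(seq_len(k) - 1L, each = n_per))
}

# Three well-separated image clusters: cluster-center images are random
# 16x16 patterns at unit RMS norm scaled so that the minimum center
# separation is `sep_ratio` times the within-cluster RMS spread (which is 1).
make_separable_images <- function(seed, n_per = 50, D = 16, sep_ratio = 10) {
  set.seed(seed)
  d <- D * D
  ctrs <- matrix(rnorm(3 * d), 3, d)
  ctrs <- ctrs / sqrt(rowSums(ctrs^2))
  ctrs <- ctrs * sep_ratio / min(dist(ctrs))
  make_blob_data(ctrs, n_per, sd = 1 / sqrt(d), seed = seed + 1000)
}

rand_stack <- function(n, d, seed) {
  set.seed(seed)
  matrix(rnorm(n * d), n, d)
}

# Smooth test image: off-center Gaussian blob, suitable for interpolation
# tolerance checks.
smooth_image <- function(D, cx = NULL, cy = NULL, width = D / 6) {
  ctr <- D %/% 2
  cx <- cx %||% (ctr + D / 5)
  cy <- cy %||% (ctr - D / 8)
  x <- matrix(0:(D - 1), D, D)
  y <- matrix(0:(D - 1), D, D, byrow = TRUE)
  exp(-((x - cx)^2 + (y - cy)^2) / (2 * width^2))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
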