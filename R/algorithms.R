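#' Clustering run parameters
#'
#' Parameters shared by all clustering loops. `beta` weighs the adaptive
#' class-size constraint (0 disables it; 0.5 is a good general-purpose
#' value). `sigma0` is the termination threshold on the fraction of images
#' changing class per iteration (conventionally 0.01). `sample_size` images
#' are drawn per iteration to estimate the characteristic dissimilarity.
#'
#' All randomness derives from `seed`: centroid initialization uses `seed`
#' itself, the characteristic-dissimilarity sample of iteration `t` uses
#' `seed + 7000 + t`, a shuffled sweep order uses `seed + 9000 + t`, and
#' empty-class reseeding uses `seed + 8000 + t`. Keep `seed` small so the
#' derived seeds stay within integer range.
#'
#' @param beta nonnegative balance weight.
#' @param sigma0 termination threshold in `[0, 1]`.
#' @param max_iter iteration cap.
#' @param seed integer master seed.
#' @param sample_size images sampled per iteration for `d_c`.
#' @param assignment_order `"dataset_order"` (default, reproducible) or
#'   `"shuffled"` (fresh seeded permutation per sweep).
#' @param reseed_empty reseed empty classes with a random image (intended
#'   for the traditional baseline; off by default).
#' @return An object of class `"ack_params"`.
#' @export
ack_params <- function(beta = 0.5, sigma0 = 0.01, max_iter = 100L, seed = 1L,
                       sample_size = 10L,
                       assignment_order = c("dataset_order", "shuffled"),
                       reseed_empty = FALSE) {
  assignment_order <- match.arg(assignment_order)
  if (beta < 0) stop("beta must be nonnegative", call. = FALSE)
  if (sigma0 < 0 || sigma0 > 1) stop("sigma0 must lie in [0, 1]", call. = FALSE)
  if (max_iter < 1) stop("max_iter must be positive", call. = FALSE)
  if (sample_size < 1) stop("sample_size must be positive", call. = FALSE)
  structure(list(beta = beta, sigma0 = sigma0, max_iter = as.integer(max_iter),
                 seed = as.integer(seed), sample_size = as.integer(sample_size),
                 assignment_order = assignment_order,
                 reseed_empty = isTRUE(reseed_empty)),
            class = "ack_params")
}

# Shared iteration shell for all four algorithms. Per iteration:
# dissimilarities to current centroids, characteristic dissimilarity d_c
# (seeded 10-image sample), constraint weight 2*lambda (ACK only), one
# assignment pass, sigma, centroid update. Terminates when sigma <= sigma0
# or max_iter is reached.
cluster_engine <- function(stack, k, params, dissim, algorithm) {
  stack <- as_image_stack(stack)
  X <- stack$pixels
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 1L || k > n) {
    stop("k must satisfy 1 <= k <= n (k = ", k, ", n = ", n, ")", call. = FALSE)
  }
  dissim <- as_dissim_spec(dissim)
  cents <- init_centroids(stack, k, params$seed)
  D <- dissim_matrix(X, cents, dissim, stack$image_side)
  p <- if (algorithm == "eqk") eqk_assign_impl(D)
       else max.col(-D, ties.method = "first") - 1L
  cents <- update_centroids_impl(X, p, k, cents)

  sigma_h <- dc_h <- tl_h <- J_h <- numeric(0)
  sigma <- Inf
  iter <- 0L
  while (sigma > params$sigma0 && iter < params$max_iter) {
    iter <- iter + 1L
    D <- dissim_matrix(X, cents, dissim, stack$image_side)
    samp <- local_seed(params$seed + 7000L + iter,
                       sample.int(n, min(params$sample_size, n)))
    d_c <- dc_from_dissim(D[samp, , drop = FALSE])
    two_lambda <- if (algorithm == "ack") {
      two_lambda_from_beta(params$beta, d_c, n, k)
    } else 0
    ord <- if (params$assignment_order == "shuffled") {
      local_seed(params$seed + 9000L + iter, sample.int(n))
    } else seq_len(n)
    p_old <- p
    p <- switch(algorithm,
      ack = ack_sweep_impl(D, p, two_lambda, ord),
      kmeans = max.col(-D, ties.method = "first") - 1L,
      spider = spider_assign_impl(D, p, ord),
      eqk = eqk_assign_impl(D))
    sigma <- membership_change_fraction(p_old, p)
    J <- objective_impl(D, p, two_lambda / 2)
    cents <- update_centroids_impl(X, p, k, cents,
                                   reseed_empty = params$reseed_empty,
                                   seed = params$seed + 8000L + iter)
    sigma_h <- c(sigma_h, sigma)
    dc_h <- c(dc_h, d_c)
    tl_h <- c(tl_h, two_lambda)
    J_h <- c(J_h, J)
  }

  structure(list(
    labels = p,
    k = k,
    centroids = cents,
    sigma_history = sigma_h,
    dc_history = dc_h,
    lambda_history = tl_h,
    objective_history = J_h,
    n_iter = iter,
    converged = is.finite(sigma) && sigma <= params$sigma0,
    algorithm = algorithm,
    params = params,
    image_side = stack$image_side
  ), class = "ack_clustering")
}

#' Adaptively constrained K-means clustering (ACK-means)
#'
#' Clusters the image stack into `k` classes while adaptively discouraging
#' unbalanced class sizes. Each iteration estimates the data's
#' characteristic dissimilarity `d_c` from a small random image sample,
#' sets the constraint weight `2*lambda = beta * d_c / floor(n/k)`, and
#' performs one sequential reassignment sweep minimizing
#' `dissim(x_i, mu_j) + 2*lambda * s'_j` per image (see
#' [ack_assign_sweep()]), followed by a centroid mean update. Iteration
#' stops when the fraction of images changing class drops to `sigma0`.
#' With `beta = 0` the procedure is exactly the traditional K-means loop.
#'
#' @param stack an [image_stack()] or pixel matrix.
#' @param k number of classes.
#' @param params an [ack_params()].
#' @param dissim a [dissim_spec()], method name, or pairwise function.
#' @return An object of class `"ack_clustering"`: 0-based `labels`, the
#'   final `centroids`, per-iteration diagnostic histories (`sigma_history`,
#'   `dc_history`, `lambda_history` holding `2*lambda`, `objective_history`),
#'   `n_iter`, and `converged`.
#' @seealso [kmeans_baseline()], [eqk_means()], [spider_kmeans()]
#' @export
ack_means <- function(stack, k, params = ack_params(), dissim = dissim_spec()) {
  cluster_engine(stack, k, params, dissim, "ack")
}

#' Traditional K-means baseline
#'
#' The classical loop: nearest-centroid assignment and mean update,
#' initialized from `k` random images. For comparability with the
#' constrained algorithms it uses the same `sigma <= sigma0` termination
#' rule and iteration cap, and logs the same diagnostics. `beta` is ignored.
#'
#' @inheritParams ack_means
#' @return An `"ack_clustering"` object.
#' @export
kmeans_baseline <- function(stack, k, params = ack_params(),
                            dissim = dissim_spec()) {
  cluster_engine(stack, k, params, dissim, "kmeans")
}

#' Equally-sized-group K-means (EQK-means)
#'
#' Forces every class to the same size (up to a difference of one when `k`
#' does not divide `n`) at every iteration through the greedy
#' sorted-assignment step of [eqk_assign()], inside the same iteration shell
#' as [ack_means()].
#'
#' @inheritParams ack_means
#' @return An `"ack_clustering"` object.
#' @export
eqk_means <- function(stack, k, params = ack_params(), dissim = dissim_spec()) {
  cluster_engine(stack, k, params, dissim, "eqk")
}

#' SPIDER-style size-factor K-means
#'
#' The traditional K-means variant whose dissimilarities are multiplied by
#' the class-size factor `s/(s -+ 1)` before each argmin (see
#' [spider_factor_assign()]), inside the same iteration shell as
#' [ack_means()].
#'
#' @inheritParams ack_means
#' @return An `"ack_clustering"` object.
#' @export
spider_kmeans <- function(stack, k, params = ack_params(),
                          dissim = dissim_spec()) {
  cluster_engine(stack, k, params, dissim, "spider")
}

#' @export
print.ack_clustering <- function(x, ...) {
  s <- class_sizes(x$labels, x$k)
  cat(sprintf("%s clustering: %d images, k = %d\n",
              switch(x$algorithm, ack = "ACK-means", kmeans = "K-means",
                     eqk = "EQK-means", spider = "SPIDER K-means"),
              length(x$labels), x$k))
  cat(sprintf("  iterations: %d (%s), final sigma = %.4g\n", x$n_iter,
              if (x$converged) "converged" else "iteration cap reached",
              if (x$n_iter > 0) x$sigma_history[x$n_iter] else NA))
  cat(sprintf("  class sizes: min %d, median %g, max %d (sd %.2f)\n",
              min(s), stats::median(s), max(s), stats::sd(s)))
  invisible(x)
}
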