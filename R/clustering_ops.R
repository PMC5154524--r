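# Elementary clustering operations. Class labels are 0-based throughout
# ("class_0based" in all on-disk tables, with a 1-based companion column).

#' Initialize centroids by random image selection
#'
#' Picks `k` distinct images of the stack uniformly at random (without
#' replacement) as the initial class representatives, so every class starts
#' with at least one natural member.
#'
#' @param stack an [image_stack()] or pixel matrix.
#' @param k number of classes, `1 <= k <= n`.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @return `k x d` centroid matrix with attribute `init_indices` (the
#'   selected 1-based image indices).
#' @export
init_centroids <- function(stack, k, seed) {
  X <- as_image_stack(stack)$pixels
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 1L || k > n) {
    stop("k must satisfy 1 <= k <= n (k = ", k, ", n = ", n, ")", call. = FALSE)
  }
  idx <- local_seed(seed, sample.int(n, k))
  C <- X[idx, , drop = FALSE]
  attr(C, "init_indices") <- idx
  C
}

#' Assign each image to its nearest centroid
#'
#' The plain K-means assignment step: `labels[i] = argmin_j dissim(x_i, mu_j)`,
#' ties broken by the lowest class index.
#'
#' @param stack an [image_stack()] or pixel matrix.
#' @param centroids `k x d` centroid matrix.
#' @param dissim a [dissim_spec()] (or method name / pairwise function).
#' @return Integer vector of 0-based labels, length `n`.
#' @export
nearest_assign <- function(stack, centroids, dissim = dissim_spec()) {
  stack <- as_image_stack(stack)
  if (nrow(centroids) < 1L) stop("centroid set is empty", call. = FALSE)
  D <- dissim_matrix(stack$pixels, centroids, dissim, stack$image_side)
  max.col(-D, ties.method = "first") - 1L
}

#' Update centroids as class means
#'
#' Recomputes each nonempty class's centroid as the arithmetic mean of its
#' member images. A class left empty by the assignment retains its previous
#' centroid (it remains a candidate, and under the size constraint an empty
#' class is maximally attractive), unless `reseed_empty` asks for a random
#' replacement image.
#'
#' @inheritParams nearest_assign
#' @param assignment integer vector of 0-based labels.
#' @param k number of classes; defaults to `nrow(prev_centroids)` or
#'   `max(assignment) + 1`.
#' @param prev_centroids previous `k x d` centroid matrix, required when a
#'   class may be empty.
#' @param reseed_empty if `TRUE`, replace empty-class centroids by a random
#'   image (seeded by `seed`); mimics the common reseeding practice for the
#'   traditional baseline.
#' @param seed seed for reseeding.
#' @return `k x d` centroid matrix.
#' @export
update_centroids <- function(stack, assignment, k = NULL, prev_centroids = NULL,
                             reseed_empty = FALSE, seed = 0L) {
  X <- as_image_stack(stack)$pixels
  k <- as.integer(k %||% if (!is.null(prev_centroids)) nrow(prev_centroids)
                         else max(assignment) + 1L)
  p <- check_labels(assignment, nrow(X), k)
  update_centroids_impl(X, p, k, prev_centroids, reseed_empty, seed)
}

update_centroids_impl <- function(X, p, k, prev, reseed_empty = FALSE, seed = 0L) {
  s <- class_sizes(p, k)
  C <- matrix(0, k, ncol(X))
  sums <- rowsum(X, group = p, reorder = TRUE)
  present <- sort(unique(p))
  C[present + 1L, ] <- sums / s[present + 1L]
  empty <- which(s == 0L)
  if (length(empty) > 0L) {
    if (reseed_empty) {
      idx <- local_seed(seed, sample.int(nrow(X), length(empty)))
      C[empty, ] <- X[idx, , drop = FALSE]
    } else if (!is.null(prev)) {
      C[empty, ] <- prev[empty, , drop = FALSE]
    } else {
      stop("class(es) ", paste(empty - 1L, collapse = ", "),
           " are empty and no previous centroids were given", call. = FALSE)
    }
  }
  C
}

#' Characteristic dissimilarity of the current iteration
#'
#' A per-iteration estimate of the data's dissimilarity scale: for each of
#' `sample_size` randomly chosen images, take the spread (max minus min) of
#' its dissimilarities to the `k` centroids, and average these spreads. Used
#' to make the class-size constraint weight scale-free.
#'
#' @inheritParams nearest_assign
#' @param sample_size number of images sampled (all images if `n` is
#'   smaller); the conventional value is 10.
#' @param seed integer seed for the sample.
#' @return Nonnegative scalar `d_c`.
#' @export
characteristic_dissimilarity <- function(stack, centroids, dissim = dissim_spec(),
                                         sample_size = 10L, seed = 0L) {
  stack <- as_image_stack(stack)
  if (is.null(dim(centroids)) || nrow(centroids) < 1L) {
    stop("centroid set is empty", call. = FALSE)
  }
  if (sample_size < 1L) stop("sample_size must be at least 1", call. = FALSE)
  n <- nrow(stack$pixels)
  idx <- local_seed(seed, sample.int(n, min(sample_size, n)))
  D <- dissim_matrix(stack$pixels[idx, , drop = FALSE], centroids, dissim,
                     stack$image_side)
  dc_from_dissim(D)
}

dc_from_dissim <- function(D) {
  mean(apply(D, 1L, max) - apply(D, 1L, min))
}

#' Constraint weight from the balance parameter
#'
#' Converts the scale-free balance parameter `beta` into the constraint
#' weight used in the assignment sweep: `2*lambda = beta * d_c / floor(n/k)`.
#' `floor(n/k)` is the common class size of a perfectly balanced partition.
#'
#' @param beta nonnegative balance parameter (0 disables the constraint).
#' @param d_c characteristic dissimilarity of the iteration.
#' @param n number of images.
#' @param k number of classes (`k <= n`).
#' @return Nonnegative scalar `2*lambda`.
#' @examples
#' two_lambda_from_beta(0.5, 100, 1000, 10) # 0.5
#' @export
two_lambda_from_beta <- function(beta, d_c, n, k) {
  if (beta < 0) stop("beta must be nonnegative", call. = FALSE)
  if (d_c < 0) stop("d_c must be nonnegative", call. = FALSE)
  div <- n %/% k
  if (is.na(div) || div < 1L) {
    stop("floor(n/k) must be at least 1 (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  }
  beta * d_c / div
}

#' One size-constrained assignment sweep
#'
#' Visits the images sequentially and reassigns each to the class minimizing
#' `dissim(x_i, mu_j) + 2*lambda * s'_j`, where `s'` is the class-size
#' vector of the current labels with image `i` removed. Sizes are updated
#' online, so later images see earlier reassignments within the same sweep.
#' Ties break to the lowest class index. With `two_lambda = 0` the sweep
#' reduces to [nearest_assign()] and is order-independent.
#'
#' @inheritParams nearest_assign
#' @param assignment current 0-based labels.
#' @param two_lambda nonnegative constraint weight (see
#'   [two_lambda_from_beta()]).
#' @param order integer sequence of 1-based image indices giving the visit
#'   order; defaults to dataset order `1:n`.
#' @return Updated 0-based label vector.
#' @export
ack_assign_sweep <- function(stack, centroids, assignment, two_lambda,
                             dissim = dissim_spec(), order = NULL) {
  stack <- as_image_stack(stack)
  if (two_lambda < 0) stop("two_lambda must be nonnegative", call. = FALSE)
  k <- nrow(centroids)
  p <- check_labels(assignment, nrow(stack$pixels), k)
  D <- dissim_matrix(stack$pixels, centroids, dissim, stack$image_side)
  ack_sweep_impl(D, p, two_lambda, order %||% seq_len(nrow(D)))
}

ack_sweep_impl <- function(D, p, two_lambda, ord) {
  k <- ncol(D)
  s <- class_sizes(p, k)
  for (i in ord) {
    own <- p[i] + 1L
    s[own] <- s[own] - 1L
    j <- which.min(D[i, ] + two_lambda * s)
    p[i] <- j - 1L
    s[j] <- s[j] + 1L
  }
  p
}

#' Fraction of images changing class between two assignments
#'
#' The convergence statistic `sigma = 1 - (1/n) * sum(delta(p_old, p_new))`:
#' the fraction of indices whose label differs.
#'
#' @param p_old,p_new 0-based label vectors of equal length.
#' @return Scalar in `[0, 1]`.
#' @export
membership_change_fraction <- function(p_old, p_new) {
  if (length(p_old) != length(p_new)) {
    stop("assignments have different lengths", call. = FALSE)
  }
  mean(p_old != p_new)
}

#' Constrained clustering objective
#'
#' Evaluates `J = sum_i dissim(x_i, mu_(p_i)) + lambda * sum_j s_j^2`.
#' With `lambda = 0` this is the classical K-means objective; the quadratic
#' size term is minimized (for fixed `n`) by equal class sizes, which is the
#' source of the balancing pressure.
#'
#' @inheritParams ack_assign_sweep
#' @param lambda nonnegative constraint weight (`lambda`, i.e. half of
#'   `two_lambda`).
#' @return Scalar objective value.
#' @export
clustering_objective <- function(stack, centroids, assignment, lambda = 0,
                                 dissim = dissim_spec()) {
  stack <- as_image_stack(stack)
  if (lambda < 0) stop("lambda must be nonnegative", call. = FALSE)
  k <- nrow(centroids)
  p <- check_labels(assignment, nrow(stack$pixels), k)
  D <- dissim_matrix(stack$pixels, centroids, dissim, stack$image_side)
  objective_impl(D, p, lambda)
}

objective_impl <- function(D, p, lambda) {
  sum(D[cbind(seq_len(nrow(D)), p + 1L)]) +
    lambda * sum(class_sizes(p, ncol(D))^2)
}

#' SPIDER-style size-factor assignment
#'
#' The modified traditional K-means assignment used in SPIDER: each raw
#' dissimilarity is multiplied by a class-size factor before the argmin,
#' `s/(s - 1)` when comparing an image to its own class (size counted with
#' the image included) and `s/(s + 1)` for every other class. Small classes
#' get factors below one and so attract members; very large classes have
#' factors near one. A singleton's own-class factor `1/0` is treated as
#' infinite, so the image always prefers any finite alternative (unless
#' `k = 1`). Images are visited sequentially with online size updates, which
#' makes an emptied class (factor 0) immediately attractive again and
#' prevents empty classes from surviving a sweep.
#'
#' @inheritParams ack_assign_sweep
#' @return Updated 0-based label vector.
#' @export
spider_factor_assign <- function(stack, centroids, assignment,
                                 dissim = dissim_spec(), order = NULL) {
  stack <- as_image_stack(stack)
  k <- nrow(centroids)
  p <- check_labels(assignment, nrow(stack$pixels), k)
  D <- dissim_matrix(stack$pixels, centroids, dissim, stack$image_side)
  spider_assign_impl(D, p, order %||% seq_len(nrow(D)))
}

spider_assign_impl <- function(D, p, ord) {
  k <- ncol(D)
  s <- class_sizes(p, k)
  for (i in ord) {
    own <- p[i] + 1L
    if (s[own] < 1L) {
      stop("internal inconsistency: image ", i, " sits in empty class ",
           own - 1L, call. = FALSE)
    }
    f <- s / (s + 1)
    f[own] <- if (s[own] > 1L) s[own] / (s[own] - 1) else Inf
    if (k == 1L) f[own] <- 1
    score <- f * D[i, ]
    score[is.nan(score)] <- Inf  # Inf factor on a zero distance
    j <- which.min(score)
    if (j != own) {
      s[own] <- s[own] - 1L
      s[j] <- s[j] + 1L
      p[i] <- j - 1L
    }
  }
  p
}

#' Equally-sized greedy assignment (EQK-means step)
#'
#' Forces a balanced partition: class capacities are `floor(n/k)`, with one
#' extra slot for each of the first `n %% k` classes. All `n * k`
#' image-centroid dissimilarities are sorted ascending and pairs are
#' accepted greedily when the image is still unassigned and the class still
#' below capacity; the resulting sizes satisfy `max - min <= 1`.
#'
#' @inheritParams nearest_assign
#' @return 0-based label vector.
#' @export
eqk_assign <- function(stack, centroids, dissim = dissim_spec()) {
  stack <- as_image_stack(stack)
  k <- nrow(centroids)
  n <- nrow(stack$pixels)
  if (k > n) stop("k must not exceed n", call. = FALSE)
  D <- dissim_matrix(stack$pixels, centroids, dissim, stack$image_side)
  eqk_assign_impl(D)
}

eqk_assign_impl <- function(D) {
  n <- nrow(D); k <- ncol(D)
  cap <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0L) cap[seq_len(r)] <- cap[seq_len(r)] + 1L
  ord <- order(D)  # stable: ties by lower column (class), then lower row
  p <- rep(NA_integer_, n)
  filled <- integer(k)
  assigned <- 0L
  for (idx in ord) {
    i <- ((idx - 1L) %% n) + 1L
    j <- ((idx - 1L) %/% n) + 1L
    if (is.na(p[i]) && filled[j] < cap[j]) {
      p[i] <- j - 1L
      filled[j] <- filled[j] + 1L
      assigned <- assigned + 1L
      if (assigned == n) break
    }
  }
  p
}
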