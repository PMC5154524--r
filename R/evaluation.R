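# Evaluation instruments: within-class angular-distance histograms,
# class-size balance curves, partition-recovery scoring, class averages.

#' Angular distance between two projection directions
#'
#' The arc angle (degrees, in `[0, 180]`) between the projection-direction
#' unit vectors of two orientations. The in-plane angle `psi` is ignored:
#' classification quality is about grouping similar projection directions,
#' while in-plane rotation is the alignment step's job. Antipodal
#' directions count as 180 degrees.
#'
#' @param o1,o2 unit 3-vectors, or lists/rows with `phi` and `theta` in
#'   degrees.
#' @return Angle in degrees.
#' @examples
#' angular_distance(c(1, 0, 0), c(0, 1, 0)) # 90
#' @export
angular_distance <- function(o1, o2) {
  d1 <- as_direction(o1)
  d2 <- as_direction(o2)
  acos(pmin(1, pmax(-1, sum(d1 * d2)))) * 180 / pi
}

as_direction <- function(o) {
  if (is.numeric(o) && length(o) == 3L) {
    nrm <- sqrt(sum(o^2))
    if (abs(nrm - 1) > 1e-6) {
      stop("direction vector is not unit length (norm = ", signif(nrm, 6), ")",
           call. = FALSE)
    }
    return(o)
  }
  if (!is.null(o$phi) && !is.null(o$theta)) {
    return(as.vector(euler_to_direction(o$phi, o$theta)))
  }
  stop("cannot interpret orientation", call. = FALSE)
}

#' Pooled within-class angular-distance histogram
#'
#' Pools the pairwise angular distances between the true projection
#' directions of every pair of images sharing a class (a class of size `s`
#' contributes `choose(s, 2)` pairs; sizes 0 and 1 contribute none), bins
#' them on `[0, 180]` degrees and normalizes the frequencies to sum to 1.
#' A sharper peak at low angles indicates classes of more coherent
#' projection orientation.
#'
#' @param assignment 0-based label vector.
#' @param orientations data frame with `phi`, `theta` (degrees), one row
#'   per image.
#' @param k number of classes; defaults to `max(assignment) + 1`.
#' @param bin_width histogram bin width in degrees (default 2).
#' @return List with `bin_edges`, `frequencies` (summing to 1),
#'   `mean_angular` (pooled mean, degrees) and `n_pairs`.
#' @export
within_class_angular_histogram <- function(assignment, orientations,
                                           k = NULL, bin_width = 2) {
  k <- as.integer(k %||% (max(assignment) + 1L))
  n <- nrow(orientations)
  p <- check_labels(assignment, n, k)
  dirs <- euler_to_direction(orientations$phi, orientations$theta)
  pooled <- pooled_within_class_angles(p, dirs, k)
  if (length(pooled) == 0L) {
    stop("no class has two or more members; the histogram is empty",
         call. = FALSE)
  }
  edges <- seq(0, 180, by = bin_width)
  if (edges[length(edges)] < 180) edges <- c(edges, 180)
  bins <- .bincode(pooled, breaks = edges, right = TRUE, include.lowest = TRUE)
  counts <- tabulate(bins, nbins = length(edges) - 1L)
  list(bin_edges = edges,
       frequencies = counts / length(pooled),
       mean_angular = mean(pooled),
       n_pairs = length(pooled))
}

pooled_within_class_angles <- function(p, dirs, k) {
  out <- vector("list", k)
  for (j in seq_len(k) - 1L) {
    idx <- which(p == j)
    if (length(idx) < 2L) next
    G <- tcrossprod(dirs[idx, , drop = FALSE])
    dots <- G[upper.tri(G)]
    out[[j + 1L]] <- acos(pmin(1, pmax(-1, dots))) * 180 / pi
  }
  unlist(out) %||% numeric(0)
}

#' Ascending class-size curve
#'
#' Class sizes sorted ascending (length `k`; empty classes contribute 0).
#' A perfectly balanced classification gives a horizontal line.
#'
#' @param assignment 0-based label vector.
#' @param k number of classes.
#' @return Integer vector of length `k`, non-decreasing, summing to `n`.
#' @export
size_rank_curve <- function(assignment, k) {
  k <- as.integer(k)
  p <- check_labels(assignment, length(assignment), k)
  sort(class_sizes(p, k))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement between an inferred partition
#' and a reference partition; 1 exactly when the partitions are identical
#' up to relabeling, around 0 for independent partitions.
#'
#' @param p,truth label vectors of equal length (any label coding).
#' @return Scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(p, truth) {
  if (length(p) != length(truth)) {
    stop("partitions have different lengths", call. = FALSE)
  }
  tab <- table(p, truth)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  npairs <- choose(length(p), 2)
  expected <- a * b / npairs
  max_index <- (a + b) / 2
  if (max_index == expected) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / (max_index - expected)
}

#' Class average image
#'
#' Pixel-wise mean of the member images of one class (members are assumed
#' already aligned by the configured dissimilarity pipeline; no
#' re-alignment is performed). Averaging `s` aligned images of a common
#' signal reduces the noise variance about `s`-fold.
#'
#' @param stack an [image_stack()] or pixel matrix.
#' @param assignment 0-based label vector.
#' @param class_id 0-based class index.
#' @return `D x D` numeric matrix.
#' @export
class_average <- function(stack, assignment, class_id) {
  stack <- as_image_stack(stack)
  idx <- which(assignment == class_id)
  if (length(idx) == 0L) {
    stop("class ", class_id, " has no members", call. = FALSE)
  }
  D <- stack$image_side
  matrix(colMeans(stack$pixels[idx, , drop = FALSE]), D, D)
}

#' Evaluation report for a clustering run
#'
#' Bundles the benchmark's quality instruments: the normalized
#' within-class angular-distance histogram and its pooled mean (requires
#' ground-truth orientations), the ascending class-size curve and its
#' standard deviation, and the per-iteration membership-change trace.
#'
#' @param result an `"ack_clustering"` object, or a 0-based label vector.
#' @param orientations optional data frame with `phi`, `theta` per image.
#' @param k number of classes (taken from `result` when available).
#' @param bin_width histogram bin width in degrees.
#' @return List of class `"ack_evaluation"` with elements
#'   `angular_histogram` (or `NULL`), `size_curve`, `size_sd`,
#'   `sigma_trace`, `mean_angular`.
#' @export
evaluate_clustering <- function(result, orientations = NULL, k = NULL,
                                bin_width = 2) {
  if (inherits(result, "ack_clustering")) {
    labels <- result$labels
    k <- k %||% result$k
    sigma_trace <- result$sigma_history
  } else {
    labels <- as.integer(result)
    k <- as.integer(k %||% (max(labels) + 1L))
    sigma_trace <- numeric(0)
  }
  hist <- NULL
  if (!is.null(orientations)) {
    hist <- within_class_angular_histogram(labels, orientations, k, bin_width)
  }
  curve <- size_rank_curve(labels, k)
  structure(list(angular_histogram = hist,
                 size_curve = curve,
                 size_sd = stats::sd(curve),
                 sigma_trace = sigma_trace,
                 mean_angular = if (is.null(hist)) NA_real_ else hist$mean_angular,
                 bin_width = bin_width),
            class = "ack_evaluation")
}

#' @export
print.ack_evaluation <- function(x, ...) {
  cat("clustering evaluation\n")
  cat(sprintf("  class sizes: %s (sd %.2f)\n",
              paste(range(x$size_curve), collapse = " - "), x$size_sd))
  if (!is.null(x$angular_histogram)) {
    cat(sprintf("  mean within-class angular distance: %.2f deg over %d pairs\n",
                x$mean_angular, x$angular_histogram$n_pairs))
  }
  if (length(x$sigma_trace) > 0) {
    cat(sprintf("  sigma trace: %s\n",
                paste(signif(x$sigma_trace, 3), collapse = ", ")))
  }
  invisible(x)
}
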