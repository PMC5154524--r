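test_that("init_centroids selects distinct seeded images and validates k", {
  X <- rand_stack(5, 4, seed = 1)
  C <- init_centroids(X, 5, seed = 7)
  # k = n: the centroid set is a permutation of the images
  expect_setequal(attr(C, "init_indices"), 1:5)
  expect_equal(C[order(attr(C, "init_indices")), ], X, ignore_attr = TRUE)

  X2 <- rand_stack(100, 4, seed = 2)
  a <- init_centroids(X2, 10, seed = 42)
  b <- init_centroids(X2, 10, seed = 42)
  expect_identical(a, b)

  sets <- vapply(1:50, function(s) {
    paste(sort(attr(init_centroids(X2, 10, seed = s), "init_indices")),
          collapse = ",")
  }, character(1))
  expect_gt(length(unique(sets)), 1L)

  expect_error(init_centroids(X, 6, seed = 1), "k must satisfy")
  expect_error(init_centroids(X, 0, seed = 1), "k must satisfy")
})

test_that("nearest_assign takes the argmin with lowest-index ties", {
  # one image at the origin, centroids at distances 2, 1, 3 (1-D pixels)
  X <- matrix(0, 1, 1)
  C <- matrix(c(sqrt(2), 1, sqrt(3)), 3, 1)
  expect_identical(nearest_assign(X, C), 1L)

  # image identical to centroid 0
  C2 <- rbind(X[1, ], C[1, ])
  expect_identical(nearest_assign(X, C2), 0L)

  # exact tie between classes 1 and 2 -> lowest index wins
  C3 <- matrix(c(5, 1, 1), 3, 1)
  expect_identical(nearest_assign(X, C3), 1L)

  bad <- function(a, b) NaN
  expect_error(nearest_assign(X, C, dissim = bad), "non-finite dissimilarity")
})

test_that("update_centroids averages members and keeps empty-class centroids", {
  X <- matrix(c(0, 0, 2, 2), 2, 2, byrow = TRUE)
  C <- update_centroids(X, c(0L, 0L), k = 1)
  expect_equal(C, matrix(c(1, 1), 1, 2), ignore_attr = TRUE)

  # singleton class equals its member
  C2 <- update_centroids(X, c(0L, 1L), k = 2)
  expect_equal(C2, X, ignore_attr = TRUE)

  # brute-force per-class loop oracle on random labels
  X3 <- rand_stack(20, 4, seed = 3)
  set.seed(4)
  p <- sample(0:2, 20, replace = TRUE)
  got <- update_centroids(X3, p, k = 3)
  want <- t(vapply(0:2, function(j) colMeans(X3[p == j, , drop = FALSE]),
                   numeric(4)))
  expect_equal(got, want, tolerance = 1e-12, ignore_attr = TRUE)

  # empty class: previous centroid retained, error without one
  prev <- matrix(9, 2, 2)
  C4 <- update_centroids(X, c(0L, 0L), k = 2, prev_centroids = prev)
  expect_equal(C4[2, ], c(9, 9))
  expect_error(update_centroids(X, c(0L, 0L), k = 2), "empty")
})

test_that("characteristic dissimilarity averages per-image max-min spreads", {
  # every image equidistant from all centroids -> d_c = 0
  X <- matrix(c(0, 4), 2, 1)
  C <- matrix(c(2, 2), 2, 1)  # both centroids identical
  expect_equal(characteristic_dissimilarity(X, C, seed = 1), 0)

  # single image with centroid distances {1, 4, 2} -> t = 3
  X1 <- matrix(0, 1, 1)
  C1 <- matrix(c(1, 2, sqrt(2)), 3, 1)  # squared distances 1, 4, 2
  expect_equal(characteristic_dissimilarity(X1, C1, seed = 5), 3)

  # all per-image spreads equal c -> mean is c
  Xs <- matrix(c(0, 0), 2, 1)
  Cs <- matrix(c(1, 2), 2, 1)
  expect_equal(characteristic_dissimilarity(Xs, Cs, sample_size = 2, seed = 2), 3)

  expect_error(
    characteristic_dissimilarity(X1, matrix(numeric(0), 0, 1), seed = 1),
    "empty")
  expect_error(characteristic_dissimilarity(X1, C1, sample_size = 0, seed = 1),
               "sample_size")
})

test_that("constraint weight follows beta * d_c / floor(n/k)", {
  expect_equal(two_lambda_from_beta(0, 123.4, 50, 5), 0)
  expect_equal(two_lambda_from_beta(0.5, 100, 1000, 10), 0.5)
  # floor, not rounding: floor(10/3) = 3
  expect_equal(two_lambda_from_beta(1, 9, 10, 3), 3)
  expect_error(two_lambda_from_beta(0.5, 1, 3, 5), "floor")
  expect_error(two_lambda_from_beta(-1, 1, 10, 2), "beta")
})

test_that("constrained sweep applies the size-penalized argmin online", {
  # two_lambda = 0 reduces to nearest_assign, independent of visit order
  X <- rand_stack(30, 9, seed = 6)
  C <- init_centroids(X, 4, seed = 6)
  p0 <- nearest_assign(X, C)
  expect_identical(ack_assign_sweep(X, C, p0, 0), p0)
  set.seed(7)
  expect_identical(ack_assign_sweep(X, C, p0, 0, order = sample(30)), p0)

  # direct score evaluation: distances (1.0, 1.2), s' = (3, 0), 2L = 0.5
  # -> scores (2.5, 1.2) -> class 1
  Xd <- matrix(c(0, 0, 0, 0), 4, 1)
  Cd <- matrix(c(1, sqrt(1.2)), 2, 1)
  p <- c(0L, 0L, 0L, 0L)  # image 1 in class 0 with 3 classmates
  got <- ack_assign_sweep(Xd, Cd, p, two_lambda = 0.5, order = 1L)
  expect_identical(got[1], 1L)
  expect_identical(got[-1], p[-1])

  expect_error(ack_assign_sweep(Xd, Cd, p, -0.1), "nonnegative")
})

test_that("each sweep decision minimizes the full constrained objective", {
  # brute-force oracle: for every image in visit order, the chosen label is
  # the argmin of J over its candidate labels with all other labels fixed
  for (case in 1:100) {
    set.seed(case)
    n <- 6; k <- 2
    X <- matrix(rnorm(n * 4), n, 4)
    C <- init_centroids(X, k, seed = case)
    p <- nearest_assign(X, C)
    two_lambda <- runif(1, 0, 2)
    got <- ack_assign_sweep(X, C, p, two_lambda)
    # sequential replay with exhaustive objective evaluation
    want <- p
    for (i in 1:n) {
      Js <- vapply(0:(k - 1), function(j) {
        q <- want; q[i] <- j
        clustering_objective(X, C, q, lambda = two_lambda / 2)
      }, numeric(1))
      want[i] <- which.min(Js) - 1L
    }
    expect_identical(got, want)
  }
})

test_that("membership change fraction counts differing labels", {
  expect_equal(membership_change_fraction(c(0L, 1L), c(0L, 1L)), 0)
  expect_equal(membership_change_fraction(c(0L, 1L), c(1L, 0L)), 1)
  expect_equal(membership_change_fraction(rep(0L, 6), c(1L, 1L, 1L, 0L, 0L, 0L)),
               0.5)
  expect_error(membership_change_fraction(c(0L), c(0L, 1L)), "lengths")
})

test_that("objective combines dissimilarity and quadratic size terms", {
  # lambda = 0, every image equal to its centroid -> J = 0
  C <- matrix(c(0, 5), 2, 1)
  X <- C[c(1, 1, 2, 2), , drop = FALSE]
  p <- c(0L, 0L, 1L, 1L)
  expect_equal(clustering_objective(X, C, p, lambda = 0), 0)
  # lambda = 1, zero dissimilarities, sizes (2, 2) -> J = 8
  expect_equal(clustering_objective(X, C, p, lambda = 1), 8)
  # size skew raises the quadratic term: (9 + 1) - (4 + 4) = 2
  p_skew <- c(0L, 0L, 0L, 1L)
  X0 <- matrix(0, 4, 1); C0 <- matrix(0, 2, 1)
  expect_equal(clustering_objective(X0, C0, p_skew, lambda = 1) -
                 clustering_objective(X0, C0, p, lambda = 1), 2)
})

test_that("SPIDER size factors favor small classes and expel singletons", {
  # equal raw distances 1.0: own class s = 5 (factor 1.25) vs other class
  # s = 2 (factor 2/3) -> reassign to the smaller class
  Xd <- matrix(0, 7, 1)
  Cd <- matrix(c(1, 1), 2, 1)  # squared distance 1 to both centroids
  p <- c(0L, 0L, 0L, 0L, 0L, 1L, 1L)
  got <- spider_factor_assign(Xd, Cd, p, order = 1L)
  expect_identical(got[1], 1L)

  # very large own class: factor ~ 1, a clearly nearer own centroid wins
  s <- 1e6
  f_large <- s / (s - 1)
  expect_lt(abs(f_large - 1), 1e-5)

  # own singleton class leaves for any finite alternative
  p2 <- c(1L, 0L, 0L, 0L, 0L, 0L, 0L)
  got2 <- spider_factor_assign(Xd, Cd, p2, order = 1L)
  expect_identical(got2[1], 0L)
})

test_that("equal-size greedy assignment respects capacities and the sort order", {
  set.seed(11)
  X9 <- matrix(rnorm(9), 9, 1)
  C3 <- matrix(rnorm(3), 3, 1)
  expect_equal(sort(tabulate(eqk_assign(X9, C3) + 1, 3)), c(3, 3, 3))

  X10 <- matrix(rnorm(10), 10, 1)
  expect_equal(sort(tabulate(eqk_assign(X10, C3) + 1, 3)),
               c(3, 3, 4))

  # one attractive centroid: 5 of 6 images nearest to centroid 0, but the
  # capacity keeps sizes (3, 3) and the 3 closest images keep centroid 0
  X6 <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5, 9.9), 6, 1)
  C2 <- matrix(c(0, 10), 2, 1)
  p <- eqk_assign(X6, C2)
  expect_equal(tabulate(p + 1, 2), c(3, 3))
  expect_identical(p, c(0L, 0L, 0L, 1L, 1L, 1L))
})
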