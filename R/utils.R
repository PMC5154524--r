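# Internal helpers shared across the package.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so package calls never clobber user
# randomness. All randomness in the package flows through this helper.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Class sizes of a 0-based label vector.
class_sizes <- function(labels, k) {
  tabulate(labels + 1L, nbins = k)
}

check_labels <- function(labels, n, k) {
  labels <- as.integer(labels)
  if (length(labels) != n) {
    stop("assignment has length ", length(labels), " but the stack has ",
         n, " images", call. = FALSE)
  }
  if (any(labels < 0L) || any(labels >= k)) {
    stop("labels must lie in [0, k); found values outside [0, ", k, ")",
         call. = FALSE)
  }
  labels
}

`%||%` <- function(x, y) if (is.null(x)) y else x
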