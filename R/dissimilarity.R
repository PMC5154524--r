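#' Squared Euclidean dissimilarity between two flattened images
#'
#' The default dissimilarity of the clustering algorithms. Squaring (rather
#' than the plain Euclidean distance) makes the centroid mean-update step the
#' exact minimizer of the within-class term, so each sweep of the constrained
#' assignment provably does not increase the objective.
#'
#' @param a,b numeric vectors of equal length.
#' @return Nonnegative scalar `sum((a - b)^2)`.
#' @examples
#' squared_euclidean(c(0, 0), c(3, 4)) # 25
#' @export
squared_euclidean <- function(a, b) {
  if (length(a) != length(b)) {
    stop("vectors have lengths ", length(a), " and ", length(b), call. = FALSE)
  }
  sum((a - b)^2)
}

#' Rotation/translation search grid for aligned dissimilarity
#'
#' Defines the discrete in-plane transform space searched by
#' [aligned_dissim()]: rotations in steps of `rotation_step` degrees over
#' `[0, 360)` and integer shifts up to `max_shift` pixels in each direction.
#'
#' @param rotation_step rotation increment in degrees (> 0).
#' @param max_shift maximum absolute shift in pixels (>= 0).
#' @param shift_step shift increment in pixels (>= 1).
#' @return An object of class `"alignment_grid"`.
#' @export
alignment_grid <- function(rotation_step = 10, max_shift = 2L, shift_step = 1L) {
  if (rotation_step <= 0) stop("rotation_step must be positive", call. = FALSE)
  if (max_shift < 0) stop("max_shift must be nonnegative", call. = FALSE)
  if (shift_step < 1) stop("shift_step must be at least 1", call. = FALSE)
  structure(list(rotation_step = rotation_step,
                 max_shift = as.integer(max_shift),
                 shift_step = as.integer(shift_step)),
            class = "alignment_grid")
}

#' Dissimilarity specification
#'
#' Selects the dissimilarity used by the clustering algorithms:
#' `"sq_euclid"` (default; squared Euclidean on flattened pixels),
#' `"euclid"` (unsquared), or `"aligned"` (minimum squared Euclidean over
#' the in-plane rotation/translation grid of an [alignment_grid()], a
#' simplified multi-reference-alignment distance). A custom pairwise
#' function `fun(a, b)` on flattened image vectors may be supplied instead.
#'
#' @param method one of `"sq_euclid"`, `"euclid"`, `"aligned"`, `"custom"`.
#' @param grid an [alignment_grid()]; used only by `"aligned"`.
#' @param fun pairwise dissimilarity function for `method = "custom"`.
#' @return An object of class `"dissim_spec"`.
#' @export
dissim_spec <- function(method = c("sq_euclid", "euclid", "aligned", "custom"),
                        grid = alignment_grid(), fun = NULL) {
  if (is.function(method)) {
    fun <- method
    method <- "custom"
  } else {
    method <- match.arg(method)
  }
  if (method == "custom" && !is.function(fun)) {
    stop("a custom dissimilarity needs a pairwise function", call. = FALSE)
  }
  structure(list(method = method, grid = grid, fun = fun),
            class = "dissim_spec")
}

as_dissim_spec <- function(x) {
  if (inherits(x, "dissim_spec")) return(x)
  if (is.function(x)) return(dissim_spec(x))
  if (is.character(x)) return(dissim_spec(x))
  stop("cannot interpret 'dissim' argument", call. = FALSE)
}

# Fast all-pairs squared Euclidean distances between rows of X (n x d) and
# rows of C (k x d). The expansion can produce tiny negatives; clamp at 0.
cross_sqdist <- function(X, C) {
  D <- matrix(rowSums(X^2), nrow(X), nrow(C)) +
    matrix(rowSums(C^2), nrow(X), nrow(C), byrow = TRUE) -
    2 * tcrossprod(X, C)
  D[D < 0] <- 0
  D
}

# n x k dissimilarity matrix between stack rows and centroid rows.
dissim_matrix <- function(X, C, dissim, image_side = NULL, check = TRUE) {
  dissim <- as_dissim_spec(dissim)
  D <- switch(dissim$method,
    sq_euclid = cross_sqdist(X, C),
    euclid = sqrt(cross_sqdist(X, C)),
    aligned = aligned_dissim_matrix(X, C, dissim$grid, image_side),
    custom = {
      out <- matrix(0, nrow(X), nrow(C))
      for (i in seq_len(nrow(X))) {
        for (j in seq_len(nrow(C))) out[i, j] <- dissim$fun(X[i, ], C[j, ])
      }
      out
    })
  if (check && !all(is.finite(D))) {
    bad <- which(!is.finite(D), arr.ind = TRUE)[1L, ]
    stop("non-finite dissimilarity between image ", bad[1L],
         " and centroid ", bad[2L], call. = FALSE)
  }
  D
}

aligned_dissim_matrix <- function(X, C, grid, image_side) {
  D <- image_side %||% as.integer(round(sqrt(ncol(X))))
  if (is.na(D) || D^2 != ncol(X)) {
    stop("aligned dissimilarity needs square images", call. = FALSE)
  }
  out <- matrix(0, nrow(X), nrow(C))
  for (i in seq_len(nrow(X))) {
    transforms <- grid_transforms(matrix(X[i, ], D, D), grid)
    for (j in seq_len(nrow(C))) {
      ref <- C[j, ]
      out[i, j] <- min(vapply(transforms,
                              function(tv) sum((tv - ref)^2), numeric(1)))
    }
  }
  out
}

# All transformed versions of an image over the grid, as flattened vectors.
grid_transforms <- function(img, grid) {
  angles <- seq(0, 360 - grid$rotation_step, by = grid$rotation_step)
  shifts <- seq(-grid$max_shift, grid$max_shift, by = grid$shift_step)
  out <- vector("list", length(angles) * length(shifts)^2)
  m <- 0L
  for (ang in angles) {
    for (dx in shifts) {
      for (dy in shifts) {
        m <- m + 1L
        out[[m]] <- as.vector(transform_image(img, ang, dx, dy))
      }
    }
  }
  out
}

#' Rotate and shift a square image
#'
#' Rotates the image counterclockwise by `angle` degrees about the pixel at
#' 0-based position `(D %/% 2, D %/% 2)`, then translates by `(dx, dy)`
#' pixels, with bilinear interpolation and zero fill for pixels mapped from
#' outside the input. Coordinates are `(x, y) = (row - 1, column - 1)`.
#'
#' @param img `D x D` numeric matrix.
#' @param angle rotation in degrees, counterclockwise.
#' @param dx,dy translation in pixels along the first and second index.
#' @return Transformed `D x D` matrix.
#' @export
transform_image <- function(img, angle, dx = 0, dy = 0) {
  img <- as.matrix(img)
  D <- nrow(img)
  if (ncol(img) != D) stop("image must be square", call. = FALSE)
  ctr <- D %/% 2
  th <- angle * pi / 180
  co <- cos(th); si <- sin(th)
  # inverse map: source = R(-angle) %*% (target - shift - center) + center
  gx <- rep(0:(D - 1L), times = D) - dx - ctr
  gy <- rep(0:(D - 1L), each = D) - dy - ctr
  sx <- co * gx + si * gy + ctr
  sy <- -si * gx + co * gy + ctr
  bilinear_sample(img, sx, sy, D, D)
}

# Bilinear sampling of img at 0-based coordinates (sx, sy); zero outside.
bilinear_sample <- function(img, sx, sy, nr, nc) {
  D1 <- nrow(img); D2 <- ncol(img)
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  val <- function(xi, yi) {
    ok <- xi >= 0 & xi <= D1 - 1L & yi >= 0 & yi <= D2 - 1L
    v <- numeric(length(xi))
    v[ok] <- img[cbind(xi[ok] + 1L, yi[ok] + 1L)]
    v
  }
  out <- (1 - fx) * (1 - fy) * val(x0, y0) +
    fx * (1 - fy) * val(x0 + 1, y0) +
    (1 - fx) * fy * val(x0, y0 + 1) +
    fx * fy * val(x0 + 1, y0 + 1)
  matrix(out, nr, nc)
}

#' Alignment-minimized dissimilarity between an image and a reference
#'
#' The simplified multi-reference-alignment distance: the minimum of
#' [squared_euclidean()] between `transform_image(img, angle, dx, dy)` and
#' `ref` over every rotation and shift of the [alignment_grid()]. The grid
#' contains the identity transform, so the result never exceeds the
#' unaligned squared distance.
#'
#' @param img,ref `D x D` numeric matrices of equal size.
#' @param grid an [alignment_grid()].
#' @return Nonnegative scalar.
#' @export
aligned_dissim <- function(img, ref, grid = alignment_grid()) {
  img <- as.matrix(img); ref <- as.matrix(ref)
  if (!all(dim(img) == dim(ref))) {
    stop("image and reference must have the same shape", call. = FALSE)
  }
  rv <- as.vector(ref)
  min(vapply(grid_transforms(img, grid),
             function(tv) sum((tv - rv)^2), numeric(1)))
}
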