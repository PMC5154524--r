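#' Particle image stack
#'
#' Container for a set of `n` square grayscale particle images, stored as an
#' `n x d` matrix of flattened pixels with `d = D^2` for image side `D`.
#' Row `i` is image `i`, flattened column-major from its `D x D` matrix
#' form (the convention used by [get_image()] and [stack_from_images()]).
#'
#' @param pixels numeric matrix (or object coercible to one) with one image
#'   per row; a single image may be passed as a `D x D` matrix via
#'   [stack_from_images()].
#' @param image_side side length `D` in pixels. Defaults to `sqrt(ncol(pixels))`.
#' @return An object of class `"image_stack"` with elements `pixels` and
#'   `image_side`.
#' @examples
#' s <- image_stack(matrix(rnorm(5 * 16), 5, 16))
#' n_images(s)
#' @export
image_stack <- function(pixels, image_side = NULL) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 1L) {
    stop("an image stack needs at least one image", call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop("image pixels must all be finite", call. = FALSE)
  }
  if (is.null(image_side)) {
    image_side <- round(sqrt(ncol(pixels)))
    # non-square feature dimension: usable for clustering, but image-shaped
    # operations (get_image, MRC output, alignment) are unavailable
    if (image_side^2 != ncol(pixels)) image_side <- NA_integer_
  }
  image_side <- as.integer(image_side)
  if (!is.na(image_side) && (image_side < 1L || image_side^2 != ncol(pixels))) {
    stop("pixel dimension ", ncol(pixels), " is not the square of the image side ",
         image_side, call. = FALSE)
  }
  structure(list(pixels = pixels, image_side = image_side),
            class = "image_stack")
}

#' @rdname image_stack
#' @param x object to coerce: an `image_stack`, a numeric matrix of
#'   flattened images, or a list of `D x D` image matrices.
#' @export
as_image_stack <- function(x) {
  if (inherits(x, "image_stack")) return(x)
  if (is.list(x) && !is.data.frame(x)) return(stack_from_images(x))
  image_stack(x)
}

#' @rdname image_stack
#' @export
n_images <- function(x) nrow(as_image_stack(x)$pixels)

#' Extract one image of a stack as a matrix
#'
#' @param stack an [image_stack()].
#' @param i image index (1-based).
#' @return `D x D` numeric matrix.
#' @export
get_image <- function(stack, i) {
  stack <- as_image_stack(stack)
  D <- stack$image_side
  if (is.na(D)) stop("stack rows are not square images", call. = FALSE)
  matrix(stack$pixels[i, ], D, D)
}

#' Build a stack from a list of square image matrices
#'
#' @param images list of `D x D` numeric matrices with a common side `D`.
#' @return An [image_stack()].
#' @export
stack_from_images <- function(images) {
  if (is.matrix(images)) images <- list(images)
  sides <- vapply(images, function(im) nrow(as.matrix(im)), integer(1))
  if (length(unique(sides)) != 1L) {
    stop("all images must share the same side length", call. = FALSE)
  }
  px <- do.call(rbind, lapply(images, function(im) as.vector(as.matrix(im))))
  image_stack(px, image_side = sides[1L])
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("image_stack: %d images of %d x %d pixels\n",
              nrow(x$pixels), x$image_side, x$image_side))
  invisible(x)
}
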