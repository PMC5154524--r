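# Minimal MRC/MRCS (MRC2014, mode 2 float32) stack reader and writer.
# The environment offers no MRC-capable R package, so the 1024-byte header
# and the little-endian float payload are handled directly.

#' Read and write MRC/MRCS image stacks
#'
#' `write_mrc_stack()` writes an [image_stack()] as an MRC2014 mode-2
#' (float32) stack, slice `i` of the file being image `i`;
#' `read_mrc_stack()` reads such a file back. Round-tripping is lossless
#' for data already at float32 precision. Values are stored little-endian.
#'
#' @param stack an [image_stack()] or pixel matrix.
#' @param path file path (conventionally `.mrcs` for stacks).
#' @param pixel_size pixel size in Angstrom recorded in the cell header.
#' @return `read_mrc_stack()` returns an [image_stack()];
#'   `write_mrc_stack()` returns `path` invisibly.
#' @export
write_mrc_stack <- function(stack, path, pixel_size = 1.0) {
  stack <- as_image_stack(stack)
  D <- stack$image_side
  if (is.na(D)) stop("stack rows are not square images", call. = FALSE)
  n <- nrow(stack$pixels)
  vals <- as.vector(t(stack$pixels))  # image-major, slice by slice
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.double(x), con, size = 4, endian = "little")
  wi(c(D, D, n))                     # nx, ny, nz
  wi(2L)                             # mode 2: float32
  wi(c(0L, 0L, 0L))                  # nxstart, nystart, nzstart
  wi(c(D, D, n))                     # mx, my, mz
  wf(c(D, D, n) * pixel_size)        # cella
  wf(c(90, 90, 90))                  # cellb
  wi(c(1L, 2L, 3L))                  # mapc, mapr, maps
  wf(c(min(vals), max(vals), mean(vals)))  # dmin, dmax, dmean
  wi(c(0L, 0L))                      # ispg, nsymbt
  wi(rep(0L, 25))                    # extra (words 25-49)
  wf(c(0, 0, 0))                     # origin
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # machst: little-endian
  wf(stats::sd(vals))                # rms
  wi(0L)                             # nlabl
  writeBin(raw(800), con)            # labels
  wf(vals)
  invisible(path)
}

#' @rdname write_mrc_stack
#' @export
read_mrc_stack <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  ri <- function(k) readBin(con, "integer", n = k, size = 4, endian = "little")
  dims <- ri(3)
  mode <- ri(1)
  if (mode != 2L) {
    stop("unsupported MRC mode ", mode, " (only mode 2 float32 is handled)",
         call. = FALSE)
  }
  if (dims[1] != dims[2]) {
    stop("MRC slices are not square: nx = ", dims[1], ", ny = ", dims[2],
         call. = FALSE)
  }
  seek(con, 92)                      # nsymbt at byte offset 92
  nsymbt <- ri(1)
  seek(con, 1024 + nsymbt)
  nval <- prod(as.double(dims))
  vals <- readBin(con, "numeric", n = nval, size = 4, endian = "little")
  if (length(vals) != nval) {
    stop("MRC payload truncated: expected ", nval, " values, read ",
         length(vals), call. = FALSE)
  }
  image_stack(matrix(vals, nrow = dims[3], ncol = dims[1] * dims[2],
                     byrow = TRUE),
              image_side = dims[1])
}
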