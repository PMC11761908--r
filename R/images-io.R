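# Image reading and writing.
#
# Raw images are 8-bit PNG, held in R as H x W (grayscale) or H x W x 3 arrays
# of intensities in [0, 255]. Processed (normalized) images are real-valued in
# [0, 1] and stored losslessly in a minimal float32 container (".f32"):
# three little-endian int32 (H, W, C) followed by H*W*C little-endian float32
# values in R's column-major order. PNG is 8-bit in this stack, which would
# quantize the Box-Cox output; the container keeps full precision.

#' Read an image
#'
#' Reads an 8-bit PNG into an intensity array in `[0, 255]`, or a processed
#' `.f32` container into a real-valued array (whatever range it was written
#' with, `[0, 1]` for normalized images).
#'
#' @param path PNG or `.f32` file.
#' @return Numeric array, `H x W` or `H x W x C`.
#' @export
read_image <- function(path) {
  lw_assert(file.exists(path), "image file not found: ", path,
            class = "lwunet_io_error")
  if (grepl("\\.f32$", path)) return(read_f32(path))
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L && dim(x)[3] == 4L) x <- x[, , 1:3, drop = FALSE]
  x * 255
}

#' Write an image as 8-bit PNG
#'
#' @param img array with intensities in `[0, 255]`.
#' @param path output file.
#' @export
write_image_png <- function(img, path) {
  img <- pmin(pmax(img, 0), 255)
  png::writePNG(img / 255, path)
  invisible(path)
}

#' @rdname read_image
#' @param img real-valued array, `H x W` or `H x W x C`.
#' @export
write_f32 <- function(img, path) {
  d <- dim(img)
  lw_assert(!is.null(d) && length(d) %in% c(2L, 3L), "img must be 2-D or 3-D")
  if (length(d) == 2L) d <- c(d, 1L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(d), con, size = 4L, endian = "little")
  writeBin(as.numeric(img), con, size = 4L, endian = "little")
  invisible(path)
}

#' @rdname read_image
#' @export
read_f32 <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  d <- readBin(con, "integer", n = 3L, size = 4L, endian = "little")
  x <- readBin(con, "numeric", n = prod(d), size = 4L, endian = "little")
  if (d[3] == 1L) array(x, dim = d[1:2]) else array(x, dim = d)
}
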