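# Size standardization and Box-Cox intensity normalization.

# Interpolation weight matrix W (n_out x n_in) for 1-D bilinear resampling
# with the half-pixel-center convention: output center i maps to source
# coordinate (i - 0.5) * n_in / n_out + 0.5 (1-based), clamped at the edges.
# 2-D resizing is separable: Y = W_rows %*% X %*% t(W_cols). Constants are
# preserved because every row of W sums to 1.
bilinear_weights <- function(n_in, n_out) {
  stopifnot(n_in >= 1, n_out >= 1)
  i <- seq_len(n_out)
  src <- (i - 0.5) * n_in / n_out + 0.5
  i0 <- floor(src)
  frac <- src - i0
  # clamp: replicate edge samples
  frac[i0 < 1] <- 0; i0[i0 < 1] <- 1
  frac[i0 >= n_in] <- 0; i0[i0 >= n_in] <- n_in
  i1 <- pmin(i0 + 1, n_in)
  w <- matrix(0, n_out, n_in)
  w[cbind(i, i0)] <- w[cbind(i, i0)] + (1 - frac)
  w[cbind(i, i1)] <- w[cbind(i, i1)] + frac
  w
}

# Separable bilinear resampling of an H x W [x C [x N]] array.
resize_bilinear <- function(img, out_h, out_w) {
  d <- dim(img)
  if (is.null(d)) lw_stop("image must be a matrix or array")
  h <- d[1]; w <- d[2]
  wr <- bilinear_weights(h, out_h)
  wc <- bilinear_weights(w, out_w)
  rest <- if (length(d) > 2) prod(d[-(1:2)]) else 1L
  x <- matrix(img, nrow = h)                 # h x (w * rest)
  y <- wr %*% x                              # out_h x (w * rest)
  y <- array(y, dim = c(out_h, w, rest))
  y <- aperm(y, c(2, 1, 3))                  # w x out_h x rest
  y <- wc %*% matrix(y, nrow = w)            # out_w x (out_h * rest)
  y <- array(y, dim = c(out_w, out_h, rest))
  y <- aperm(y, c(2, 1, 3))
  if (length(d) == 2) dim(y) <- c(out_h, out_w) else dim(y) <- c(out_h, out_w, d[-(1:2)])
  y
}

#' Resize an image with bilinear interpolation
#'
#' Resamples an intensity grid to the requested size using separable bilinear
#' interpolation with half-pixel-centered sample positions. The channel count
#' is preserved and constant images stay constant.
#'
#' @param img `H x W` or `H x W x C` intensity array.
#' @param out_w,out_h target width and height in pixels (>= 1).
#' @return Array of dimension `out_h x out_w [x C]`.
#' @export
resize_image <- function(img, out_w, out_h) {
  lw_assert(!is.null(dim(img)) && all(dim(img) >= 1) && length(img) > 0,
            "empty or dimensionless image", class = "lwunet_input_error")
  lw_assert(out_w >= 1 && out_h >= 1, "output size must be >= 1",
            class = "lwunet_input_error")
  resize_bilinear(img, out_h, out_w)
}

#' Box-Cox parameters
#'
#' The power-transform parameter `lambda` (0.5 by default) and the positive
#' shift/scale applied to move 8-bit intensities into the strictly positive
#' domain the transform requires: a pixel value `v` in `[0, 255]` enters the
#' transform as `x = (v + epsilon_shift) / 256`.
#'
#' @param lambda transformation exponent; `lambda = 0` means the log transform.
#' @param epsilon_shift positive offset added before scaling (default 1).
#' @return A `lwunet_boxcox` parameter list.
#' @export
box_cox_params <- function(lambda = 0.5, epsilon_shift = 1) {
  lw_assert(is.numeric(lambda) && length(lambda) == 1 && is.finite(lambda),
            "lambda must be a finite scalar", class = "lwunet_input_error")
  lw_assert(epsilon_shift > 0, "epsilon_shift must be > 0",
            class = "lwunet_input_error")
  structure(list(lambda = lambda, epsilon_shift = epsilon_shift),
            class = "lwunet_boxcox")
}

# Raw power transform on the already-shifted positive domain.
box_cox_raw <- function(x, lambda) {
  if (lambda == 0) log(x) else (x^lambda - 1) / lambda
}

#' Box-Cox intensity normalization
#'
#' Maps each pixel `v` in `[0, 255]` to the positive domain
#' `x = (v + epsilon_shift)/256`, applies the power transform
#' `(x^lambda - 1)/lambda` (`log x` when `lambda = 0`), then min-max rescales
#' the result to `[0, 1]` per image. The mapping is strictly increasing in `v`
#' for any `lambda`, so pixel rank order is preserved.
#'
#' @param img intensity array in `[0, 255]`.
#' @param params a [box_cox_params()] object.
#' @return Real-valued array in `[0, 1]`, same shape as `img`.
#' @export
box_cox_transform <- function(img, params = box_cox_params()) {
  lw_assert(inherits(params, "lwunet_boxcox"), "params must be box_cox_params()",
            class = "lwunet_input_error")
  lw_assert(all(is.finite(img)) && min(img) >= 0 && max(img) <= 255,
            "intensities must be finite and in [0, 255]",
            class = "lwunet_input_error")
  x <- (img + params$epsilon_shift) / 256
  y <- box_cox_raw(x, params$lambda)
  if (!all(is.finite(y))) {
    lw_stop("Box-Cox transform produced non-finite values",
            class = "lwunet_numeric_error")
  }
  r <- range(y)
  if (r[2] > r[1]) (y - r[1]) / (r[2] - r[1]) else y * 0
}

#' Preprocess a dataset manifest
#'
#' Reads every image referenced by the manifest, resizes it to `size` x `size`,
#' applies [box_cox_transform()] and writes the normalized image as a float32
#' container (`.f32`) under `out_dir`. A new manifest pointing at the processed
#' files is written to `out_dir/manifest.csv` and returned. The run is a pure
#' function of the input bytes, the parameters and the size: rerunning it
#' produces byte-identical outputs.
#'
#' @param m a `lwunet_manifest` whose paths are readable images.
#' @param params a [box_cox_params()] object.
#' @param size output edge length in pixels (default 256).
#' @param out_dir directory for processed images (created if needed).
#' @return The output `lwunet_manifest`.
#' @export
preprocess_dataset <- function(m, params = box_cox_params(), size = 256,
                               out_dir) {
  lw_assert(inherits(m, "lwunet_manifest"), "m must be a manifest",
            class = "lwunet_input_error")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  failures <- character(0)
  out_paths <- character(nrow(m))
  for (i in seq_len(nrow(m))) {
    p <- m$path[i]
    out_paths[i] <- file.path(
      out_dir, paste0(tools::file_path_sans_ext(basename(p)), ".f32"))
    ok <- tryCatch({
      img <- read_image(p)
      img <- resize_image(img, size, size)
      img <- pmin(pmax(img, 0), 255)   # bilinear stays in hull; guard rounding
      norm <- box_cox_transform(img, params)
      write_f32(norm, out_paths[i])
      TRUE
    }, error = function(e) {
      failures <<- c(failures, paste0(p, ": ", conditionMessage(e)))
      FALSE
    })
  }
  if (length(failures) > 0) {
    lw_stop("preprocessing failed for ", length(failures), " record(s):\n",
            paste(failures, collapse = "\n"), class = "lwunet_io_error")
  }
  rec <- as.data.frame(m)
  rec$path <- out_paths
  out <- manifest(rec, image_size = size, seed = attr(m, "seed"))
  write_manifest(out, file.path(out_dir, "manifest.csv"))
  out
}
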