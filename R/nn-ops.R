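# Network primitives.
#
# Tensors are H x W x C arrays (single image) or H x W x C x N (mini-batch);
# all contracts are stated in H x W x C semantics. The depthwise 3x3
# convolution runs in compiled code (src/dwconv.cpp); the pointwise (1x1)
# convolution is a BLAS gemm per sample; batch norm and ReLU are vectorized
# per-channel array operations.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# --- shape plumbing -------------------------------------------------------

as_nhwcn <- function(x) {
  d <- dim(x)
  lw_assert(!is.null(d) && length(d) %in% c(2L, 3L, 4L),
            "expected an H x W [x C [x N]] array", class = "lwunet_shape_error")
  if (length(d) == 2L) dim(x) <- c(d, 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  x
}

restore_rank <- function(y, template_dim) {
  if (length(template_dim) == 3L) dim(y) <- dim(y)[1:3]
  if (length(template_dim) == 2L) dim(y) <- dim(y)[1:2]
  y
}

# --- depthwise / pointwise convolutions ----------------------------------

# Depthwise 3x3 convolution (stride 1, zero pad 1); compiled kernels in
# src/dwconv.cpp, operating on H x W x C x N arrays.
dwconv_fwd <- function(x, kd) dwconv_fwd_cpp(x, kd)
dwconv_bwd <- function(x, kd, dy) dwconv_bwd_cpp(x, kd, dy)

# Per-channel sum over space and batch: H x W x C x N -> length-C vector.
channel_sum <- function(x, hw, c, n) {
  rowSums(matrix(.colSums(x, hw, c * n), c, n))
}

# Broadcast a per-channel vector over an H x W x C x N array: the coefficient
# vector of length hw*c recycles over the batch dimension.
ch_rep <- function(v, hw) rep(v, each = hw)

# --- batch normalization --------------------------------------------------

# Per-channel batch norm on H x W x C x N arrays. Training mode uses
# mini-batch statistics over space and batch (biased variance, as is
# standard); eval mode uses the stored running statistics.
bn_fwd4 <- function(y, p, training, hw, cc, n) {
  if (training) {
    m <- hw * n
    mu <- channel_sum(y, hw, cc, n) / m
    xc <- y - ch_rep(mu, hw)
    v <- channel_sum(xc * xc, hw, cc, n) / m
  } else {
    mu <- p$run_mean
    v <- p$run_var
    xc <- y - ch_rep(mu, hw)
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- xc * ch_rep(invstd, hw)
  out <- xhat * ch_rep(p$gamma, hw) + ch_rep(p$beta, hw)
  list(out = out, xhat = xhat, invstd = invstd, mu = mu, var = v)
}

bn_bwd4 <- function(dy, cache, gamma, hw, cc, n) {
  m <- hw * n
  xhat <- cache$xhat
  dgamma <- channel_sum(dy * xhat, hw, cc, n)
  dbeta <- channel_sum(dy, hw, cc, n)
  dxhat <- dy * ch_rep(gamma, hw)
  mean1 <- channel_sum(dxhat, hw, cc, n) / m
  mean2 <- channel_sum(dxhat * xhat, hw, cc, n) / m
  dx <- (dxhat - ch_rep(mean1, hw) - xhat * ch_rep(mean2, hw)) *
    ch_rep(cache$invstd, hw)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# --- DSConv block ---------------------------------------------------------

#' Depthwise-separable convolution parameters
#'
#' One DSConv block holds `Cin` 3x3 depthwise kernels, a `Cin x Cout`
#' pointwise (1x1) mixing matrix, and the batch-norm state that follows the
#' convolutions (no convolution biases; BN supplies the shift). Weights are
#' He-initialized from the current RNG stream.
#'
#' @param cin,cout input and output channel counts.
#' @param init `"he"` (default) or `"zero"`.
#' @return A `lwunet_dsconv_params` list.
#' @export
dsconv_params <- function(cin, cout, init = "he") {
  lw_assert(cin >= 1 && cout >= 1, "channel counts must be >= 1",
            class = "lwunet_input_error")
  if (init == "he") {
    dw <- array(stats::rnorm(9 * cin, sd = sqrt(2 / 9)), c(3, 3, cin))
    pw <- matrix(stats::rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout)
  } else {
    dw <- array(0, c(3, 3, cin))
    pw <- matrix(0, cin, cout)
  }
  structure(list(dw = dw, pw = pw,
                 gamma = rep(1, cout), beta = rep(0, cout),
                 run_mean = rep(0, cout), run_var = rep(1, cout)),
            class = "lwunet_dsconv_params")
}

dsconv_fwd <- function(x, p, training = FALSE) {
  d <- dim(x)
  cin <- dim(p$dw)[3]
  lw_assert(d[3] == cin,
            "channel mismatch: input has ", d[3], ", block expects ", cin,
            class = "lwunet_shape_error")
  xd <- dwconv_fwd(x, p$dw)
  hw <- d[1] * d[2]
  cout <- ncol(p$pw)
  n <- d[4]
  y <- array(0, c(d[1], d[2], cout, n))
  for (i in seq_len(n)) {
    y[, , , i] <- matrix(xd[, , , i], hw, cin) %*% p$pw
  }
  bn <- bn_fwd4(y, p, training, hw, cout, n)
  out <- bn$out
  out[out < 0] <- 0
  list(y = out,
       cache = list(x = x, xd = xd, bn = bn, relu_in = bn$out, d = d,
                    cout = cout))
}

dsconv_bwd <- function(dy, p, cache) {
  d <- cache$d
  hw <- d[1] * d[2]
  cin <- d[3]
  cout <- cache$cout
  n <- d[4]
  dy <- dy * (cache$relu_in > 0)
  bnb <- bn_bwd4(dy, cache$bn, p$gamma, hw, cout, n)
  dpw <- matrix(0, cin, cout)
  dxd <- array(0, d)
  for (i in seq_len(n)) {
    gi <- matrix(bnb$dx[, , , i], hw, cout)
    xdi <- matrix(cache$xd[, , , i], hw, cin)
    dpw <- dpw + crossprod(xdi, gi)
    dxd[, , , i] <- tcrossprod(gi, p$pw)
  }
  dwb <- dwconv_bwd(cache$x, p$dw, dxd)
  list(dx = dwb$dx,
       grads = list(dw = dwb$dkd, pw = dpw,
                    gamma = bnb$dgamma, beta = bnb$dbeta))
}

# Update running BN stats after a training-mode forward pass.
dsconv_update_running <- function(p, cache, momentum = BN_MOMENTUM) {
  p$run_mean <- (1 - momentum) * p$run_mean + momentum * cache$bn$mu
  p$run_var <- (1 - momentum) * p$run_var + momentum * cache$bn$var
  p
}

#' Depthwise-separable convolution block
#'
#' Applies a 3x3 depthwise convolution (stride 1, zero padding 1), a 1x1
#' pointwise convolution expanding/reducing channels, batch normalization
#' (mini-batch statistics in training mode, running statistics otherwise) and
#' ReLU. Spatial dimensions are preserved.
#'
#' @param X `H x W x C` feature map (a batch axis may be appended).
#' @param p a [dsconv_params()] block whose `Cin` matches `X`'s channels.
#' @param training_mode logical; selects the batch-norm statistics.
#' @return Feature map `H x W x Cout`.
#' @export
dsconv_block <- function(X, p, training_mode = FALSE) {
  x4 <- as_nhwcn(X)
  out <- dsconv_fwd(x4, p, training = training_mode)
  restore_rank(out$y, dim(X))
}

# --- pooling / resampling / concat ---------------------------------------

avgpool_fwd <- function(x) {
  d <- dim(x)
  lw_assert(d[1] %% 2 == 0 && d[2] %% 2 == 0,
            "spatial dims must be even for 2x2 pooling",
            class = "lwunet_shape_error")
  io <- seq(1, d[1], by = 2); jo <- seq(1, d[2], by = 2)
  (x[io, jo, , , drop = FALSE] + x[io + 1, jo, , , drop = FALSE] +
     x[io, jo + 1, , , drop = FALSE] + x[io + 1, jo + 1, , , drop = FALSE]) / 4
}

avgpool_bwd <- function(dy, in_dim) {
  dx <- array(0, in_dim)
  io <- seq(1, in_dim[1], by = 2); jo <- seq(1, in_dim[2], by = 2)
  g <- dy / 4
  dx[io, jo, , ] <- g
  dx[io + 1, jo, , ] <- g
  dx[io, jo + 1, , ] <- g
  dx[io + 1, jo + 1, , ] <- g
  dx
}

#' Average-pool downsampling
#'
#' Halves both spatial dimensions with a 2x2 mean-pooling kernel at stride 2.
#'
#' @param X `H x W x C` feature map with even `H` and `W`.
#' @return `(H/2) x (W/2) x C` feature map.
#' @export
downsample_avgpool <- function(X) {
  restore_rank(avgpool_fwd(as_nhwcn(X)), dim(X))
}

apply_separable <- function(x, wr, wc) {
  d <- dim(x)
  rest <- prod(d[-(1:2)])
  y <- wr %*% matrix(x, d[1], d[2] * rest)
  y <- array(y, c(nrow(wr), d[2], rest))
  y <- aperm(y, c(2, 1, 3))
  y <- wc %*% matrix(y, d[2], nrow(wr) * rest)
  y <- aperm(array(y, c(nrow(wc), nrow(wr), rest)), c(2, 1, 3))
  dim(y) <- c(nrow(wr), nrow(wc), d[-(1:2)])
  y
}

up2_fwd <- function(x) {
  d <- dim(x)
  wr <- bilinear_weights(d[1], 2L * d[1])
  wc <- bilinear_weights(d[2], 2L * d[2])
  apply_separable(x, wr, wc)
}

# Exact adjoint of up2_fwd (bilinear upsampling is a fixed linear map).
up2_bwd <- function(dy, in_dim) {
  wr <- bilinear_weights(in_dim[1], 2L * in_dim[1])
  wc <- bilinear_weights(in_dim[2], 2L * in_dim[2])
  apply_separable(dy, t(wr), t(wc))
}

#' Bilinear 2x upsampling
#'
#' Doubles both spatial dimensions by separable bilinear interpolation
#' (half-pixel-center convention). Constant maps stay constant.
#'
#' @param X `H x W x C` feature map.
#' @return `2H x 2W x C` feature map.
#' @export
upsample_bilinear <- function(X) {
  restore_rank(up2_fwd(as_nhwcn(X)), dim(X))
}

#' Channel concatenation of decoder and skip features
#'
#' Stacks the upsampled decoder map and the matching encoder map along the
#' channel axis; the first block of output channels is `up`, the second `enc`.
#'
#' @param up,enc feature maps with identical spatial dimensions.
#' @return Feature map with `C_up + C_enc` channels.
#' @export
concat_skip <- function(up, enc) {
  u <- as_nhwcn(up); e <- as_nhwcn(enc)
  du <- dim(u); de <- dim(e)
  lw_assert(all(du[c(1, 2, 4)] == de[c(1, 2, 4)]),
            "spatial/batch mismatch in skip concatenation",
            class = "lwunet_shape_error")
  out <- array(0, c(du[1], du[2], du[3] + de[3], du[4]))
  out[, , seq_len(du[3]), ] <- u
  out[, , du[3] + seq_len(de[3]), ] <- e
  if (length(dim(up)) == 3L && length(dim(enc)) == 3L) dim(out) <- dim(out)[1:3]
  out
}

# --- head -----------------------------------------------------------------

gap_fwd <- function(x) {
  d <- dim(x)
  m <- colMeans(matrix(x, d[1] * d[2], d[3] * d[4]))
  matrix(m, d[3], d[4])   # C x N
}

gap_bwd <- function(dpooled, in_dim) {
  hw <- in_dim[1] * in_dim[2]
  array(rep(as.numeric(dpooled), each = hw) / hw, in_dim)
}

#' Fully-connected classification head parameters
#'
#' @param channels decoder output channels feeding the head.
#' @param num_classes number of classes (default 2).
#' @param init `"he"` or `"zero"`.
#' @return A `lwunet_head_params` list with `Wfc` (`channels x num_classes`)
#'   and `bfc` (`num_classes`).
#' @export
head_params <- function(channels, num_classes = 2, init = "he") {
  Wfc <- if (init == "he") {
    matrix(stats::rnorm(channels * num_classes, sd = sqrt(2 / channels)),
           channels, num_classes)
  } else matrix(0, channels, num_classes)
  structure(list(Wfc = Wfc, bfc = rep(0, num_classes)),
            class = "lwunet_head_params")
}

#' Global-average-pool + fully-connected classification head
#'
#' Averages each channel over all spatial positions, then applies the affine
#' map `Wfc' pooled + bfc`.
#'
#' @param Ydec `H x W x C` decoder output (batch axis allowed).
#' @param head a [head_params()] object with `C` rows.
#' @return Numeric score vector of length `num_classes` (or a
#'   `num_classes x N` matrix for a batch).
#' @export
classify_head <- function(Ydec, head) {
  x4 <- as_nhwcn(Ydec)
  pooled <- gap_fwd(x4)   # C x N
  lw_assert(nrow(head$Wfc) == nrow(pooled),
            "head dimensions do not match decoder channels",
            class = "lwunet_shape_error")
  scores <- crossprod(head$Wfc, pooled) + head$bfc   # K x N
  if (length(dim(Ydec)) <= 3L) as.numeric(scores) else scores
}

# --- loss -----------------------------------------------------------------

# Softmax cross-entropy. scores: K x N; labels: integer class index 1..K.
# Returns mean loss, accuracy, and d(loss)/d(scores).
softmax_ce <- function(scores, labels) {
  k <- nrow(scores); n <- ncol(scores)
  s <- sweep(scores, 2, apply(scores, 2, max))
  es <- exp(s)
  p <- sweep(es, 2, colSums(es), `/`)
  idx <- cbind(labels, seq_len(n))
  pt <- p[cbind(labels, seq_len(n))]
  loss <- -mean(log(pmax(pt, 1e-12)))
  pred <- apply(scores, 2, which.max)
  dscores <- p
  dscores[idx] <- dscores[idx] - 1
  dscores <- dscores / n
  list(loss = loss, acc = mean(pred == labels), dscores = dscores,
       prob = p, pred = pred)
}
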