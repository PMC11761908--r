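# Independent reference implementations used as oracles. These are written
# as naive per-pixel loops, deliberately sharing no code with the package
# internals they check.

# Naive separable bilinear resize, half-pixel-center convention.
naive_bilinear_resize <- function(img, out_h, out_w) {
  d <- dim(img)
  if (length(d) == 2L) {
    out <- matrix(0, out_h, out_w)
    for (i in seq_len(out_h)) {
      for (j in seq_len(out_w)) {
        si <- (i - 0.5) * d[1] / out_h + 0.5
        sj <- (j - 0.5) * d[2] / out_w + 0.5
        i0 <- floor(si); fi <- si - i0
        j0 <- floor(sj); fj <- sj - j0
        if (i0 < 1) { i0 <- 1; fi <- 0 }
        if (i0 >= d[1]) { i0 <- d[1]; fi <- 0 }
        if (j0 < 1) { j0 <- 1; fj <- 0 }
        if (j0 >= d[2]) { j0 <- d[2]; fj <- 0 }
        i1 <- min(i0 + 1, d[1]); j1 <- min(j0 + 1, d[2])
        out[i, j] <- (1 - fi) * (1 - fj) * img[i0, j0] +
          fi * (1 - fj) * img[i1, j0] +
          (1 - fi) * fj * img[i0, j1] +
          fi * fj * img[i1, j1]
      }
    }
    return(out)
  }
  out <- array(0, c(out_h, out_w, d[3]))
  for (c in seq_len(d[3])) {
    out[, , c] <- naive_bilinear_resize(img[, , c], out_h, out_w)
  }
  out
}

# Direct nested-summation depthwise + pointwise convolution (3x3 depthwise,
# stride 1, zero pad 1; 1x1 pointwise), the raw two-stage factorized
# convolution before normalization.
naive_dsconv_raw <- function(x, dw, pw) {
  h <- dim(x)[1]; w <- dim(x)[2]; cin <- dim(x)[3]; cout <- ncol(pw)
  xd <- array(0, c(h, w, cin))
  for (i in seq_len(h)) for (j in seq_len(w)) for (c in seq_len(cin)) {
    s <- 0
    for (m in 1:3) for (n in 1:3) {
      ii <- i + m - 2; jj <- j + n - 2
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w) {
        s <- s + x[ii, jj, c] * dw[m, n, c]
      }
    }
    xd[i, j, c] <- s
  }
  z <- array(0, c(h, w, cout))
  for (i in seq_len(h)) for (j in seq_len(w)) for (k in seq_len(cout)) {
    z[i, j, k] <- sum(xd[i, j, ] * pw[, k])
  }
  z
}

# Count the multiplications a depthwise-separable layer performs by literal
# enumeration of its two stages on an h x w map.
naive_dsconv_mult_count <- function(h, w, cin, cout, k = 3) {
  n <- 0
  for (i in seq_len(h)) for (j in seq_len(w)) {
    n <- n + cin * k * k   # depthwise: k x k multiplies per input channel
    n <- n + cin * cout    # pointwise: cin multiplies per output channel
  }
  n
}

# A DSConv block with neutral batch-norm (eval mode, zero running mean, unit
# running variance) so the convolution arithmetic is exposed up to the exact
# 1/sqrt(1 + eps) normalization factor.
neutral_dsconv_params <- function(dw, pw) {
  cout <- ncol(pw)
  p <- dsconv_params(dim(dw)[3], cout, init = "zero")
  p$dw <- dw
  p$pw <- pw
  p
}

BN_EPS_TEST <- 1e-5
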