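test_that("a delta-kernel identity block reduces to ReLU", {
  set.seed(1)
  cc <- 3
  dw <- array(0, c(3, 3, cc)); dw[2, 2, ] <- 1
  p <- neutral_dsconv_params(dw, diag(cc))
  x <- array(rnorm(6 * 6 * cc), c(6, 6, cc))
  out <- dsconv_block(x, p, training_mode = FALSE)
  expect_equal(out, pmax(x, 0) / sqrt(1 + BN_EPS_TEST), tolerance = 1e-4)
})

test_that("DSConv output equals the direct nested-summation oracle", {
  set.seed(7)
  cases <- list(c(5, 5, 2, 3), c(8, 8, 4, 4), c(4, 7, 3, 2), c(8, 3, 1, 5))
  for (cs in cases) {
    x <- array(rnorm(cs[1] * cs[2] * cs[3]), cs[1:3])
    dw <- array(rnorm(9 * cs[3]), c(3, 3, cs[3]))
    pw <- matrix(rnorm(cs[3] * cs[4]), cs[3], cs[4])
    z <- naive_dsconv_raw(x, dw, pw)
    expected <- pmax(z / sqrt(1 + BN_EPS_TEST), 0)
    got <- dsconv_block(x, neutral_dsconv_params(dw, pw))
    expect_lt(max(abs(got - expected)), 1e-5)
  }
  # channel mismatch is a shape error
  p <- neutral_dsconv_params(array(0, c(3, 3, 2)), matrix(0, 2, 4))
  expect_error(dsconv_block(array(0, c(4, 4, 3)), p),
               class = "lwunet_shape_error")
})

test_that("parameter counts follow Cin*K^2 + Cin*Cout + 2*Cout", {
  set.seed(1)
  p <- dsconv_params(3, 16)
  expect_equal(length(p$dw) + length(p$pw) + length(p$gamma) + length(p$beta),
               107)
  mc <- model_config(base_channels = 16)
  model <- init_model(mc, seed = 1)
  expect_equal(count_parameters(model), count_parameters_formula(mc))
  # depthwise-separable layers are smaller than standard 3x3 convolutions
  ch <- lwunet:::layer_channels(mc)
  std <- sum(vapply(ch, function(io) io[1] * io[2] * 9 + 2 * io[2], 0)) +
    16 * 2 + 2
  expect_lt(count_parameters(model), std)
})

test_that("multiply-count ratio is 1/Cout + 1/K^2", {
  cnt <- conv_multiply_counts(6, 5, 3, 8)
  expect_equal(cnt$dsconv, naive_dsconv_mult_count(6, 5, 3, 8))
  expect_equal(cnt$ratio, 1 / 8 + 1 / 9)
  cnt2 <- conv_multiply_counts(4, 4, 16, 32, k = 3)
  expect_equal(cnt2$ratio, 1 / 32 + 1 / 9)
  expect_equal(cnt2$dsconv, naive_dsconv_mult_count(4, 4, 16, 32))
})

test_that("average pooling halves dimensions and averages 2x2 blocks", {
  expect_equal(as.numeric(downsample_avgpool(array(c(1, 3, 2, 4), c(2, 2, 1)))),
               2.5)
  cst <- downsample_avgpool(array(3.7, c(8, 8, 2)))
  expect_equal(dim(cst), c(4, 4, 2))
  expect_true(all(cst == 3.7))
  ramp <- array(0:15, c(4, 4, 1))
  got <- downsample_avgpool(ramp)
  brute <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    brute[i, j] <- mean(ramp[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), 1])
  }
  expect_equal(got[, , 1], brute)
  expect_error(downsample_avgpool(array(0, c(5, 4, 1))),
               class = "lwunet_shape_error")
})

test_that("bilinear upsampling doubles dimensions and preserves constants", {
  cst <- upsample_bilinear(array(2.5, c(4, 4, 3)))
  expect_equal(dim(cst), c(8, 8, 3))
  expect_true(all(abs(cst - 2.5) < 1e-12))
  expect_equal(dim(upsample_bilinear(array(0, c(8, 8, 4)))), c(16, 16, 4))
  x <- array(c(1, 3, 2, 4), c(2, 2, 1))
  expect_equal(upsample_bilinear(x)[, , 1],
               naive_bilinear_resize(x[, , 1], 4, 4), tolerance = 1e-12)
})

test_that("skip concatenation stacks channels in order", {
  up <- array(rnorm(32 * 32 * 16), c(32, 32, 16))
  enc <- array(rnorm(32 * 32 * 8), c(32, 32, 8))
  out <- concat_skip(up, enc)
  expect_equal(dim(out), c(32, 32, 24))
  expect_identical(out[, , 1:16], up)
  expect_identical(out[, , 17:24], enc)
  expect_error(concat_skip(up, array(0, c(16, 16, 8))),
               class = "lwunet_shape_error")
})

test_that("the classification head is pool-then-affine", {
  x <- array(rep(c(1.5, -2, 4), each = 16), c(4, 4, 3))
  h <- head_params(3, 3, init = "zero")
  h$Wfc <- diag(3)
  expect_equal(classify_head(x, h), c(1.5, -2, 4))
  h0 <- head_params(3, 2, init = "zero")
  h0$bfc <- c(0.3, -0.7)
  expect_equal(classify_head(x, h0), c(0.3, -0.7))
  set.seed(5)
  x <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  h <- head_params(3, 2)
  pooled <- apply(x, 3, mean)
  expect_equal(classify_head(x, h),
               as.numeric(t(h$Wfc) %*% pooled + h$bfc), tolerance = 1e-12)
  expect_error(classify_head(array(0, c(4, 4, 5)), h),
               class = "lwunet_shape_error")
})

test_that("the network has 9 DSConv layers with schedule C0*{1,2,4,8,16}", {
  mc <- model_config(base_channels = 16, input_size = 64)
  model <- init_model(mc, seed = 2)
  expect_equal(n_dsconv_layers(model), 9L)
  x <- lwunet:::as_nhwcn(array(runif(64 * 64 * 3), c(64, 64, 3)))
  fwd <- lwunet:::forward_model(model, x)
  expect_equal(fwd$enc_channels, c(16L, 32L, 64L, 128L))
  expect_equal(ncol(model$layers$bottleneck$pw), 256L)
  # spatial dims halve four times through the encoder
  for (i in 1:4) {
    expect_equal(fwd$cache[[paste0("pool", i, "_in_dim")]][1], 64L / 2^(i - 1))
  }
  # decoder restores them level by level back to the input resolution
  expect_equal(fwd$cache$gap_in_dim[1:2], c(64L, 64L))
})

test_that("forward is size-agnostic through global pooling", {
  mc <- model_config(base_channels = 4, input_size = 256)
  model <- init_model(mc, seed = 3)
  s256 <- forward(array(runif(256 * 256 * 3), c(256, 256, 3)), model)
  expect_length(s256, 2)
  s64 <- forward(array(runif(64 * 64 * 3), c(64, 64, 3)), model)
  expect_length(s64, 2)
  expect_error(forward(array(0, c(40, 40, 3)), model),
               class = "lwunet_shape_error")
})

test_that("analytic gradients match finite differences", {
  set.seed(11)
  mc <- model_config(base_channels = 2, input_size = 16)
  model <- init_model(mc, seed = 4)
  x <- array(runif(16 * 16 * 3 * 2), c(16, 16, 3, 2))
  y <- c(1, 2)
  loss_of <- function(m) {
    lwunet:::softmax_ce(lwunet:::forward_model(m, x, training = TRUE)$scores,
                        y)$loss
  }
  fwd <- lwunet:::forward_model(model, x, training = TRUE)
  gr <- lwunet:::backward_model(model, fwd,
                                lwunet:::softmax_ce(fwd$scores, y)$dscores)
  eps <- 1e-6
  probes <- list(
    c("enc1", "dw"), c("enc2", "pw"), c("enc4", "gamma"), c("bottleneck", "pw"),
    c("dec4", "dw"), c("dec2", "beta"), c("dec1", "pw"))
  for (pr in probes) {
    arr <- model$layers[[pr[1]]][[pr[2]]]
    idx <- sample(length(arr), 1)
    m2 <- model; m2$layers[[pr[1]]][[pr[2]]][idx] <- arr[idx] + eps
    lp <- loss_of(m2)
    m2$layers[[pr[1]]][[pr[2]]][idx] <- arr[idx] - eps
    lm <- loss_of(m2)
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(gr[[pr[1]]][[pr[2]]][idx] - num) / max(abs(num), 1e-6), 1e-4)
  }
})

test_that("checkpoints round-trip bit-for-bit", {
  mc <- model_config(base_channels = 2, input_size = 32)
  model <- init_model(mc, seed = 6)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  f <- tempfile(fileext = ".ckpt")
  save_checkpoint(model, f)
  loaded <- load_checkpoint(f)
  expect_identical(forward(x, loaded), forward(x, model))
  expect_true(file.exists(paste0(f, ".json")))
})
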