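# GAN-side computations: adaptive instance normalization, logistic
# discriminator losses, feature-matching loss, gradient penalty, Frechet
# distance between Gaussian-fitted image embeddings, and a desk-scale
# mini-GAN (MLP generator/discriminator) that exercises all of them with
# exact analytic gradients — including the double-backprop term the gradient
# penalty requires.

#' Adaptive instance normalization
#'
#' Standardizes a feature-map channel to zero mean / unit standard deviation
#' (population sd), then rescales by the style scale `ys` and shifts by the
#' style bias `yb`: `ys * (x - mean(x)) / sd(x) + yb`. A constant channel is
#' stabilized by `sigma_eps` and maps to the constant `yb`.
#'
#' @param x numeric array/vector with at least 2 elements (one channel).
#' @param ys style scale.
#' @param yb style bias.
#' @param sigma_eps positive stabilizer added to the standard deviation.
#' @return Array of the same shape; mean `yb`, sd `|ys|` (up to `sigma_eps`).
#' @export
adain <- function(x, ys, yb, sigma_eps = 1e-8) {
  lw_assert(length(x) >= 2, "channel needs at least 2 pixels",
            class = "lwunet_input_error")
  lw_assert(sigma_eps > 0, "sigma_eps must be > 0", class = "lwunet_input_error")
  mu <- mean(x)
  sg <- sqrt(mean((x - mu)^2))
  ys * (x - mu) / (sg + sigma_eps) + yb
}

#' Logistic discriminator probabilities
#'
#' Elementwise logistic map of discriminator logits to probabilities in
#' (0, 1), computed in a numerically stable form.
#'
#' @param logits finite numeric vector.
#' @return Probabilities `1 / (1 + exp(-logits))`.
#' @export
discriminator_probability <- function(logits) {
  lw_assert(all(is.finite(logits)), "logits must be finite",
            class = "lwunet_input_error")
  ifelse(logits >= 0, 1 / (1 + exp(-logits)),
         exp(logits) / (1 + exp(logits)))
}

# Numerically stable softplus log(1 + exp(x)).
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Non-saturating logistic discriminator losses
#'
#' `L_real = mean(-log sigmoid(d_real))`, `L_fake = mean(-log(1 -
#' sigmoid(d_fake)))`, `L_total = L_real + L_fake`, evaluated through
#' softplus so no log argument ever reaches 0.
#'
#' @param d_real_logits,d_fake_logits finite discriminator logits.
#' @return List `(L_real, L_fake, L_total)`.
#' @export
discriminator_losses <- function(d_real_logits, d_fake_logits) {
  lw_assert(all(is.finite(c(d_real_logits, d_fake_logits))),
            "logits must be finite", class = "lwunet_input_error")
  l_real <- mean(softplus(-d_real_logits))
  l_fake <- mean(softplus(d_fake_logits))
  list(L_real = l_real, L_fake = l_fake, L_total = l_real + l_fake)
}

#' Feature-matching loss
#'
#' Squared Euclidean distance between the mean feature vectors of real and
#' generated samples under a fixed feature extractor.
#'
#' @param phi_real_mean,phi_fake_mean equal-length mean feature vectors.
#' @return Non-negative scalar, 0 iff the means are equal.
#' @export
feature_matching_loss <- function(phi_real_mean, phi_fake_mean) {
  lw_assert(length(phi_real_mean) == length(phi_fake_mean),
            "feature dimensions differ", class = "lwunet_shape_error")
  sum((phi_real_mean - phi_fake_mean)^2)
}

#' Gradient penalty
#'
#' Mean of `(||grad|| - 1)^2` over gradient norms of the discriminator taken
#' at interpolates between real and generated samples (the Lipschitz
#' regularizer).
#'
#' @param grad_norms non-negative gradient norms.
#' @return Scalar penalty.
#' @export
gradient_penalty <- function(grad_norms) {
  lw_assert(all(grad_norms >= 0), "gradient norms must be >= 0",
            class = "lwunet_input_error")
  mean((grad_norms - 1)^2)
}

# --- Frechet distance -----------------------------------------------------

#' Gaussian summary of an embedding set
#'
#' @param x `n x d` matrix of embedding vectors (rows = samples, `n >= 2`).
#' @return A `lwunet_gaussian_stats` list: mean vector `mu`, covariance
#'   `sigma` (unbiased, `n - 1` denominator), sample count `n`.
#' @export
gaussian_stats <- function(x) {
  x <- as.matrix(x)
  lw_assert(nrow(x) >= 2, "need at least 2 samples", class = "lwunet_input_error")
  structure(list(mu = colMeans(x), sigma = stats::cov(x), n = nrow(x)),
            class = "lwunet_gaussian_stats")
}

#' Frechet distance between two Gaussians
#'
#' `||mu_r - mu_g||^2 + Tr(Sigma_r + Sigma_g - 2 (Sigma_r Sigma_g)^{1/2})`.
#' The matrix square root is taken by eigendecomposition of the symmetrized
#' product `Sigma_r^{1/2} Sigma_g Sigma_r^{1/2}`; eigenvalues below
#' `-1e-8 * max(1, |lambda|_max)` raise an error, smaller negatives (sampling
#' noise) are clamped to 0, and the final score is clamped at 0.
#'
#' @param real,gen `lwunet_gaussian_stats` (or lists with `mu`, `sigma`) of
#'   equal embedding dimension.
#' @return Non-negative scalar; 0 for identical statistics.
#' @export
fid_score <- function(real, gen) {
  mu_r <- real$mu; mu_g <- gen$mu
  s_r <- as.matrix(real$sigma); s_g <- as.matrix(gen$sigma)
  lw_assert(length(mu_r) == length(mu_g) && all(dim(s_r) == dim(s_g)),
            "embedding dimensions differ", class = "lwunet_shape_error")
  lw_assert(all(is.finite(s_r)) && all(is.finite(s_g)),
            "non-finite covariance", class = "lwunet_numeric_error")
  s_r <- (s_r + t(s_r)) / 2
  s_g <- (s_g + t(s_g)) / 2
  er <- eigen(s_r, symmetric = TRUE)
  r_half <- er$vectors %*% (sqrt(pmax(er$values, 0)) * t(er$vectors))
  s <- r_half %*% s_g %*% r_half
  ev <- eigen((s + t(s)) / 2, symmetric = TRUE, only.values = TRUE)$values
  tol <- 1e-8 * max(1, abs(ev))
  lw_assert(min(ev) > -tol, "covariance product is not PSD within tolerance",
            class = "lwunet_numeric_error")
  fid <- sum((mu_r - mu_g)^2) + sum(diag(s_r)) + sum(diag(s_g)) -
    2 * sum(sqrt(pmax(ev, 0)))
  max(fid, 0)
}

#' Embed images for Frechet-distance computation
#'
#' `"pixels"`: each image is scaled to `[0, 1]` and flattened into a vector
#' of length `H * W * C` — a deterministic, download-free embedding;
#' optionally the image is first bilinearly resized to `size x size` and/or
#' channel-averaged to grayscale to keep the covariance dimension small.
#' `"encoder"`: images (normalized to `[0, 1]`, resized to the model's input
#' size) are passed through a trained model's encoder + bottleneck and
#' globally average-pooled into a `16 * C0`-dimensional vector.
#'
#' @param images list of `H x W [x C]` arrays in `[0, 255]`, or a
#'   `lwunet_manifest` whose images are read from disk.
#' @param embedding `"pixels"` or `"encoder"`.
#' @param size optional pixel-embedding edge length (`NULL` keeps the native
#'   size).
#' @param gray average channels to grayscale before flattening.
#' @param model a `lwunet_model` (required for `"encoder"`).
#' @return `n x d` embedding matrix.
#' @export
embed_images <- function(images, embedding = c("pixels", "encoder"),
                         size = NULL, gray = FALSE, model = NULL) {
  embedding <- match.arg(embedding)
  if (inherits(images, "lwunet_manifest")) {
    images <- lapply(images$path, read_image)
  }
  lw_assert(length(images) >= 1, "no images to embed",
            class = "lwunet_input_error")
  if (embedding == "pixels") {
    rows <- lapply(images, function(img) {
      if (gray && length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
      if (!is.null(size)) img <- resize_bilinear(img, size, size)
      as.numeric(img) / 255
    })
    return(do.call(rbind, rows))
  }
  lw_assert(inherits(model, "lwunet_model"),
            "encoder embedding needs a trained model",
            class = "lwunet_config_error")
  insz <- model$config$input_size
  rows <- lapply(images, function(img) {
    if (length(dim(img)) == 2L) {
      img <- array(img, c(dim(img), model$config$in_channels))
    }
    x <- as_nhwcn(resize_bilinear(img, insz, insz) / 255)
    h <- x
    for (i in 1:4) {
      h <- avgpool_fwd(dsconv_fwd(h, model$layers[[paste0("enc", i)]])$y)
    }
    h <- dsconv_fwd(h, model$layers$bottleneck)$y
    as.numeric(gap_fwd(h))
  })
  do.call(rbind, rows)
}

#' Frechet distance between two image sets
#'
#' Convenience wrapper: embeds both sets with [embed_images()] and returns
#' [fid_score()] between their Gaussian summaries.
#'
#' @param a,b image lists, manifests, or directories of PNG files.
#' @param ... passed to [embed_images()].
#' @return Scalar Frechet distance.
#' @export
fid_between <- function(a, b, ...) {
  load_set <- function(s) {
    if (is.character(s) && length(s) == 1 && dir.exists(s)) {
      files <- list.files(s, pattern = "\\.(png|f32)$", full.names = TRUE)
      lw_assert(length(files) >= 2, "need at least 2 images in ", s,
                class = "lwunet_input_error")
      return(lapply(sort(files), read_image))
    }
    if (is.character(s) && length(s) == 1 && file.exists(s)) {
      return(read_manifest(s))
    }
    s
  }
  ea <- embed_images(load_set(a), ...)
  eb <- embed_images(load_set(b), ...)
  fid_score(gaussian_stats(ea), gaussian_stats(eb))
}

# --- MLP machinery for the mini-GAN --------------------------------------

lrelu <- function(x, alpha = 0.2) ifelse(x > 0, x, alpha * x)
lrelu_grad <- function(a, alpha = 0.2) ifelse(a > 0, 1, alpha)

mlp_init <- function(sizes) {
  n <- length(sizes) - 1
  layers <- vector("list", n)
  for (l in seq_len(n)) {
    layers[[l]] <- list(
      W = matrix(stats::rnorm(sizes[l + 1] * sizes[l],
                              sd = sqrt(2 / sizes[l])), sizes[l + 1], sizes[l]),
      b = rep(0, sizes[l + 1]))
  }
  layers
}

# x: d x N. Hidden layers leaky-ReLU; the final layer is linear, optionally
# squashed by a sigmoid (generator output).
mlp_forward <- function(net, x, final = c("linear", "sigmoid"), alpha = 0.2) {
  final <- match.arg(final)
  L <- length(net)
  a <- vector("list", L); h <- vector("list", L + 1)
  h[[1]] <- x
  for (l in seq_len(L)) {
    a[[l]] <- net[[l]]$W %*% h[[l]] + net[[l]]$b
    h[[l + 1]] <- if (l < L) lrelu(a[[l]], alpha)
    else if (final == "sigmoid") 1 / (1 + exp(-a[[l]])) else a[[l]]
  }
  list(out = h[[L + 1]], a = a, h = h, final = final, alpha = alpha)
}

# dout: gradient at the network output. Returns parameter grads and dx.
mlp_backward <- function(net, fwd, dout) {
  L <- length(net)
  grads <- vector("list", L)
  d <- dout
  if (fwd$final == "sigmoid") {
    s <- fwd$out
    d <- d * s * (1 - s)
  }
  for (l in L:1) {
    grads[[l]] <- list(W = d %*% t(fwd$h[[l]]), b = rowSums(d))
    if (l > 1) {
      d <- (t(net[[l]]$W) %*% d) * lrelu_grad(fwd$a[[l - 1]], fwd$alpha)
    } else {
      d <- t(net[[l]]$W) %*% d
    }
  }
  list(grads = grads, dx = d)
}

# Gradient of the scalar discriminator output w.r.t. its input, per sample.
# Assumes final linear layer with a single output unit.
mlp_input_grad <- function(net, fwd) {
  L <- length(net)
  s <- matrix(1, 1, ncol(fwd$out))
  slist <- vector("list", L)
  slist[[L]] <- s
  for (l in L:2) {
    s <- (t(net[[l]]$W) %*% s) * lrelu_grad(fwd$a[[l - 1]], fwd$alpha)
    slist[[l - 1]] <- s
  }
  list(g = t(net[[1]]$W) %*% s, s = slist)
}

# Analytic gradient of the gradient penalty w.r.t. the discriminator weights
# (double backprop). With piecewise-linear activations the input gradient is
# g = W1' D1 W2' D2 ... WL' and, holding the activation masks fixed (exact
# almost everywhere), dP/dWl = s_l t_{l-1}' / N with s_l the usual backward
# chain and t_l the forward chain seeded by r = dP/dg.
gp_weight_grads <- function(net, fwd, ig) {
  L <- length(net)
  n <- ncol(fwd$out)
  g <- ig$g
  norms <- sqrt(colSums(g^2))
  penalty <- mean((norms - 1)^2)
  r <- sweep(g, 2, 2 * (norms - 1) / pmax(norms, 1e-12), `*`) / n
  tl <- vector("list", L)  # tl[[l]] = t_{l-1}
  tl[[1]] <- r
  for (l in seq_len(L - 1)) {
    tl[[l + 1]] <- (net[[l]]$W %*% tl[[l]]) * lrelu_grad(fwd$a[[l]], fwd$alpha)
  }
  grads <- vector("list", L)
  for (l in seq_len(L)) {
    grads[[l]] <- list(W = ig$s[[l]] %*% t(tl[[l]]), b = rep(0, nrow(net[[l]]$W)))
  }
  list(grads = grads, penalty = penalty, norms = norms)
}

adam_init_mlp <- function(net) {
  lapply(net, function(l) list(W = list(m = l$W * 0, v = l$W * 0),
                               b = list(m = l$b * 0, v = l$b * 0)))
}

adam_step_mlp <- function(net, grads, st, t, lr, beta1 = 0.5, beta2 = 0.999,
                          eps = 1e-8) {
  bc1 <- 1 - beta1^t; bc2 <- 1 - beta2^t
  for (l in seq_along(net)) {
    for (f in c("W", "b")) {
      g <- grads[[l]][[f]]
      st[[l]][[f]]$m <- beta1 * st[[l]][[f]]$m + (1 - beta1) * g
      st[[l]][[f]]$v <- beta2 * st[[l]][[f]]$v + (1 - beta2) * g^2
      net[[l]][[f]] <- net[[l]][[f]] -
        lr * (st[[l]][[f]]$m / bc1) / (sqrt(st[[l]][[f]]$v / bc2) + eps)
    }
  }
  list(net = net, st = st)
}

add_grads <- function(a, b, scale = 1) {
  for (l in seq_along(a)) {
    a[[l]]$W <- a[[l]]$W + scale * b[[l]]$W
    a[[l]]$b <- a[[l]]$b + scale * b[[l]]$b
  }
  a
}

#' Mini-GAN configuration
#'
#' @param latent_dim standard-normal latent dimension.
#' @param steps training steps.
#' @param batch_size samples per step.
#' @param lr Adam learning rate (both networks).
#' @param lambda_fm feature-matching loss weight on the generator.
#' @param lambda_gp gradient-penalty weight on the discriminator.
#' @param fid_every record a pixel-embedding Frechet distance every this many
#'   steps (plus before the first and after the last step).
#' @param fid_n samples per Frechet evaluation.
#' @param fid_pixel_size pixel-embedding edge length for the trace (default 8).
#' @param seed integer seed.
#' @return A `lwunet_mini_gan_config` list.
#' @export
mini_gan_config <- function(latent_dim = 32, steps = 500, batch_size = 32,
                            lr = 2e-4, lambda_fm = 1, lambda_gp = 10,
                            fid_every = 100, fid_n = 128, fid_pixel_size = 8,
                            seed = 1) {
  structure(as.list(environment()), class = "lwunet_mini_gan_config")
}

#' Train a desk-scale mini-GAN
#'
#' Adversarial training of an MLP generator (latent -> 128 -> 256 -> pixels,
#' sigmoid output) against an MLP discriminator (pixels -> 128 -> 64 -> 1,
#' leaky-ReLU hidden layers) on small grayscale images, with the
#' non-saturating logistic losses, a feature-matching term on the
#' discriminator's last hidden layer, and a gradient penalty on interpolates
#' (exact analytic double-backprop). Fully seeded and deterministic.
#'
#' @param m a `lwunet_manifest` (>= 100 training images, edge <= 64) or an
#'   `n x npix` matrix of flattened grayscale images in `[0, 1]`.
#' @param config a [mini_gan_config()].
#' @param image_size edge length when `m` is a matrix.
#' @return A `lwunet_mini_gan` bundle: `generator`, `discriminator`,
#'   `losses` (per-step data frame), `fid_trace`, `config`, `image_size`.
#' @export
train_mini_gan <- function(m, config = mini_gan_config(), image_size = NULL) {
  if (inherits(m, "lwunet_manifest")) {
    rec <- m[m$split == "train", ]
    lw_assert(nrow(rec) >= 100, "need at least 100 training images",
              class = "lwunet_input_error")
    image_size <- attr(m, "image_size")
    lw_assert(is.finite(image_size) && image_size <= 64,
              "mini-GAN expects images of edge <= 64",
              class = "lwunet_input_error")
    x <- do.call(rbind, lapply(rec$path, function(p) {
      img <- read_image(p)
      if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
      as.numeric(img) / 255
    }))
  } else {
    x <- as.matrix(m)
    lw_assert(!is.null(image_size), "image_size required for matrix input",
              class = "lwunet_input_error")
  }
  npix <- ncol(x)
  cfg <- config
  with_seed(cfg$seed, {
    G <- mlp_init(c(cfg$latent_dim, 128, 256, npix))
    D <- mlp_init(c(npix, 128, 64, 1))
    stG <- adam_init_mlp(G); stD <- adam_init_mlp(D)
    losses <- vector("list", cfg$steps)
    fid_trace <- list()
    pixel_fid <- function(step) {
      z <- matrix(stats::rnorm(cfg$latent_dim * cfg$fid_n), cfg$latent_dim)
      fake <- mlp_forward(G, z, final = "sigmoid")$out   # npix x n
      idx <- sample(nrow(x), min(cfg$fid_n, nrow(x)))
      to_imgs <- function(mat_cols) {
        lapply(seq_len(ncol(mat_cols)), function(i) {
          matrix(mat_cols[, i] * 255, image_size, image_size)
        })
      }
      er <- embed_images(to_imgs(t(x[idx, , drop = FALSE])),
                         size = cfg$fid_pixel_size)
      ef <- embed_images(to_imgs(fake), size = cfg$fid_pixel_size)
      fid_trace[[length(fid_trace) + 1]] <<-
        data.frame(step = step,
                   fid = fid_score(gaussian_stats(er), gaussian_stats(ef)))
    }
    pixel_fid(0L)
    for (step in seq_len(cfg$steps)) {
      idx <- sample(nrow(x), cfg$batch_size, replace = nrow(x) < cfg$batch_size)
      xr <- t(x[idx, , drop = FALSE])                     # npix x B
      z <- matrix(stats::rnorm(cfg$latent_dim * cfg$batch_size), cfg$latent_dim)
      gf <- mlp_forward(G, z, final = "sigmoid")
      xf <- gf$out
      # --- discriminator update ---
      fr <- mlp_forward(D, xr)
      ff <- mlp_forward(D, xf)
      dl <- discriminator_losses(as.numeric(fr$out), as.numeric(ff$out))
      B <- cfg$batch_size
      d_real <- matrix(-discriminator_probability(-as.numeric(fr$out)) / B,
                       1, B)
      d_fake <- matrix(discriminator_probability(as.numeric(ff$out)) / B, 1, B)
      gD <- add_grads(mlp_backward(D, fr, d_real)$grads,
                      mlp_backward(D, ff, d_fake)$grads)
      eps_mix <- matrix(stats::runif(B), npix, B, byrow = TRUE)
      xh <- eps_mix * xr + (1 - eps_mix) * xf
      fh <- mlp_forward(D, xh)
      gp <- gp_weight_grads(D, fh, mlp_input_grad(D, fh))
      gD <- add_grads(gD, gp$grads, scale = cfg$lambda_gp)
      sD <- adam_step_mlp(D, gD, stD, step, cfg$lr)
      D <- sD$net; stD <- sD$st
      # --- generator update (fresh discriminator pass on same fakes) ---
      gf <- mlp_forward(G, z, final = "sigmoid")
      xf <- gf$out
      ff <- mlp_forward(D, xf)
      fr <- mlp_forward(D, xr)
      g_adv <- matrix(-discriminator_probability(-as.numeric(ff$out)) / B, 1, B)
      back_adv <- mlp_backward(D, ff, g_adv)
      phi_real <- rowMeans(fr$h[[3]])
      phi_fake <- rowMeans(ff$h[[3]])
      fm <- feature_matching_loss(phi_real, phi_fake)
      # inject d(fm)/d(phi_fake) at D's second hidden layer and push to input
      d_phi <- matrix(-2 * (phi_real - phi_fake) / B, ncol = 1)[, rep(1, B)]
      d <- d_phi * lrelu_grad(ff$a[[2]], ff$alpha)
      d <- t(D[[2]]$W) %*% d * lrelu_grad(ff$a[[1]], ff$alpha)
      dxf_fm <- t(D[[1]]$W) %*% d
      dxf <- back_adv$dx + cfg$lambda_fm * dxf_fm
      gG <- mlp_backward(G, gf, dxf)$grads
      sG <- adam_step_mlp(G, gG, stG, step, cfg$lr)
      G <- sG$net; stG <- sG$st
      g_loss <- mean(softplus(-as.numeric(ff$out)))
      losses[[step]] <- data.frame(step = step, d_real = dl$L_real,
                                   d_fake = dl$L_fake, d_total = dl$L_total,
                                   gp = gp$penalty, g_adv = g_loss, fm = fm)
      if (!all(is.finite(unlist(losses[[step]])))) {
        lw_stop("mini-GAN diverged (non-finite loss) at step ", step,
                class = "lwunet_numeric_error")
      }
      if (step %% cfg$fid_every == 0 || step == cfg$steps) pixel_fid(step)
    }
    structure(list(generator = G, discriminator = D,
                   losses = do.call(rbind, losses),
                   fid_trace = do.call(rbind, fid_trace),
                   config = cfg, image_size = image_size),
              class = "lwunet_mini_gan")
  })
}

#' Sample images from a trained mini-GAN
#'
#' @param bundle a `lwunet_mini_gan`.
#' @param n number of images.
#' @param seed optional seed for the latent draws.
#' @return List of `size x size` grayscale matrices in `[0, 255]`.
#' @export
sample_mini_gan <- function(bundle, n, seed = NULL) {
  with_seed(seed, {
    z <- matrix(stats::rnorm(bundle$config$latent_dim * n),
                bundle$config$latent_dim)
    out <- mlp_forward(bundle$generator, z, final = "sigmoid")$out
    lapply(seq_len(n), function(i) {
      matrix(out[, i] * 255, bundle$image_size, bundle$image_size)
    })
  })
}
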