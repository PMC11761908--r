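test_that("adain standardizes then restyles a channel", {
  set.seed(1)
  x <- rnorm(200, mean = 3, sd = 2)
  # inverse of standardization recovers the input
  mu <- mean(x); sg <- sqrt(mean((x - mu)^2))
  expect_equal(adain(x, ys = sg, yb = mu), x, tolerance = 1e-6)
  z <- adain(x, 1, 0)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-6)
  # zero-variance path is stabilized, no exception
  cst <- adain(rep(2, 10), ys = 1, yb = 5)
  expect_equal(cst, rep(5, 10))
  expect_error(adain(1, 1, 0), class = "lwunet_input_error")
})

test_that("discriminator losses match their closed forms", {
  l0 <- discriminator_losses(0, 0)
  expect_equal(l0$L_real, log(2))
  expect_equal(l0$L_fake, log(2))
  expect_equal(l0$L_total, 2 * log(2))
  expect_lt(discriminator_losses(50, -50)$L_total, 1e-8)
  set.seed(2)
  dr <- rnorm(40); df <- rnorm(40)
  l <- discriminator_losses(dr, df)
  expect_equal(l$L_real, mean(-log(1 / (1 + exp(-dr)))), tolerance = 1e-12)
  expect_equal(l$L_fake, mean(-log(1 - 1 / (1 + exp(-df)))), tolerance = 1e-12)
  expect_equal(l$L_total, l$L_real + l$L_fake)
})

test_that("discriminator probabilities are logistic and symmetric", {
  expect_equal(discriminator_probability(0), 0.5)
  expect_gt(discriminator_probability(40), 1 - 1e-12)
  x <- seq(-5, 5, by = 0.5)
  expect_equal(discriminator_probability(x) + discriminator_probability(-x),
               rep(1, length(x)), tolerance = 1e-12)
})

test_that("feature-matching loss is the squared distance between means", {
  expect_equal(feature_matching_loss(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(feature_matching_loss(c(1, 0), c(0, 0)), 1)
  set.seed(3)
  a <- rnorm(16); b <- rnorm(16)
  expect_equal(feature_matching_loss(a, b), sum((a - b)^2))
  expect_error(feature_matching_loss(1:3, 1:4), class = "lwunet_shape_error")
})

test_that("gradient penalty has its closed-form values", {
  expect_equal(gradient_penalty(rep(1, 8)), 0)
  expect_equal(gradient_penalty(rep(2, 8)), 1)
  expect_equal(gradient_penalty(rep(0, 8)), 1)
  expect_error(gradient_penalty(c(1, -0.1)), class = "lwunet_input_error")
})

test_that("the penalty's weight gradient matches numerical differentiation", {
  set.seed(4)
  npix <- 10
  D <- lwunet:::mlp_init(c(npix, 8, 6, 1))
  x <- matrix(runif(npix * 4), npix, 4)
  gp_of <- function(net) {
    fwd <- lwunet:::mlp_forward(net, x)
    g <- lwunet:::mlp_input_grad(net, fwd)$g
    mean((sqrt(colSums(g^2)) - 1)^2)
  }
  fwd <- lwunet:::mlp_forward(D, x)
  gp <- lwunet:::gp_weight_grads(D, fwd, lwunet:::mlp_input_grad(D, fwd))
  expect_equal(gp$penalty, gp_of(D), tolerance = 1e-12)
  eps <- 1e-6
  for (l in 1:3) for (rep in 1:3) {
    i <- sample(nrow(D[[l]]$W), 1); j <- sample(ncol(D[[l]]$W), 1)
    D2 <- D
    D2[[l]]$W[i, j] <- D2[[l]]$W[i, j] + eps
    lp <- gp_of(D2)
    D2[[l]]$W[i, j] <- D2[[l]]$W[i, j] - 2 * eps
    lm <- gp_of(D2)
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(gp$grads[[l]]$W[i, j] - num) / max(abs(num), 1e-6), 1e-4)
  }
})

test_that("the Frechet distance has its closed forms and oracle agreement", {
  set.seed(5)
  a <- matrix(rnorm(200 * 3), 200, 3)
  sa <- gaussian_stats(a)
  expect_equal(fid_score(sa, sa), 0, tolerance = 1e-10)
  # 1-D unit Gaussians one apart
  expect_equal(fid_score(list(mu = 0, sigma = matrix(1)),
                         list(mu = 1, sigma = matrix(1))), 1)
  # 3-D random case vs an independent eigendecomposition implementation
  b <- matrix(rnorm(200 * 3, mean = 0.4), 200, 3) %*%
    matrix(c(1, 0.3, 0, 0.3, 1, 0.2, 0, 0.2, 1), 3)
  sb <- gaussian_stats(b)
  oracle <- function(s1, s2) {
    ev <- eigen(s1$sigma %*% s2$sigma)$values
    sum((s1$mu - s2$mu)^2) + sum(diag(s1$sigma)) + sum(diag(s2$sigma)) -
      2 * sum(sqrt(pmax(Re(ev), 0)))
  }
  expect_equal(fid_score(sa, sb), oracle(sa, sb), tolerance = 1e-6)
  # symmetry and joint-translation invariance
  expect_equal(fid_score(sa, sb), fid_score(sb, sa), tolerance = 1e-10)
  shift <- c(5, -2, 1)
  sa2 <- sa; sa2$mu <- sa$mu + shift
  sb2 <- sb; sb2$mu <- sb$mu + shift
  expect_equal(fid_score(sa2, sb2), fid_score(sa, sb), tolerance = 1e-9)
  expect_error(fid_score(sa, list(mu = 1:2, sigma = diag(2))),
               class = "lwunet_shape_error")
})

test_that("pixel embeddings flatten H*W*C and are deterministic", {
  set.seed(6)
  imgs <- lapply(1:4, function(i) array(runif(8 * 8 * 3, 0, 255), c(8, 8, 3)))
  e <- embed_images(imgs)
  expect_equal(dim(e), c(4, 8 * 8 * 3))
  expect_identical(gaussian_stats(e), gaussian_stats(embed_images(imgs)))
  e2 <- embed_images(imgs, size = 4, gray = TRUE)
  expect_equal(dim(e2), c(4, 16))
  expect_error(embed_images(imgs, embedding = "encoder"),
               class = "lwunet_config_error")
})

test_that("encoder embeddings pool the bottleneck to 16*C0 dimensions", {
  mc <- model_config(base_channels = 2, input_size = 32)
  model <- init_model(mc, seed = 9)
  imgs <- lapply(1:3, function(i) {
    lwunet:::with_seed(i, array(runif(16 * 16 * 3, 0, 255), c(16, 16, 3)))
  })
  e <- embed_images(imgs, embedding = "encoder", model = model)
  expect_equal(dim(e), c(3, 16 * 2))
  expect_identical(e, embed_images(imgs, embedding = "encoder", model = model))
})

test_that("same-class draws are closer in Frechet distance than cross-class draws", {
  gen_set <- function(label, seed, n = 200) {
    lwunet:::with_seed(seed, lapply(seq_len(n), function(i) {
      spec <- lwunet:::sample_lesion_spec(label, "USI", 32)
      render_modality(make_lesion_mask(spec, 32), "USI")
    }))
  }
  st <- function(imgs) gaussian_stats(embed_images(imgs, size = 16))
  benign1 <- st(gen_set("benign", 101))
  benign2 <- st(gen_set("benign", 202))
  malignant <- st(gen_set("malignant", 303))
  expect_lt(fid_score(benign1, benign2), fid_score(benign1, malignant))
})

test_that("the mini-GAN trains deterministically with finite losses and falling FID", {
  dir <- file.path(tempdir(), "lwunet-gan")
  m <- generate_dataset(80, size = 32, seed = 21, out_dir = dir,
                        train_fraction = 0.8, modalities = "USI")
  cfg <- mini_gan_config(steps = 500, fid_every = 250, seed = 13)
  b <- train_mini_gan(m, cfg)
  expect_true(all(is.finite(as.matrix(b$losses[, -1]))))
  expect_equal(nrow(b$losses), 500)
  fid0 <- b$fid_trace$fid[b$fid_trace$step == 0]
  fid_final <- b$fid_trace$fid[b$fid_trace$step == 500]
  expect_lt(fid_final, fid0)
  # identical seeds give identical traces
  b2 <- train_mini_gan(m, cfg)
  expect_identical(b$losses, b2$losses)
  expect_identical(b$fid_trace, b2$fid_trace)
  imgs <- sample_mini_gan(b, 3, seed = 1)
  expect_length(imgs, 3)
  expect_equal(dim(imgs[[1]]), c(32, 32))
  expect_error(train_mini_gan(m[1:50, ], cfg), class = "lwunet_input_error")
  unlink(dir, recursive = TRUE)
})
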