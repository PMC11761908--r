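# The nine-layer depthwise-separable encoder/decoder classifier.
#
# Encoder: four DSConv blocks with channel schedule C0, 2*C0, 4*C0, 8*C0,
# each followed by 2x2 average-pool downsampling. Bottleneck: one DSConv
# mapping 8*C0 -> 16*C0. Decoder: four levels, each bilinearly upsampling
# 2x, concatenating the matching encoder map, and applying a DSConv that
# brings the channels back down (24*C0 -> 8*C0, 12*C0 -> 4*C0, 6*C0 -> 2*C0,
# 3*C0 -> C0). Head: global average pool + fully-connected layer. Exactly
# nine DSConv layers execute in any instantiation.

#' Model configuration
#'
#' @param in_channels input image channels (default 3).
#' @param base_channels first encoder output width `C0` (default 16).
#' @param num_classes output classes (default 2).
#' @param input_size input edge length; must be divisible by 16 because the
#'   encoder halves the resolution four times.
#' @return A `lwunet_model_config` list.
#' @export
model_config <- function(in_channels = 3, base_channels = 16, num_classes = 2,
                         input_size = 256) {
  lw_assert(base_channels >= 1, "base_channels must be >= 1",
            class = "lwunet_input_error")
  lw_assert(input_size %% 16 == 0, "input_size must be divisible by 16",
            class = "lwunet_shape_error")
  structure(list(in_channels = as.integer(in_channels),
                 base_channels = as.integer(base_channels),
                 num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 kernel_size = 3L, encoder_depth = 4L),
            class = "lwunet_model_config")
}

# Per-layer (cin, cout) schedule for a given C0.
layer_channels <- function(config) {
  c0 <- config$base_channels
  list(enc1 = c(config$in_channels, c0),
       enc2 = c(c0, 2 * c0),
       enc3 = c(2 * c0, 4 * c0),
       enc4 = c(4 * c0, 8 * c0),
       bottleneck = c(8 * c0, 16 * c0),
       dec4 = c(24 * c0, 8 * c0),
       dec3 = c(12 * c0, 4 * c0),
       dec2 = c(6 * c0, 2 * c0),
       dec1 = c(3 * c0, c0))
}

#' Instantiate a model
#'
#' Creates all layer parameters (nine DSConv blocks plus the FC head) with
#' seeded He initialization.
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialization.
#' @return A `lwunet_model` list with `config`, `layers`, `head`.
#' @export
init_model <- function(config = model_config(), seed = 1) {
  with_seed(seed, {
    ch <- layer_channels(config)
    layers <- lapply(ch, function(io) dsconv_params(io[1], io[2]))
    head <- head_params(config$base_channels, config$num_classes)
    structure(list(config = config, layers = layers, head = head),
              class = "lwunet_model")
  })
}

#' Number of DSConv layers in a model
#' @param model a `lwunet_model`.
#' @return Integer layer count (always 9 by construction).
#' @export
n_dsconv_layers <- function(model) length(model$layers)

#' Count trainable parameters
#'
#' Enumerates every trainable array in the model (depthwise kernels,
#' pointwise matrices, batch-norm scale and shift, FC weights and biases;
#' running statistics are not trainable).
#'
#' @param model a `lwunet_model`.
#' @return Exact integer parameter count.
#' @export
count_parameters <- function(model) {
  n <- 0L
  for (p in model$layers) {
    n <- n + length(p$dw) + length(p$pw) + length(p$gamma) + length(p$beta)
  }
  n + length(model$head$Wfc) + length(model$head$bfc)
}

#' Closed-form parameter count
#'
#' Layer-by-layer sum of `Cin*K^2 + Cin*Cout + 2*Cout` over the nine DSConv
#' blocks plus `C0*num_classes + num_classes` for the head; an independent
#' check on [count_parameters()].
#'
#' @param config a [model_config()].
#' @return Integer parameter count.
#' @export
count_parameters_formula <- function(config = model_config()) {
  ch <- layer_channels(config)
  k2 <- config$kernel_size^2
  n <- sum(vapply(ch, function(io) io[1] * k2 + io[1] * io[2] + 2 * io[2], 0))
  as.integer(n + config$base_channels * config$num_classes + config$num_classes)
}

#' Multiply counts for depthwise-separable vs standard convolution
#'
#' For one layer on an `h x w` map: DSConv costs `h*w*(cin*k^2 + cin*cout)`
#' multiplies, a standard convolution `h*w*cin*cout*k^2`; their ratio is
#' `1/cout + 1/k^2`.
#'
#' @param h,w,cin,cout,k layer geometry.
#' @return List with `dsconv`, `standard`, `ratio`.
#' @export
conv_multiply_counts <- function(h, w, cin, cout, k = 3) {
  ds <- h * w * (cin * k^2 + cin * cout)
  std <- h * w * cin * cout * k^2
  list(dsconv = ds, standard = std, ratio = ds / std)
}

# --- full forward / backward ---------------------------------------------

forward_model <- function(model, x, training = FALSE, keep_cache = training) {
  d <- dim(x)
  lw_assert(length(d) == 4L, "forward_model expects H x W x C x N",
            class = "lwunet_shape_error")
  lw_assert(d[1] %% 16 == 0 && d[2] %% 16 == 0,
            "input spatial size must be divisible by 16",
            class = "lwunet_shape_error")
  lw_assert(d[3] == model$config$in_channels, "input channel mismatch",
            class = "lwunet_shape_error")
  L <- model$layers
  cache <- list()
  enc_out <- list()
  h <- x
  for (i in 1:4) {
    nm <- paste0("enc", i)
    o <- dsconv_fwd(h, L[[nm]], training)
    enc_out[[i]] <- o$y
    cache[[nm]] <- if (keep_cache) o$cache else NULL
    cache[[paste0("pool", i, "_in_dim")]] <- dim(o$y)
    h <- avgpool_fwd(o$y)
  }
  o <- dsconv_fwd(h, L$bottleneck, training)
  cache$bottleneck <- if (keep_cache) o$cache else NULL
  h <- o$y
  for (i in 4:1) {
    nm <- paste0("dec", i)
    cache[[paste0("up", i, "_in_dim")]] <- dim(h)
    up <- up2_fwd(h)
    cat_in <- concat_skip(up, enc_out[[i]])
    o <- dsconv_fwd(cat_in, L[[nm]], training)
    cache[[nm]] <- if (keep_cache) o$cache else NULL
    cache[[paste0("split", i)]] <- c(dim(up)[3], dim(enc_out[[i]])[3])
    h <- o$y
  }
  cache$gap_in_dim <- dim(h)
  pooled <- gap_fwd(h)                                # C0 x N
  scores <- crossprod(model$head$Wfc, pooled) + model$head$bfc
  list(scores = scores, pooled = pooled, cache = cache,
       enc_channels = vapply(enc_out, function(e) dim(e)[3], 0L))
}

backward_model <- function(model, fwd, dscores) {
  L <- model$layers
  cache <- fwd$cache
  grads <- list()
  # scores = Wfc' pooled + b  =>  dWfc = pooled dscores', dbfc = rowsum(dscores)
  grads$head <- list(Wfc = tcrossprod(fwd$pooled, dscores),
                     bfc = rowSums(dscores))
  dh <- gap_bwd(model$head$Wfc %*% dscores, cache$gap_in_dim)
  denc <- vector("list", 4)
  for (i in 1:4) {
    nm <- paste0("dec", i)
    b <- dsconv_bwd(dh, L[[nm]], cache[[nm]])
    grads[[nm]] <- b$grads
    split <- cache[[paste0("split", i)]]
    dup <- b$dx[, , seq_len(split[1]), , drop = FALSE]
    denc[[i]] <- b$dx[, , split[1] + seq_len(split[2]), , drop = FALSE]
    dh <- up2_bwd(dup, cache[[paste0("up", i, "_in_dim")]])
  }
  b <- dsconv_bwd(dh, L$bottleneck, cache$bottleneck)
  grads$bottleneck <- b$grads
  dh <- b$dx
  for (i in 4:1) {
    nm <- paste0("enc", i)
    dpool <- avgpool_bwd(dh, cache[[paste0("pool", i, "_in_dim")]])
    b <- dsconv_bwd(dpool + denc[[i]], L[[nm]], cache[[nm]])
    grads[[nm]] <- b$grads
    dh <- b$dx
  }
  grads
}

# Fold training-mode batch statistics into the running BN state.
update_running_stats <- function(model, fwd) {
  for (nm in names(model$layers)) {
    model$layers[[nm]] <- dsconv_update_running(model$layers[[nm]],
                                                fwd$cache[[nm]])
  }
  model
}

#' Forward pass on one image
#'
#' Runs the full encoder/decoder/head on a normalized image and returns the
#' class-score vector. Inference uses running batch-norm statistics unless
#' `training_mode` is set.
#'
#' @param img `H x W x C` normalized image, `H`, `W` divisible by 16.
#' @param model a `lwunet_model`.
#' @param training_mode logical.
#' @return Numeric vector of `num_classes` scores.
#' @export
forward <- function(img, model, training_mode = FALSE) {
  x <- as_nhwcn(img)
  out <- forward_model(model, x, training = training_mode, keep_cache = FALSE)
  as.numeric(out$scores)
}

# --- checkpoints ----------------------------------------------------------

#' Save / load model checkpoints
#'
#' A checkpoint is a single serialized weights file plus a JSON sidecar
#' recording the architecture configuration and a content hash, so a loaded
#' model can be checked against the expected architecture.
#'
#' @param model a `lwunet_model`.
#' @param path checkpoint file (sidecar written to `<path>.json`).
#' @return `save_checkpoint`: the path, invisibly. `load_checkpoint`: the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path, compress = FALSE)
  cfg <- unclass(model$config)
  cfg$n_layers <- n_dsconv_layers(model)
  cfg$n_parameters <- count_parameters(model)
  cfg$package_version <- as.character(utils::packageVersion("lwunet"))
  jsonlite::write_json(cfg, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  lw_assert(file.exists(path), "checkpoint not found: ", path,
            class = "lwunet_io_error")
  model <- readRDS(path)
  lw_assert(inherits(model, "lwunet_model"), "file is not a model checkpoint",
            class = "lwunet_input_error")
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    cfg <- jsonlite::read_json(side)
    lw_assert(cfg$base_channels == model$config$base_channels &&
                cfg$num_classes == model$config$num_classes,
              "checkpoint sidecar does not match stored weights",
              class = "lwunet_input_error")
  }
  model
}
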