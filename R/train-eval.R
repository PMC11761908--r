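# Experimental protocol: stratified k-fold cross-validation on the training
# split, Adam + categorical cross-entropy training with per-epoch history,
# best-checkpoint selection on fold-held-out validation accuracy, and
# evaluation of every fold's best model on the single fixed test split.

#' Training configuration
#'
#' @param learning_rate Adam step size (default 1e-5).
#' @param batch_size mini-batch size (default 16).
#' @param epochs training epochs per fold (default 50).
#' @param k_folds number of cross-validation folds (default 5).
#' @param seed integer seed covering weight init, fold shuffling and batch
#'   order.
#' @return A `lwunet_train_config` list. The loss is categorical
#'   cross-entropy over the two-logit softmax head.
#' @export
train_config <- function(learning_rate = 1e-5, batch_size = 16, epochs = 50,
                         k_folds = 5, seed = 1) {
  lw_assert(learning_rate > 0, "learning_rate must be > 0",
            class = "lwunet_input_error")
  lw_assert(epochs >= 1, "epochs must be >= 1", class = "lwunet_input_error")
  lw_assert(k_folds >= 2, "k_folds must be >= 2", class = "lwunet_input_error")
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), k_folds = as.integer(k_folds),
                 seed = as.integer(seed), optimizer = "adam",
                 loss = "categorical_crossentropy"),
            class = "lwunet_train_config")
}

# --- Adam -----------------------------------------------------------------

TRAINABLE_FIELDS <- c("dw", "pw", "gamma", "beta")

adam_init <- function(model) {
  zero_like <- function(p, fields) {
    out <- list()
    for (f in fields) out[[f]] <- list(m = p[[f]] * 0, v = p[[f]] * 0)
    out
  }
  st <- lapply(model$layers, zero_like, fields = TRAINABLE_FIELDS)
  st$head <- zero_like(model$head, c("Wfc", "bfc"))
  st$t <- 0L
  st
}

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, s) {
    for (f in names(s)) {
      s[[f]]$m <- beta1 * s[[f]]$m + (1 - beta1) * g[[f]]
      s[[f]]$v <- beta2 * s[[f]]$v + (1 - beta2) * g[[f]]^2
      p[[f]] <- p[[f]] - lr * (s[[f]]$m / bc1) / (sqrt(s[[f]]$v / bc2) + eps)
    }
    list(p = p, s = s)
  }
  for (nm in names(model$layers)) {
    r <- upd(model$layers[[nm]], grads[[nm]], state[[nm]])
    model$layers[[nm]] <- r$p
    state[[nm]] <- r$s
  }
  r <- upd(model$head, grads$head, state$head)
  model$head <- r$p
  state$head <- r$s
  list(model = model, state = state)
}

# --- data loading ---------------------------------------------------------

label_index <- function(labels) match(labels, LWUNET_LABELS)

#' Load a preprocessed manifest into memory
#'
#' Reads every referenced `.f32` image into a single `H x W x C x N` array
#' with integer class labels (benign = 1, malignant = 2).
#'
#' @param m a `lwunet_manifest` pointing at preprocessed images.
#' @return List with `x` (array), `y` (integer labels), `labels` (characters).
#' @export
load_image_array <- function(m) {
  lw_assert(nrow(m) > 0, "empty manifest", class = "lwunet_input_error")
  first <- read_image(m$path[1])
  d <- dim(first)
  if (length(d) == 2L) d <- c(d, 1L)
  x <- array(0, c(d, nrow(m)))
  for (i in seq_len(nrow(m))) {
    img <- read_image(m$path[i])
    if (length(dim(img)) == 2L) dim(img) <- c(dim(img), 1L)
    lw_assert(all(dim(img) == d), "inconsistent image sizes in manifest: ",
              m$path[i], class = "lwunet_input_error")
    x[, , , i] <- img
  }
  list(x = x, y = label_index(m$label), labels = m$label)
}

# --- folds ----------------------------------------------------------------

#' Stratified fold assignment
#'
#' Partitions the training split into `k` disjoint validation folds,
#' stratified by class x modality, with seeded shuffling. Test records keep
#' fold `"none"`.
#'
#' @param m a `lwunet_manifest`.
#' @param k number of folds.
#' @param seed integer seed.
#' @return The manifest with the `fold` column filled for train records.
#' @export
make_folds <- function(m, k = 5, seed = 1) {
  lw_assert(inherits(m, "lwunet_manifest"), "m must be a manifest",
            class = "lwunet_input_error")
  train_idx <- which(m$split == "train")
  lw_assert(length(train_idx) >= k, "not enough training records",
            class = "lwunet_input_error")
  fold <- rep("none", nrow(m))
  with_seed(seed, {
    for (mod in unique(m$modality)) {
      for (lab in LWUNET_LABELS) {
        cell <- train_idx[m$modality[train_idx] == mod &
                            m$label[train_idx] == lab]
        if (length(cell) == 0) next
        lw_assert(length(cell) >= k, "class x modality cell '", mod, "/", lab,
                  "' has fewer than k members", class = "lwunet_input_error")
        cell <- sample(cell)
        fold[cell] <- as.character(rep_len(seq_len(k), length(cell)))
      }
    }
  })
  rec <- as.data.frame(m)
  rec$fold <- fold
  manifest(rec, image_size = attr(m, "image_size"), seed = attr(m, "seed"))
}

# --- training loop --------------------------------------------------------

# One full training run on in-memory arrays. Returns the trained model (with
# final running BN stats), the best-validation-accuracy snapshot, and the
# per-epoch history.
train_loop <- function(model, tc, x_train, y_train, x_val, y_val) {
  state <- adam_init(model)
  n <- length(y_train)
  history <- data.frame()
  best <- list(val_acc = -Inf, model = model, epoch = 0L)
  for (epoch in seq_len(tc$epochs)) {
    ord <- sample(n)
    tl <- 0; ta <- 0; nb <- 0
    for (start in seq(1, n, by = tc$batch_size)) {
      idx <- ord[start:min(start + tc$batch_size - 1, n)]
      xb <- x_train[, , , idx, drop = FALSE]
      yb <- y_train[idx]
      fwd <- forward_model(model, xb, training = TRUE)
      ce <- softmax_ce(fwd$scores, yb)
      if (!is.finite(ce$loss)) {
        lw_stop("non-finite training loss at epoch ", epoch,
                class = "lwunet_numeric_error")
      }
      model <- update_running_stats(model, fwd)
      grads <- backward_model(model, fwd, ce$dscores)
      st <- adam_step(model, grads, state, tc$learning_rate)
      model <- st$model
      state <- st$state
      tl <- tl + ce$loss * length(idx)
      ta <- ta + ce$acc * length(idx)
      nb <- nb + length(idx)
    }
    val <- eval_pass(model, x_val, y_val, tc$batch_size)
    history <- rbind(history, data.frame(
      epoch = epoch, train_loss = tl / nb, train_acc = 100 * ta / nb,
      val_loss = val$loss, val_acc = 100 * val$acc))
    if (100 * val$acc > best$val_acc) {
      best <- list(val_acc = 100 * val$acc, model = model, epoch = epoch)
    }
  }
  list(model = model, best = best, history = history)
}

# Deterministic inference pass (running BN statistics); loss + accuracy +
# predictions.
eval_pass <- function(model, x, y, batch_size = 32) {
  n <- length(y)
  loss <- 0; acc <- 0
  pred <- integer(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fwd <- forward_model(model, x[, , , idx, drop = FALSE], training = FALSE,
                         keep_cache = FALSE)
    ce <- softmax_ce(fwd$scores, y[idx])
    loss <- loss + ce$loss * length(idx)
    acc <- acc + ce$acc * length(idx)
    pred[idx] <- ce$pred
  }
  list(loss = loss / n, acc = acc / n, pred = pred)
}

#' Train one cross-validation fold
#'
#' Trains on all training records outside `fold_id`, validates on the
#' held-out fold each epoch, snapshots the weights at the best validation
#' accuracy, and evaluates that checkpoint on the fixed test split. Fully
#' seeded: weight initialization, batch order and fold shuffling all derive
#' from the training seed, so identical calls give identical histories.
#'
#' @param m a fold-assigned, preprocessed `lwunet_manifest`
#'   (see [make_folds()]).
#' @param fold_id which fold to hold out for validation.
#' @param mc a [model_config()].
#' @param tc a [train_config()].
#' @param out_dir where to write the checkpoint and history CSV (optional).
#' @param data optional preloaded `load_image_array()` result for the full
#'   manifest (avoids re-reading images across folds).
#' @return List (`lwunet_fold_result`): `fold`, `history`, `checkpoint`,
#'   `report` (test-set `lwunet_metrics_report`), `best_epoch`.
#' @export
train_fold <- function(m, fold_id, mc, tc, out_dir = NULL, data = NULL) {
  if (is.null(data)) data <- load_image_array(m)
  tr <- which(m$split == "train" & m$fold != as.character(fold_id) &
                m$fold != "none")
  va <- which(m$fold == as.character(fold_id))
  te <- which(m$split == "test")
  lw_assert(length(tr) > 0 && length(va) > 0, "fold ", fold_id,
            " has an empty train or validation set",
            class = "lwunet_input_error")
  run_seed <- tc$seed + 1000L * as.integer(fold_id)
  res <- with_seed(run_seed, {
    model <- init_model(mc, seed = run_seed)
    train_loop(model, tc, data$x[, , , tr, drop = FALSE], data$y[tr],
               data$x[, , , va, drop = FALSE], data$y[va])
  })
  history <- cbind(fold = fold_id, res$history)
  checkpoint <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    checkpoint <- file.path(out_dir, sprintf("fold%s.ckpt", fold_id))
    save_checkpoint(res$best$model, checkpoint)
    utils::write.csv(history, file.path(out_dir,
                                        sprintf("history_fold%s.csv", fold_id)),
                     row.names = FALSE)
  }
  report <- NULL
  if (length(te) > 0) {
    ev <- eval_pass(res$best$model, data$x[, , , te, drop = FALSE], data$y[te])
    report <- metrics_report(
      confusion_matrix(data$labels[te], LWUNET_LABELS[ev$pred]), fold = fold_id)
  }
  structure(list(fold = fold_id, history = history, checkpoint = checkpoint,
                 best_epoch = res$best$epoch, best_model = res$best$model,
                 report = report),
            class = "lwunet_fold_result")
}

#' Evaluate a checkpoint on a test manifest
#'
#' Deterministic inference with running batch-norm statistics.
#'
#' @param checkpoint path from [save_checkpoint()] (or a `lwunet_model`).
#' @param test_m preprocessed manifest; only its `split == "test"` records
#'   are evaluated (all records if none are marked).
#' @return A `lwunet_metrics_report`.
#' @export
evaluate_on_test <- function(checkpoint, test_m) {
  model <- if (inherits(checkpoint, "lwunet_model")) checkpoint else
    load_checkpoint(checkpoint)
  rec <- if (any(test_m$split == "test")) test_m[test_m$split == "test", ] else
    test_m
  data <- load_image_array(manifest(as.data.frame(rec),
                                    image_size = attr(test_m, "image_size"),
                                    seed = attr(test_m, "seed")))
  ev <- eval_pass(model, data$x, data$y)
  metrics_report(confusion_matrix(data$labels, LWUNET_LABELS[ev$pred]))
}

#' Cross-validated training
#'
#' [make_folds()] then [train_fold()] for each fold, evaluating every fold's
#' best checkpoint on the fixed test split, and aggregating the fold reports
#' with [aggregate_folds()]. Histories (CSV) and reports (JSON) are written
#' under `out_dir` when given.
#'
#' @param m preprocessed `lwunet_manifest` with train/test splits.
#' @param mc a [model_config()].
#' @param tc a [train_config()].
#' @param out_dir optional artifact directory.
#' @return List with `folds` (list of `lwunet_fold_result`) and `aggregate`
#'   (`lwunet_metrics_aggregate`).
#' @export
cross_validate <- function(m, mc, tc, out_dir = NULL) {
  mf <- make_folds(m, k = tc$k_folds, seed = tc$seed)
  data <- load_image_array(mf)
  folds <- lapply(seq_len(tc$k_folds), function(f) {
    tryCatch(train_fold(mf, f, mc, tc, out_dir = out_dir, data = data),
             error = function(e) {
               lw_stop("fold ", f, " failed: ", conditionMessage(e))
             })
  })
  agg <- aggregate_folds(lapply(folds, function(fr) fr$report))
  if (!is.null(out_dir)) {
    write_metrics_json(agg, file.path(out_dir, "aggregate.json"))
    for (fr in folds) {
      write_metrics_json(fr$report,
                         file.path(out_dir, sprintf("report_fold%s.json",
                                                    fr$fold)))
    }
  }
  list(folds = folds, aggregate = agg)
}
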