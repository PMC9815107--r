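# Seeded training loop. The default hyperparameters follow the reference
# protocol: 150 epochs, Adam at learning rate 1e-4, batch size 16, focal
# loss with inverse-frequency class weights computed on the training split.
# Everything random (initialization, shuffling) is derived from the config
# seed, so two runs with identical config and data are identical on one
# platform.

#' Training configuration
#'
#' @param epochs Number of epochs (default 150).
#' @param learning_rate Initial Adam learning rate (default 1e-4, no decay
#'   schedule).
#' @param batch_size Mini-batch size (default 16).
#' @param optimizer Only `"adam"` (beta 0.9 / 0.999) is provided.
#' @param loss A [loss_config()] (default: focal loss, gamma 2,
#'   inverse-frequency class weights).
#' @param seed Integer seed governing data order and any augmentation noise.
#' @param checkpoint_dir Optional directory for the best-validation and final
#'   checkpoints.
#' @param metrics_path Optional CSV path for the per-epoch history.
#' @param shuffle Reshuffle the training order every epoch (default `TRUE`).
#' @param stop_at_train_acc Optional early-exit threshold on training
#'   accuracy in `[0, 1]`; `NULL` (default) trains all epochs.
#' @param verbose Print one log line per epoch to stderr.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 150L, learning_rate = 1e-4,
                         batch_size = 16L, optimizer = "adam",
                         loss = loss_config("focal", gamma = 2),
                         seed = 1L, checkpoint_dir = NULL,
                         metrics_path = NULL, shuffle = TRUE,
                         stop_at_train_acc = NULL, verbose = FALSE) {
  stopifnot(epochs >= 1L, learning_rate > 0, batch_size >= 1L)
  if (!identical(optimizer, "adam")) {
    stop("only the adam optimizer is provided", call. = FALSE)
  }
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), optimizer = optimizer,
                 loss = loss, seed = as.integer(seed),
                 checkpoint_dir = checkpoint_dir,
                 metrics_path = metrics_path, shuffle = isTRUE(shuffle),
                 stop_at_train_acc = stop_at_train_acc,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Preprocess 8-bit images into a model input batch
#'
#' Resizes bilinearly to the target resolution, scales to `[0, 1]` and
#' standardizes per channel with the given statistics.
#'
#' @param imgs A list of H x W x 3 arrays (0..255) or a single such array.
#' @param resolution Target square resolution.
#' @param stats List with per-channel `mean` and `sd` on the `[0, 1]` scale;
#'   `NULL` applies mean 0.5, sd 0.5.
#' @return Numeric array (N, 3, resolution, resolution).
#' @export
preprocess_images <- function(imgs, resolution, stats = NULL) {
  if (is.array(imgs) && length(dim(imgs)) == 3L) imgs <- list(imgs)
  if (is.null(stats)) stats <- list(mean = rep(0.5, 3), sd = rep(0.5, 3))
  n <- length(imgs)
  out <- array(0, c(n, 3L, resolution, resolution))
  for (i in seq_len(n)) {
    img <- imgs[[i]] / 255
    x <- aperm(img, c(3L, 1L, 2L))           # (3, H, W)
    x <- array(x, c(1L, dim(x)))
    x <- resize_bilinear_cpp(x, resolution, resolution)
    out[i, , , ] <- x[1L, , , ]
  }
  for (ch in 1:3) {
    out[, ch, , ] <- (out[, ch, , ] - stats$mean[ch]) / stats$sd[ch]
  }
  out
}

# Load every record of a manifest as a preprocessed tensor plus labels.
manifest_tensor <- function(manifest, resolution, stats = NULL) {
  df <- as.data.frame(manifest)
  imgs <- mapply(load_record_image, df$path, df$provenance, SIMPLIFY = FALSE)
  classes <- attr(manifest, "classes")
  labels <- match(df$label, classes)
  raw <- preprocess_images(imgs, resolution, stats = list(mean = rep(0, 3),
                                                          sd = rep(1, 3)))
  list(raw = raw, labels = labels, classes = classes)
}

channel_stats_from_tensor <- function(raw) {
  mu <- numeric(3); s <- numeric(3)
  for (ch in 1:3) {
    v <- raw[, ch, , ]
    mu[ch] <- mean(v)
    s[ch] <- stats::sd(v)
  }
  s[s < 1e-6] <- 1
  list(mean = mu, sd = s)
}

standardize_tensor <- function(raw, stats) {
  for (ch in 1:3) {
    raw[, ch, , ] <- (raw[, ch, , ] - stats$mean[ch]) / stats$sd[ch]
  }
  raw
}

adam_init <- function(params) {
  list(m = param_map(function(p) p * 0, params),
       v = param_map(function(p) p * 0, params),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- param_map(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- param_map(function(v, g) beta2 * v + (1 - beta2) * g * g,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  params <- param_map(function(p, m, v) {
    p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }, params, state$m, state$v)
  list(params = params, state = state)
}

eval_pass <- function(model, x, labels, alpha, loss_cfg, batch_size = 64L) {
  n <- dim(x)[1]
  total_loss <- 0
  pred <- integer(n)
  for (start in seq(1L, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, n)
    xb <- x[ix, , , , drop = FALSE]
    logits <- model_forward(model, xb, training = FALSE)$logits
    sl <- softmax_loss_grad(logits, labels[ix], alpha,
                            gamma = if (loss_cfg$kind == "focal")
                              loss_cfg$gamma else 0,
                            reduction = "sum")
    total_loss <- total_loss + sl$loss
    pred[ix] <- max.col(sl$probs, ties.method = "first")
  }
  list(loss = total_loss / n, acc = mean(pred == labels), pred = pred)
}

#' Train a model on manifests
#'
#' Loads all images, computes per-channel normalization statistics on the
#' training split, resolves class weights, and runs the seeded mini-batch
#' loop. The per-epoch history records training loss/accuracy (computed in
#' evaluation mode at epoch end) and validation accuracy; the best-validation
#' parameters are retained.
#'
#' @param model An `msf_model` whose head width matches the manifest's class
#'   vocabulary.
#' @param train_manifest,val_manifest Manifests from [split_dataset()] /
#'   [load_image_folder()]; `val_manifest` may be `NULL`.
#' @param config A [train_config()].
#' @return List with elements `model` (final), `best_model`, `history`
#'   (data.frame epoch/train_loss/train_acc/val_acc) and `config`.
#' @export
train <- function(model, train_manifest, val_manifest = NULL,
                  config = train_config()) {
  stopifnot(inherits(model, "msf_model"), inherits(config, "train_config"))
  if (nrow(train_manifest) == 0) stop("empty training manifest", call. = FALSE)
  classes <- attr(train_manifest, "classes")
  if (length(classes) != model$config$num_classes) {
    stop(sprintf("model has %d outputs but the manifest has %d classes",
                 model$config$num_classes, length(classes)), call. = FALSE)
  }

  res <- model$config$resolution
  tr <- manifest_tensor(train_manifest, res)
  stats <- channel_stats_from_tensor(tr$raw)
  x_tr <- standardize_tensor(tr$raw, stats)
  y_tr <- tr$labels
  model$classes <- classes
  model$norm_stats <- stats

  has_val <- !is.null(val_manifest) && nrow(val_manifest) > 0
  if (has_val) {
    va <- manifest_tensor(val_manifest, res, stats)
    x_va <- standardize_tensor(va$raw, stats)
    y_va <- va$labels
  }

  loss_cfg <- config$loss
  alpha <- resolve_alpha(loss_cfg, y_tr, length(classes))
  gamma <- if (loss_cfg$kind == "focal") loss_cfg$gamma else 0

  params <- model_params(model)
  opt <- adam_init(params)
  n <- length(y_tr)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        train_acc = numeric(0), val_acc = numeric(0))
  best_val <- -Inf
  best_state <- NULL

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      order_ix <- if (config$shuffle) sample.int(n) else seq_len(n)
      for (start in seq(1L, n, by = config$batch_size)) {
        ix <- order_ix[start:min(start + config$batch_size - 1L, n)]
        xb <- x_tr[ix, , , , drop = FALSE]
        fw <- model_forward(model, xb, training = TRUE)
        model <- fw$model
        sl <- softmax_loss_grad(fw$logits, y_tr[ix], alpha, gamma = gamma,
                                reduction = "mean")
        if (!is.finite(sl$loss)) {
          stop(sprintf("training diverged (non-finite loss) at epoch %d",
                       epoch), call. = FALSE)
        }
        bw <- model_backward(model, fw$caches, sl$dlogits)
        upd <- adam_step(params, bw$grads, opt, config$learning_rate)
        params <- upd$params
        opt <- upd$state
        model <- model_set_params(model, params)
      }

      ev_tr <- eval_pass(model, x_tr, y_tr, alpha, loss_cfg)
      val_acc <- NA_real_
      if (has_val) {
        ev_va <- eval_pass(model, x_va, y_va, alpha, loss_cfg)
        val_acc <- ev_va$acc
      }
      history[epoch, ] <- list(epoch, ev_tr$loss, ev_tr$acc, val_acc)
      score <- if (has_val) val_acc else ev_tr$acc
      if (score >= best_val) {
        best_val <- score
        best_state <- list(params = params, buffers = model_buffers(model))
      }
      if (config$verbose) {
        message(sprintf("[%s] epoch %3d  loss %.4f  train_acc %.3f  val_acc %s",
                        format(Sys.time(), "%H:%M:%S"), epoch, ev_tr$loss,
                        ev_tr$acc,
                        if (is.na(val_acc)) "-" else sprintf("%.3f", val_acc)))
      }
      if (!is.null(config$stop_at_train_acc) &&
          ev_tr$acc >= config$stop_at_train_acc) break
    }
  })

  best_model <- model
  if (!is.null(best_state)) {
    best_model <- model_set_params(best_model, best_state$params)
    best_model <- model_set_buffers(best_model, best_state$buffers)
  }
  if (!is.null(config$metrics_path)) {
    utils::write.csv(history, config$metrics_path, row.names = FALSE)
  }
  if (!is.null(config$checkpoint_dir)) {
    dir.create(config$checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(best_model,
                    file.path(config$checkpoint_dir, "checkpoint_best.rds"))
    save_checkpoint(model,
                    file.path(config$checkpoint_dir, "checkpoint_final.rds"))
  }
  list(model = model, best_model = best_model, history = history,
       config = config)
}

#' Compare loss configurations on identical data
#'
#' Trains one seeded run per loss configuration on the same splits and
#' reports per-class recall plus overall accuracy, exhibiting how the choice
#' of loss shifts attention between majority and minority classes.
#'
#' @param model_factory Function `(seed) -> msf_model` building a fresh
#'   model for each run.
#' @param train_manifest,val_manifest Data for every run.
#' @param configs Named list of at least two [train_config()]s.
#' @return data.frame with columns `config`, `class`, `recall`, `accuracy`.
#' @export
evaluate_loss_choice <- function(model_factory, train_manifest,
                                 val_manifest = NULL, configs) {
  if (length(configs) < 2L) {
    stop("supply at least two training configurations", call. = FALSE)
  }
  if (is.null(names(configs)) || any(names(configs) == "")) {
    names(configs) <- paste0("config", seq_along(configs))
  }
  eval_manifest <- if (!is.null(val_manifest) && nrow(val_manifest) > 0) {
    val_manifest
  } else {
    train_manifest
  }
  classes <- attr(train_manifest, "classes")
  out <- list()
  for (nm in names(configs)) {
    cfg <- configs[[nm]]
    run <- train(model_factory(cfg$seed), train_manifest, val_manifest, cfg)
    ev <- evaluate_model(run$model, eval_manifest)
    rec <- confusion_metrics(ev$confusion)
    out[[nm]] <- data.frame(config = nm, class = classes,
                            recall = rec$per_class$recall,
                            accuracy = rec$accuracy)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Evaluate a trained model on a manifest
#'
#' @param model A trained `msf_model` (with normalization statistics).
#' @param manifest Manifest to evaluate.
#' @return List with `accuracy`, `confusion` (an `msf_confusion`), `pred`
#'   and `truth` (1-based class indices).
#' @export
evaluate_model <- function(model, manifest) {
  stopifnot(inherits(model, "msf_model"))
  if (nrow(manifest) == 0) stop("empty manifest", call. = FALSE)
  res <- model$config$resolution
  stats <- model$norm_stats
  if (is.null(stats)) stats <- list(mean = rep(0.5, 3), sd = rep(0.5, 3))
  te <- manifest_tensor(manifest, res)
  x <- standardize_tensor(te$raw, stats)
  n <- dim(x)[1]
  pred <- integer(n)
  for (start in seq(1L, n, by = 64L)) {
    ix <- start:min(start + 63L, n)
    probs <- predict(model, x[ix, , , , drop = FALSE])
    pred[ix] <- max.col(probs, ties.method = "first")
  }
  cm <- confusion_matrix(te$labels, pred, labels = te$classes)
  list(accuracy = mean(pred == te$labels), confusion = cm, pred = pred,
       truth = te$labels)
}
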