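#' Training hyperparameters
#'
#' Defaults mirror the deployment recipe this package implements: ADAM at an
#' initial learning rate of 0.01, reduced by 80 percent (multiplied by 0.2)
#' after every 20 epochs, minibatches of 32 for recurrent variants (128 is
#' the conventional maximum for the pure-CNN variant), up to 200 epochs, and
#' early stopping once the training loss reaches 0.01 and the validation
#' loss 0.1. An optional two-phase mode warms the convolutional stack up with
#' SGDM before switching to ADAM.
#'
#' @param optimizer `"ADAM"` (joint end-to-end training, the default) or
#'   `"SGDM"`.
#' @param lr_init Initial learning rate.
#' @param lr_decay_factor Multiplier applied to the learning rate at each
#'   decay step (0.2 = an 80 percent reduction).
#' @param lr_decay_every_epochs Epochs between decay steps.
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param seed Integer seed fixing initialisation, shuffling and dropout.
#' @param early_stop_train_loss,early_stop_val_loss Stop once the epoch
#'   training loss and the validation loss are both at or below these.
#' @param val_per_epoch Validation evaluations per epoch (1 or 2).
#' @param clip_norm Global gradient-norm ceiling applied before each update
#'   (standard stabilisation for recurrent nets); `Inf` disables clipping.
#' @param adam_eps ADAM denominator offset. The default 1e-3 keeps the
#'   per-coordinate step well below the learning rate wherever gradients are
#'   small relative to it, which stabilises the large-fan-in convolutions at
#'   the configured learning rate.
#' @param two_phase Warm up with SGDM for `warmup_epochs`, then ADAM.
#' @param warmup_epochs Length of the SGDM warm-up when `two_phase = TRUE`.
#' @return A list of class `train_config`.
#' @export
train_config <- function(optimizer = c("ADAM", "SGDM"), lr_init = 0.01,
                         lr_decay_factor = 0.2, lr_decay_every_epochs = 20,
                         epochs = 200, batch_size = 32, seed = 1L,
                         early_stop_train_loss = 0.01,
                         early_stop_val_loss = 0.1,
                         val_per_epoch = 1L,
                         clip_norm = 1,
                         adam_eps = 1e-3,
                         two_phase = FALSE, warmup_epochs = 10L) {
  optimizer <- match.arg(optimizer)
  stopifnot(lr_init > 0, lr_decay_factor > 0, lr_decay_factor <= 1,
            lr_decay_every_epochs >= 1, epochs >= 1, batch_size >= 1,
            val_per_epoch %in% c(1L, 2L))
  structure(list(optimizer = optimizer, lr_init = lr_init,
                 lr_decay_factor = lr_decay_factor,
                 lr_decay_every_epochs = as.integer(lr_decay_every_epochs),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed),
                 early_stop_train_loss = early_stop_train_loss,
                 early_stop_val_loss = early_stop_val_loss,
                 val_per_epoch = as.integer(val_per_epoch),
                 clip_norm = clip_norm,
                 adam_eps = adam_eps,
                 two_phase = isTRUE(two_phase),
                 warmup_epochs = as.integer(warmup_epochs)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' `lr_init * factor^floor((epoch - 1) / every)`: epoch 21 under the defaults
#' runs at 0.01 * 0.2 = 0.002.
#'
#' @param cfg A [train_config()].
#' @param epoch 1-based epoch number.
#' @return The learning rate.
#' @export
lr_at_epoch <- function(cfg, epoch) {
  cfg$lr_init * cfg$lr_decay_factor^((epoch - 1) %/% cfg$lr_decay_every_epochs)
}

# Stack tensor list-column rows into an array (T, C, B).
tensors_to_array <- function(tensors, rows = seq_len(nrow(tensors))) {
  d <- dim(tensors$tensor[[rows[1]]])
  out <- array(0, c(d[1], d[2], length(rows)))
  for (j in seq_along(rows)) out[, , j] <- tensors$tensor[[rows[j]]]
  out
}

eval_metrics <- function(arch, params, tensors, rows, batch_size,
                         shapes = arch_shapes(arch)) {
  if (length(rows) == 0) return(list(loss = NA_real_, acc = NA_real_))
  loss_sum <- 0
  correct <- 0
  for (chunk in split(rows, ceiling(seq_along(rows) / batch_size))) {
    X <- tensors_to_array(tensors, chunk)
    y <- tensors$label[chunk]
    fw <- nn_forward(arch, params, X, training = FALSE, shapes = shapes)
    sx <- softmax_xent(fw$logits, y)
    loss_sum <- loss_sum + sx$loss * length(chunk)
    correct <- correct + sum(max.col(sx$probs, ties.method = "first") == y)
  }
  list(loss = loss_sum / length(rows), acc = correct / length(rows))
}

#' Train a gesture classifier
#'
#' Trains the given architecture end to end on the train split of a gesture
#' dataset with softmax cross-entropy loss, validating against the val split.
#' Given the same seed the whole run — initialisation, shuffling, dropout —
#' is bit-reproducible. Training stops early once the epoch training loss and
#' the validation loss both reach their configured targets.
#'
#' @param arch An `emg_architecture`; its `n_classes` must cover the labels.
#' @param dataset A gesture dataset from [split_intra()], [split_inter()] or
#'   [prepare_gesture_dataset()] (an `emg_tensors` tibble with a `split`
#'   column).
#' @param cfg A [train_config()].
#' @param verbose Log per-epoch metrics to stderr.
#' @return An object of class `emg_model`: the architecture, trained weights,
#'   config, and a `history` tibble (`epoch`, `lr`, `train_loss`,
#'   `train_acc`, `val_loss`, `val_acc`).
#' @export
train_model <- function(arch, dataset, cfg = train_config(), verbose = FALSE) {
  assert_no_leakage(dataset)
  train_rows <- which(dataset$split == "train")
  val_rows <- which(dataset$split == "val")
  if (length(train_rows) == 0) abort("training split is empty")
  if (any(dataset$label < 1 | dataset$label > arch$n_classes)) {
    abort(sprintf("labels must lie in 1..%d", arch$n_classes))
  }

  withr::local_seed(cfg$seed)
  shapes <- arch_shapes(arch)
  params <- nn_init(arch)
  stopifnot(engine_param_count(params) == true_param_count(arch))
  state <- opt_init(params)
  step <- 0L
  history <- list()

  for (epoch in seq_len(cfg$epochs)) {
    lr <- lr_at_epoch(cfg, epoch)
    optimizer <- cfg$optimizer
    if (cfg$two_phase) {
      optimizer <- if (epoch <= cfg$warmup_epochs) "SGDM" else "ADAM"
    }
    idx <- sample(train_rows)
    batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
    loss_sum <- 0
    correct <- 0
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      X <- tensors_to_array(dataset, b)
      y <- dataset$label[b]
      fw <- nn_forward(arch, params, X, training = TRUE, shapes = shapes)
      sx <- softmax_xent(fw$logits, y)
      if (!is.finite(sx$loss)) {
        abort(sprintf("non-finite loss at epoch %d, batch %d (lr = %g)",
                      epoch, bi, lr))
      }
      grads <- nn_backward(arch, params, fw$caches, sx$dlogits,
                           shapes = shapes)
      grads <- clip_gradients(grads, cfg$clip_norm %||% Inf)
      step <- step + 1L
      upd <- opt_step(params, grads, state, lr, optimizer, step,
                      eps = cfg$adam_eps %||% 1e-3)
      params <- upd$params
      state <- upd$state
      loss_sum <- loss_sum + sx$loss * length(b)
      correct <- correct + sum(max.col(sx$probs, ties.method = "first") == y)
      if (cfg$val_per_epoch == 2L && bi == length(batches) %/% 2) {
        vm <- eval_metrics(arch, params, dataset, val_rows, cfg$batch_size, shapes)
        history[[length(history) + 1]] <- tibble::tibble(
          epoch = epoch - 0.5, lr = lr,
          train_loss = loss_sum / sum(lengths(batches[1:bi])),
          train_acc = correct / sum(lengths(batches[1:bi])),
          val_loss = vm$loss, val_acc = vm$acc)
      }
    }
    train_loss <- loss_sum / length(idx)
    train_acc <- correct / length(idx)
    vm <- eval_metrics(arch, params, dataset, val_rows, cfg$batch_size, shapes)
    history[[length(history) + 1]] <- tibble::tibble(
      epoch = as.numeric(epoch), lr = lr,
      train_loss = train_loss, train_acc = train_acc,
      val_loss = vm$loss, val_acc = vm$acc)
    if (verbose) {
      message(sprintf(
        "epoch %3d lr %.4g train loss %.4f acc %.3f val loss %s acc %s",
        epoch, lr, train_loss, train_acc,
        format(vm$loss, digits = 4), format(vm$acc, digits = 3)))
    }
    stop_val <- if (is.na(vm$loss)) TRUE else vm$loss <= cfg$early_stop_val_loss
    if (train_loss <= cfg$early_stop_train_loss && stop_val) break
  }

  structure(list(
    architecture = arch,
    params = params,
    config = cfg,
    history = dplyr::bind_rows(history),
    n_params = engine_param_count(params),
    feature_kind = attr(dataset, "feature_kind"),
    window_spec = attr(dataset, "window_spec")
  ), class = "emg_model")
}

#' @export
print.emg_model <- function(x, ...) {
  last <- tail(x$history, 1)
  cat(sprintf("<emg_model> %s, %d parameters, trained %g epochs\n",
              x$architecture$variant, x$n_params, max(x$history$epoch)))
  cat(sprintf("  final train loss %.4f acc %.3f; val loss %s acc %s\n",
              last$train_loss, last$train_acc,
              format(last$val_loss, digits = 4),
              format(last$val_acc, digits = 3)))
  invisible(x)
}

#' Predict gesture classes
#'
#' @param object An `emg_model`.
#' @param newdata An `emg_tensors` tibble.
#' @param type `"class"` for integer labels, `"prob"` for the softmax matrix.
#' @param batch_size Forward-pass chunk size.
#' @param ... Unused.
#' @return Integer vector of labels, or an `n x n_classes` matrix.
#' @export
predict.emg_model <- function(object, newdata, type = c("class", "prob"),
                              batch_size = 64, ...) {
  type <- match.arg(type)
  rows <- seq_len(nrow(newdata))
  shapes <- arch_shapes(object$architecture)
  probs <- matrix(NA_real_, nrow(newdata), object$architecture$n_classes)
  for (chunk in split(rows, ceiling(seq_along(rows) / batch_size))) {
    X <- tensors_to_array(newdata, chunk)
    fw <- nn_forward(object$architecture, object$params, X, training = FALSE,
                     shapes = shapes)
    probs[chunk, ] <- softmax_probs(fw$logits)
  }
  if (type == "prob") probs else max.col(probs, ties.method = "first")
}

#' Training history accessors and plots
#'
#' `tidy()` returns the per-layer parameter table, `glance()` a one-row
#' summary, and `autoplot()` the loss/accuracy curves.
#'
#' @param x,object An `emg_model`.
#' @param ... Unused.
#' @name emg_model_methods
NULL

#' @rdname emg_model_methods
#' @export
tidy.emg_model <- function(x, ...) {
  shapes <- arch_shapes(x$architecture)
  tibble::tibble(
    layer = seq_along(x$params),
    kind = shapes$kind,
    n_params = vapply(x$params, function(p) {
      if (is.null(p)) 0 else sum(vapply(p, length, numeric(1)))
    }, numeric(1))
  )
}

#' @rdname emg_model_methods
#' @export
glance.emg_model <- function(x, ...) {
  last <- tail(x$history, 1)
  tibble::tibble(variant = x$architecture$variant,
                 n_params = x$n_params,
                 epochs_trained = max(x$history$epoch),
                 train_loss = last$train_loss, train_acc = last$train_acc,
                 val_loss = last$val_loss, val_acc = last$val_acc)
}

#' @rdname emg_model_methods
#' @export
autoplot.emg_model <- function(object, ...) {
  df <- object$history |>
    tidyr::pivot_longer(c("train_loss", "val_loss", "train_acc", "val_acc"),
                        names_to = c("split", "metric"), names_sep = "_",
                        values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$value,
                                   colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(y = NULL)
}

#' Persist and restore trained models
#'
#' The artifact is a single RDS file holding weights, architecture, config
#' and history; [model_size_bytes()] reports its on-disk size, the quantity
#' to compare against an embedded flash budget.
#'
#' @param model An `emg_model`.
#' @param path File path (conventionally `.rds`).
#' @return `path` / the restored model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "emg_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "emg_model")) abort("not a saved emg_model")
  model
}

#' @rdname save_model
#' @export
model_size_bytes <- function(path) as.integer(file.size(path))
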