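window_key <- function(dataset) {
  paste(dataset$trial_id, dataset$window_start, sep = "@")
}

#' Guard against split leakage
#'
#' Asserts that no window (identified by trial and window start) is assigned
#' to more than one of train/val/test. Called on every training and
#' evaluation run.
#'
#' @param dataset An `emg_tensors` tibble with a `split` column.
#' @return The dataset, invisibly.
#' @export
assert_no_leakage <- function(dataset) {
  if (!"split" %in% names(dataset)) {
    abort("dataset has no split assignments; run split_intra()/split_inter()")
  }
  dup <- dataset |>
    dplyr::mutate(key = window_key(dataset)) |>
    dplyr::distinct(.data$key, .data$split) |>
    dplyr::count(.data$key) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("window(s) assigned to multiple splits: %s",
                  paste(head(dup$key, 5), collapse = ", ")))
  }
  invisible(dataset)
}

# Per-trial assignment: first 2/3 of windows (in temporal order) train, last
# third test; val is the contiguous tail of the training portion.
intra_assign <- function(k, val_fraction) {
  n_train_pool <- (2L * k) %/% 3L
  n_val <- floor(val_fraction * n_train_pool)
  c(rep("train", n_train_pool - n_val), rep("val", n_val),
    rep("test", k - n_train_pool))
}

#' Intra-experiment split
#'
#' Within each trial the first two thirds of its windows (in temporal order)
#' go to training and the last third to testing; validation is carved from
#' the contiguous tail of the training portion. Use
#' [prepare_gesture_dataset()] to apply the same protocol at the raw-signal
#' level, before preprocessing, so filter and normalization statistics cannot
#' leak either.
#'
#' @param tensors An `emg_tensors` tibble.
#' @param val_fraction Fraction of the training portion carved for
#'   validation.
#' @return The tibble with a `split` column (`"train"`, `"val"`, `"test"`).
#' @export
split_intra <- function(tensors, val_fraction = 0.1) {
  if (any(duplicated(window_key(tensors)))) {
    abort("duplicate windows in input; cannot split")
  }
  short <- tensors |>
    dplyr::count(.data$trial_id) |>
    dplyr::filter(.data$n < 3)
  if (nrow(short) > 0) {
    abort(sprintf("trial(s) too short to split into thirds: %s",
                  paste(short$trial_id, collapse = ", ")))
  }
  out <- tensors |>
    dplyr::arrange(.data$trial_id, .data$window_start) |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::mutate(split = intra_assign(dplyr::n(), val_fraction)) |>
    dplyr::ungroup()
  out <- new_emg_tensors(out, attr(tensors, "feature_kind"),
                         attr(tensors, "window_spec"))
  assert_no_leakage(out)
}

#' Inter-experiment split
#'
#' All windows of one complete protocol repetition (experiment) train the
#' model; all windows of another test it. Validation is carved from the
#' temporal tail of each training trial.
#'
#' @param tensors An `emg_tensors` tibble with an `experiment` column.
#' @param train_experiment,test_experiment Experiment identifiers.
#' @param val_fraction Fraction of each training trial carved for validation.
#' @return The tibble (restricted to the two experiments) with a `split`
#'   column.
#' @export
split_inter <- function(tensors, train_experiment, test_experiment,
                        val_fraction = 0.1) {
  present <- unique(tensors$experiment)
  for (e in c(train_experiment, test_experiment)) {
    if (!e %in% present) {
      abort(sprintf("experiment %s not present (have: %s)",
                    e, paste(present, collapse = ", ")))
    }
  }
  out <- tensors |>
    dplyr::filter(.data$experiment %in% c(train_experiment, test_experiment)) |>
    dplyr::arrange(.data$trial_id, .data$window_start) |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::mutate(split = if (dplyr::first(.data$experiment) == train_experiment) {
      k <- dplyr::n()
      n_val <- floor(val_fraction * k)
      c(rep("train", k - n_val), rep("val", n_val))
    } else {
      rep("test", dplyr::n())
    }) |>
    dplyr::ungroup()
  out <- new_emg_tensors(out, attr(tensors, "feature_kind"),
                         attr(tensors, "window_spec"))
  assert_no_leakage(out)
}

#' Split-then-preprocess pipeline
#'
#' Builds a ready-to-train gesture dataset from raw recordings and their
#' label sidecar, enforcing split-before-preprocessing: each labelled trial
#' segment is cut at the raw-signal level (intra: first two thirds train
#' pool, last third test; inter: whole trials by experiment), each portion is
#' conditioned independently with [emg_preprocess()] — so min-max statistics
#' never cross a split — and only then windowed into feature tensors.
#'
#' @param recordings A single [emg_recording()] or a list of them (e.g. one
#'   per protocol repetition from [simulate_semg()]).
#' @param labels Label sidecar tibble covering all recordings, with a
#'   `recording` column indexing into `recordings` (defaults to 1).
#' @param feature_kind Feature representation; see [build_feature_tensors()].
#' @param spec A [window_spec()].
#' @param settings A [filter_settings()].
#' @param split `"intra"` or `"inter"`.
#' @param train_experiment,test_experiment Experiment ids for `"inter"`.
#' @param val_fraction Validation fraction of the training portion.
#' @return An `emg_tensors` tibble with a `split` column.
#' @export
prepare_gesture_dataset <- function(recordings, labels,
                                    feature_kind = "FFT_RMS",
                                    spec = window_spec(),
                                    settings = filter_settings(),
                                    split = c("intra", "inter"),
                                    train_experiment = NULL,
                                    test_experiment = NULL,
                                    val_fraction = 0.1) {
  split <- match.arg(split)
  if (inherits(recordings, "emg_recording")) recordings <- list(recordings)
  if (!"recording" %in% names(labels)) labels$recording <- 1L
  if (split == "inter") {
    for (e in c(train_experiment, test_experiment)) {
      if (is.null(e) || !e %in% labels$experiment) {
        abort("train_experiment/test_experiment must name present experiments")
      }
    }
  }

  piece_tensors <- function(rec, row, from, to, role) {
    seg <- rec_slice(rec, from, to)
    pp <- suppressWarnings(emg_preprocess(seg, settings))
    seg_labels <- tibble::tibble(
      trial_id = row$trial_id, subject_id = row$subject_id,
      experiment = row$experiment, gesture_label = row$gesture_label,
      start_sample = 0L, end_sample = to - from)
    tens <- build_feature_tensors(pp, feature_kind, spec, seg_labels)
    tens$window_start <- tens$window_start + from  # global coordinates
    tens$split <- role
    tens
  }

  pieces <- purrr::map_dfr(seq_len(nrow(labels)), function(i) {
    row <- labels[i, ]
    rec <- recordings[[row$recording]]
    if (split == "intra") {
      n <- row$end_sample - row$start_sample
      if (n < 3 * spec$window_len) {
        abort(sprintf("trial %s (%d samples) too short for three %d-sample parts",
                      row$trial_id, n, spec$window_len))
      }
      cut <- row$start_sample + (2L * n) %/% 3L
      train_part <- piece_tensors(rec, row, row$start_sample, cut, "train")
      k <- nrow(train_part)
      n_val <- floor(val_fraction * k)
      if (n_val > 0) {
        train_part$split[(k - n_val + 1):k] <- "val"
      }
      test_part <- piece_tensors(rec, row, cut, row$end_sample, "test")
      dplyr::bind_rows(train_part, test_part)
    } else {
      role <- if (row$experiment == train_experiment) "train"
              else if (row$experiment == test_experiment) "test"
              else return(NULL)
      part <- piece_tensors(rec, row, row$start_sample, row$end_sample, role)
      if (role == "train") {
        k <- nrow(part)
        n_val <- floor(val_fraction * k)
        if (n_val > 0) part$split[(k - n_val + 1):k] <- "val"
      }
      part
    }
  })
  out <- new_emg_tensors(pieces, feature_kind, spec)
  assert_no_leakage(out)
}

#' Evaluate a trained model on the test split
#'
#' @param model An `emg_model`.
#' @param dataset A split gesture dataset; rows with `split == "test"` are
#'   scored.
#' @param model_bytes Optional on-disk artifact size to carry in the report.
#' @return An `emg_eval` object: `confusion` (true x predicted count
#'   matrix), `per_class_accuracy` (NA for classes absent from the test
#'   set), `overall_accuracy`, `n_test`, `model_bytes`.
#' @export
evaluate_model <- function(model, dataset, model_bytes = NA_integer_) {
  assert_no_leakage(dataset)
  test_rows <- which(dataset$split == "test")
  if (length(test_rows) == 0) abort("test split is empty")
  truth <- dataset$label[test_rows]
  pred <- predict(model, dataset[test_rows, ])
  k <- model$architecture$n_classes
  confusion <- matrix(0L, k, k,
                      dimnames = list(true = seq_len(k), pred = seq_len(k)))
  for (i in seq_along(truth)) {
    confusion[truth[i], pred[i]] <- confusion[truth[i], pred[i]] + 1L
  }
  row_tot <- rowSums(confusion)
  per_class <- ifelse(row_tot > 0, diag(confusion) / row_tot, NA_real_)
  structure(list(
    confusion = confusion,
    per_class_accuracy = setNames(per_class, seq_len(k)),
    overall_accuracy = sum(diag(confusion)) / sum(confusion),
    n_test = length(truth),
    model_bytes = model_bytes
  ), class = "emg_eval")
}

#' @export
print.emg_eval <- function(x, ...) {
  cat(sprintf("<emg_eval> overall accuracy %.4f on %d test windows\n",
              x$overall_accuracy, x$n_test))
  defined <- x$per_class_accuracy[!is.na(x$per_class_accuracy)]
  worst <- sort(defined)[seq_len(min(3, length(defined)))]
  cat("  weakest classes:",
      paste(sprintf("%s=%.2f", names(worst), worst), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.emg_eval <- function(x, ...) {
  tibble::tibble(class = seq_len(nrow(x$confusion)),
                 n_test = unname(rowSums(x$confusion)),
                 accuracy = unname(x$per_class_accuracy))
}

#' @export
glance.emg_eval <- function(x, ...) {
  tibble::tibble(overall_accuracy = x$overall_accuracy,
                 n_test = x$n_test,
                 model_bytes = x$model_bytes)
}

#' Confusion-matrix heat map
#'
#' @param object An `emg_eval`.
#' @param normalize Show row-normalized percentages instead of counts.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.emg_eval <- function(object, normalize = TRUE, ...) {
  cm <- object$confusion
  if (normalize) {
    rs <- rowSums(cm)
    cm <- sweep(cm, 1, ifelse(rs > 0, rs, 1), "/") * 100
  }
  df <- as.data.frame(as.table(cm))
  names(df) <- c("true", "pred", "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$pred, .data$true,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$value)), size = 2.5) +
    ggplot2::scale_y_discrete(limits = rev(levels(df$true))) +
    ggplot2::labs(x = "predicted gesture", y = "true gesture",
                  fill = if (normalize) "%" else "count")
}

#' Write a confusion matrix to CSV
#'
#' @param eval An `emg_eval`.
#' @param path Output file.
#' @export
write_confusion_csv <- function(eval, path) {
  utils::write.csv(as.data.frame(eval$confusion), path, row.names = TRUE)
  invisible(path)
}

#' Feature x architecture comparison grid
#'
#' Trains and evaluates every combination of feature representation and
#' model variant on the same raw data under the intra-experiment protocol,
#' returning one row per combination — the harness behind "which feature and
#' which network fit the flash budget at what accuracy".
#'
#' @param recordings,labels Raw data as for [prepare_gesture_dataset()].
#' @param feature_kinds Character vector of feature representations.
#' @param variants Character vector of architecture variant names.
#' @param spec,settings Windowing and filter settings.
#' @param cfg A [train_config()]; the same seed is used for every cell.
#' @param arch_args Extra arguments passed to [build_architecture()] (e.g.
#'   smaller map counts for quick studies).
#' @return A tibble: `feature_kind`, `variant`, `accuracy`, `flash_total`,
#'   `model_bytes`.
#' @export
compare_grid <- function(recordings, labels,
                         feature_kinds = c("RAW", "FFT_RMS"),
                         variants = c("CNN2D_LSTM"),
                         spec = window_spec(), settings = filter_settings(),
                         cfg = train_config(), arch_args = list()) {
  stopifnot(length(feature_kinds) >= 1, length(variants) >= 1)
  if (inherits(recordings, "emg_recording")) recordings <- list(recordings)
  purrr::map_dfr(feature_kinds, function(fk) {
    dataset <- prepare_gesture_dataset(recordings, labels, feature_kind = fk,
                                       spec = spec, settings = settings)
    purrr::map_dfr(variants, function(v) {
      n_cls <- max(labels$gesture_label)
      arch <- do.call(build_architecture,
                      c(list(variant = v,
                             input_shape = c(spec$window_len,
                                             n_channels(recordings[[1]]), 1L),
                             n_classes = n_cls),
                        arch_args))
      model <- train_model(arch, dataset, cfg)
      tmp <- tempfile(fileext = ".rds")
      save_model(model, tmp)
      bytes <- model_size_bytes(tmp)
      unlink(tmp)
      ev <- evaluate_model(model, dataset, model_bytes = bytes)
      tibble::tibble(feature_kind = fk, variant = v,
                     accuracy = ev$overall_accuracy,
                     flash_total = flash_size_estimate(arch)$flash_total,
                     model_bytes = bytes)
    })
  })
}
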