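# A tensor set laid out as trials of known window counts, for split tests.
trial_tensors <- function(counts, dims = c(8L, 2L)) {
  rows <- purrr::imap_dfr(counts, function(k, nm) {
    tibble::tibble(
      tensor = replicate(k, matrix(0, dims[1], dims[2]), simplify = FALSE),
      label = 1L,
      subject_id = "S1",
      trial_id = nm,
      experiment = as.integer(sub("^e(\\d+).*", "\\1", nm)),
      window_start = (seq_len(k) - 1L) * dims[1]
    )
  })
  emgrec:::new_emg_tensors(rows, "RAW",
                           window_spec(window_len = dims[1], step = dims[1]))
}

test_that("intra split gives 180/20/100 on a 300-window trial", {
  ds <- split_intra(trial_tensors(c(e1_t1 = 300L)), val_fraction = 0.1)
  expect_equal(unname(table(ds$split)[c("train", "val", "test")]),
               c(180L, 20L, 100L), ignore_attr = TRUE)
  # temporal ordering: all train windows precede val, which precede test
  expect_true(max(ds$window_start[ds$split == "train"]) <
              min(ds$window_start[ds$split == "val"]))
  expect_true(max(ds$window_start[ds$split == "val"]) <
              min(ds$window_start[ds$split == "test"]))
})

test_that("intra split handles the minimal 3-window trial and short trials", {
  ds <- split_intra(trial_tensors(c(e1_t1 = 3L)))
  expect_equal(sum(ds$split == "train"), 2L)
  expect_equal(sum(ds$split == "test"), 1L)
  expect_error(split_intra(trial_tensors(c(e1_t1 = 2L))), "too short")
})

test_that("inter split assigns whole experiments and rejects missing ids", {
  tens <- trial_tensors(c(e1_t1 = 10L, e1_t2 = 10L, e2_t1 = 8L, e2_t2 = 8L))
  ds <- split_inter(tens, train_experiment = 1L, test_experiment = 2L)
  expect_true(all(ds$split[ds$experiment == 2L] == "test"))
  expect_true(all(ds$split[ds$experiment == 1L] %in% c("train", "val")))
  expect_equal(sum(ds$split == "val"), 2L)  # 10% tail of each 10-window trial
  expect_error(split_inter(tens, 1L, 9L), "not present")
})

test_that("the leakage guard rejects double-assigned windows", {
  tens <- trial_tensors(c(e1_t1 = 6L))
  ds <- split_intra(tens)
  dup <- dplyr::bind_rows(ds, dplyr::mutate(ds[1, ], split = "test"))
  expect_error(assert_no_leakage(dup), "multiple splits")
  expect_silent(assert_no_leakage(ds))
  expect_error(assert_no_leakage(tens), "no split")
})

test_that("evaluation reports match a brute-force tally", {
  # hand-built 3-class prediction list scored against explicit enumeration
  truth <- c(1, 1, 1, 2, 2, 3, 3, 3, 3)
  pred <- c(1, 2, 1, 2, 2, 3, 1, 3, 2)
  fake_model <- structure(list(architecture = list(n_classes = 3L)),
                          class = "emg_model")
  rows <- tibble::tibble(
    tensor = replicate(length(truth), matrix(0, 4, 2), simplify = FALSE),
    label = as.integer(truth), subject_id = "S", trial_id = "t",
    experiment = 1L, window_start = seq_along(truth), split = "test")
  ds <- emgrec:::new_emg_tensors(rows, "RAW", window_spec(4, 4))

  # stub predict by computing the confusion matrix directly
  cm <- matrix(0L, 3, 3)
  for (i in seq_along(truth)) cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  expect_equal(diag(cm), c(2L, 2L, 2L))
  expect_equal(sum(cm), length(truth))

  # full evaluate_model on a genuinely trained model: see integration tests;
  # here check the report invariants via the internal constructor path
  ev <- structure(list(confusion = cm,
                       per_class_accuracy = diag(cm) / rowSums(cm),
                       overall_accuracy = sum(diag(cm)) / sum(cm),
                       n_test = length(truth), model_bytes = NA_integer_),
                  class = "emg_eval")
  expect_equal(ev$overall_accuracy, 6 / 9)
  expect_equal(unname(rowSums(ev$confusion)), as.integer(table(truth)),
               ignore_attr = TRUE)
  td <- tidy(ev)
  expect_equal(td$accuracy, c(2/3, 1, 1/2))
})

test_that("evaluate_model scores a trained model and flags absent classes", {
  arch <- tiny_arch()
  tens <- separable_tensors(n_per_class = 24)
  ds <- split_intra(tens)
  cfg <- train_config(epochs = 25, batch_size = 8, seed = 5,
                      lr_init = 0.005)
  model <- train_model(arch, ds, cfg)
  ev <- evaluate_model(model, ds)
  expect_equal(sum(ev$confusion), sum(ds$split == "test"))
  expect_equal(ev$overall_accuracy,
               sum(diag(ev$confusion)) / sum(ev$confusion))
  expect_gte(ev$overall_accuracy, 0.99)  # linearly separable classes

  # drop class 2 from the test set: its accuracy must be NA, not 0
  ds2 <- ds
  ds2$split[ds2$split == "test" & ds2$label == 2L] <- "train"
  ds2 <- emgrec:::new_emg_tensors(ds2, "RAW", attr(ds, "window_spec"))
  ev2 <- evaluate_model(model, ds2)
  expect_true(is.na(ev2$per_class_accuracy[2]))
  expect_false(is.na(ev2$per_class_accuracy[1]))
})

test_that("split-then-preprocess pipeline keeps splits disjoint in time", {
  sim <- simulate_semg(quick_protocol(), seed = 3)
  ds <- prepare_gesture_dataset(sim$recordings, sim$labels,
                                feature_kind = "RAW",
                                spec = window_spec(window_len = 200,
                                                   step = 200))
  expect_silent(assert_no_leakage(ds))
  by_trial <- split(ds, ds$trial_id)
  for (tr in by_trial) {
    if (!any(tr$split == "test")) next
    expect_true(min(tr$window_start[tr$split == "test"]) >
                max(tr$window_start[tr$split %in% c("train", "val")]))
  }
  # every trial contributes both train and test windows
  expect_true(all(purrr::map_lgl(by_trial, ~ any(.x$split == "test"))))
})

test_that("compare_grid crosses features with variants and favours FFT on spectral classes", {
  # two gestures distinguished almost purely by carrier band; per-channel
  # min-max normalization strips amplitude scale, so RAW windows carry
  # little class signal while FFT features separate cleanly
  p <- gesture_protocol(
    n_classes = 2, n_channels = 6, fs = 2000,
    trial_duration_s = 1.6, rest_duration_s = 0.2, repetitions = 2,
    activation_matrix = matrix(c(1.0, 0.8, 1.0, 0.8, 1.0, 0.8,
                                 0.55, 0.8, 0.55, 0.8, 0.55, 0.8),
                               nrow = 2, byrow = TRUE),
    carrier_bands = rbind(c(40, 100), c(300, 360)),
    noise_floor = 0.02)
  sim <- simulate_semg(p, seed = 77)
  cfg <- train_config(epochs = 12, batch_size = 8, seed = 77)
  grid <- compare_grid(sim$recordings, sim$labels,
                       feature_kinds = c("RAW", "FFT_RMS"),
                       variants = c("CNN_LSTM", "CNN2D_LSTM"),
                       cfg = cfg,
                       arch_args = list(conv1_maps = 16L, conv2_maps = 4L,
                                        lstm_units = 8L))
  expect_equal(nrow(grid), 4)  # 2 features x 2 variants
  expect_setequal(grid$feature_kind, c("RAW", "FFT_RMS"))
  # every row carries the flash estimate of its architecture
  expect_true(all(grid$flash_total > 0))
  expect_true(all(grid$model_bytes > 0))
  acc <- function(fk, v) grid$accuracy[grid$feature_kind == fk & grid$variant == v]
  for (v in unique(grid$variant)) {
    expect_gte(acc("FFT_RMS", v), acc("RAW", v))
  }
})
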