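test_that("generation is deterministic given the seed", {
  p <- quick_protocol()
  a <- simulate_semg(p, seed = 11)
  b <- simulate_semg(p, seed = 11)
  expect_identical(rec_matrix_for_tests(a$recordings[[1]]),
                   rec_matrix_for_tests(b$recordings[[1]]))
  expect_identical(a$labels, b$labels)
  c <- simulate_semg(p, seed = 12)
  expect_false(identical(rec_matrix_for_tests(a$recordings[[1]]),
                         rec_matrix_for_tests(c$recordings[[1]])))
})

test_that("label sidecar marks gesture windows at the protocol timing", {
  p <- quick_protocol()
  sim <- simulate_semg(p, seed = 2)
  expect_equal(nrow(sim$labels), p$n_classes * p$repetitions)
  block <- round((p$trial_duration_s + p$rest_duration_s) * p$fs)
  first <- sim$labels[sim$labels$experiment == 1, ]
  expect_equal(first$start_sample, (first$gesture_label - 1L) * block)
  expect_equal(first$end_sample - first$start_sample,
               rep(round(p$trial_duration_s * p$fs), p$n_classes))
})

test_that("channel RMS during activation scales with the activation weight", {
  p <- quick_protocol()
  sim <- simulate_semg(p, seed = 5)
  m <- rec_matrix_for_tests(sim$recordings[[1]])
  block <- round((p$trial_duration_s + p$rest_duration_s) * p$fs)
  n_trial <- round(p$trial_duration_s * p$fs)
  ramp <- round(p$onset_s * p$fs)
  for (g in seq_len(p$n_classes)) {
    # middle of the trial, past the envelope ramps
    rows <- ((g - 1) * block + ramp + 1):((g - 1) * block + n_trial - ramp)
    for (ch in seq_len(p$n_channels)) {
      w <- p$activation_matrix[g, ch]
      observed <- rms_of(m[rows, ch])
      expected <- sqrt(w^2 + p$noise_floor^2)
      if (w == 0) {
        # inactive channel: trial RMS is at the noise floor
        expect_lt(observed, 2 * p$noise_floor)
      } else {
        expect_equal(observed, expected, tolerance = 0.1)
      }
    }
  }
})

test_that("rest periods sit at the noise floor", {
  p <- quick_protocol()
  sim <- simulate_semg(p, seed = 8)
  m <- rec_matrix_for_tests(sim$recordings[[1]])
  block <- round((p$trial_duration_s + p$rest_duration_s) * p$fs)
  n_trial <- round(p$trial_duration_s * p$fs)
  rest_rows <- (n_trial + 1):block  # rest after gesture 1
  expect_equal(rms_of(m[rest_rows, 1]), p$noise_floor, tolerance = 0.1)
})

test_that("classes with disjoint carrier bands separate in FFT features", {
  # two classes distinguished only by carrier band
  p <- gesture_protocol(
    n_classes = 2, n_channels = 2, fs = 2000,
    trial_duration_s = 1, rest_duration_s = 0.2, repetitions = 1,
    activation_matrix = matrix(c(1, 0.8, 0.55, 0.8), nrow = 2, byrow = TRUE),
    carrier_bands = rbind(c(40, 100), c(300, 360)),
    noise_floor = 0.02)
  sim <- simulate_semg(p, seed = 21)
  tens <- build_feature_tensors(
    emg_preprocess(sim$recordings[[1]], filter_settings()),
    "FFT", window_spec(window_len = 200, step = 200),
    labels = sim$labels)
  # dominant non-DC FFT bin (first frame, 20 Hz resolution) falls inside the
  # class's own carrier band
  for (i in seq_len(nrow(tens))) {
    band <- p$carrier_bands[tens$label[i], ]
    spec <- tens$tensor[[i]][2:50, 1]  # bins 1..49 of frame 1, channel 1
    peak_hz <- which.max(spec) * 2000 / 100
    expect_gte(peak_hz, band[1] - 30)
    expect_lte(peak_hz, band[2] + 30)
  }
})

test_that("degenerate protocols are rejected", {
  expect_error(gesture_protocol(carrier_bands = cbind(rep(10, 16),
                                                      rep(100, 16))),
               "inside")
  am <- default_activation_matrix_for_tests()
  am[2, ] <- am[1, ]
  expect_error(gesture_protocol(activation_matrix = am), "too similar")
})

test_that("the default protocol satisfies its own invariants", {
  p <- gesture_protocol()
  expect_equal(dim(p$activation_matrix), c(16L, 6L))
  d <- as.matrix(dist(p$activation_matrix, method = "manhattan"))
  diag(d) <- Inf
  expect_gt(min(d), 0.2)
  expect_true(all(p$carrier_bands[, 1] > 20))
  expect_true(all(p$carrier_bands[, 2] < 1000))
  # the designated confusable pair shares its carrier band
  expect_equal(p$carrier_bands[7, ], p$carrier_bands[8, ])
})
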