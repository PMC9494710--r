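test_that("scalar features match hand-computed examples", {
  expect_equal(emg_mav(c(1, -1, 1, -1)), 1)
  expect_equal(emg_mav(c(3, -4)), 3.5)
  expect_equal(emg_mav(rep(0, 10)), 0)

  expect_equal(emg_rms(rep(-2, 5)), 2)
  expect_equal(emg_rms(c(3, -4)), sqrt(12.5))
  expect_equal(emg_rms(rep(0, 4)), 0)

  expect_equal(emg_wl(rep(5, 10)), 0)
  expect_equal(emg_wl(c(0, 1, 0, 1)), 3)
  expect_equal(emg_wl(c(0, 2, 5)), 5)  # monotone ramp telescopes

  expect_equal(emg_ssc(1:10), 0)            # strictly monotone
  expect_equal(emg_ssc(c(0, 1, 0, 1, 0)), 3)
  expect_equal(emg_ssc(rep(2, 5)), 0)

  expect_equal(emg_zc(c(1, 2, 3)), 0)       # all positive
  expect_equal(emg_zc(c(1, -1, 1, -1), epsilon = 0.5), 3)
  expect_equal(emg_zc(c(0.1, -0.1), epsilon = 1), 0)  # suppressed by threshold

  expect_error(emg_wl(1), "2 samples")
  expect_error(emg_ssc(c(1, 2)), "3 samples")
})

test_that("scalar features match brute-force oracles on random windows", {
  withr::with_seed(101, {
    for (rep in 1:1000) {
      n <- sample(3:50, 1)
      x <- rnorm(n)
      eps <- runif(1, 0, 0.5)
      expect_equal(emg_mav(x), oracle_mav(x))
      expect_equal(emg_rms(x), oracle_rms(x))
      expect_equal(emg_wl(x), oracle_wl(x))
      expect_equal(emg_ssc(x, eps), oracle_ssc(x, eps))
      expect_equal(emg_zc(x, eps), oracle_zc(x, eps))
    }
  })
})

test_that("scalar features are positively homogeneous and shift invariant", {
  withr::with_seed(7, {
    x <- rnorm(64)
    for (c in c(0.5, 2, 17)) {
      expect_equal(emg_rms(c * x), c * emg_rms(x))
      expect_equal(emg_wl(c * x), c * emg_wl(x))
      expect_equal(emg_mav(c * x), c * emg_mav(x))
    }
  })
  # periodic window shifted by one full period gives identical features
  per <- sin(2 * pi * (0:63) / 8)
  shifted <- sin(2 * pi * (8:71) / 8)
  expect_equal(emg_mav(per), emg_mav(shifted))
  expect_equal(emg_wl(per), emg_wl(shifted))
  expect_equal(emg_zc(per), emg_zc(shifted))
})

test_that("fft_magnitude agrees with a naive DFT oracle", {
  expect_equal(fft_magnitude(rep(0, 16)), rep(0, 16))
  # DC: bin 1 carries N*|c|
  mag <- fft_magnitude(rep(2, 100))
  expect_equal(mag[1], 200)
  expect_equal(max(abs(mag[-1])), 0, tolerance = 1e-9)
  # pure cosine at bin 5 of 100 -> magnitude 50 at bins 5 and 95 (0-based)
  x <- cos(2 * pi * 5 * (0:99) / 100)
  mag <- fft_magnitude(x)
  expect_equal(mag[6], 50, tolerance = 1e-9)
  expect_equal(mag[96], 50, tolerance = 1e-9)
  expect_lt(max(mag[-c(6, 96)]), 1e-9)

  withr::with_seed(13, {
    for (n in c(4, 16, 100)) {
      x <- rnorm(n)
      expect_equal(fft_magnitude(x), naive_dft_mag(x), tolerance = 1e-9)
    }
  })
})

test_that("window counts follow floor((n - len)/step) + 1", {
  rec <- emg_recording(matrix(rnorm(200 * 2), ncol = 2), fs = 2000)
  w <- sliding_windows(rec, window_spec(window_len = 200, step = 1))
  expect_equal(nrow(w), 2)  # one window per channel

  rec300 <- emg_recording(matrix(rnorm(300), ncol = 1), fs = 2000)
  w3 <- sliding_windows(rec300, window_spec(window_len = 100, step = 100))
  expect_equal(nrow(w3), 3)
  expect_equal(w3$window_start, c(0, 100, 200))

  expect_error(
    sliding_windows(emg_recording(matrix(rnorm(99), ncol = 1), fs = 2000),
                    window_spec(window_len = 100, step = 1)),
    "99")

  # randomized property versus explicit enumeration
  withr::with_seed(5, {
    for (i in 1:50) {
      len <- sample(2:40, 1)
      step <- sample(seq_len(len), 1)
      n <- len + sample(0:100, 1)
      starts <- emgrec:::window_starts(n, len, step)
      brute <- 0L
      s <- 0L
      while (s + len <= n) {
        brute <- brute + 1L
        s <- s + step
      }
      expect_equal(length(starts), brute)
      expect_equal(length(starts), (n - len) %/% step + 1)
    }
  })
})

test_that("feature tensors have the declared shapes and labels", {
  withr::with_seed(31, {
    rec <- emg_recording(matrix(runif(200 * 6), ncol = 6), fs = 2000,
                         gesture_label = 3L, trial_id = "t1",
                         subject_id = "S1")
  })
  raw <- build_feature_tensors(rec, "RAW")
  expect_equal(nrow(raw), 1)
  expect_equal(dim(raw$tensor[[1]]), c(200, 6))
  expect_equal(raw$label, 3L)
  expect_equal(raw$tensor[[1]], rec_matrix_for_tests(rec), ignore_attr = TRUE)

  # FFT of a constant window: per channel, bins 1 and 101 carry 100*c
  crec <- emg_recording(matrix(rep(c(0.5, 0.25), each = 200), ncol = 2),
                        fs = 2000, gesture_label = 1L)
  ft <- build_feature_tensors(crec, "FFT")
  tn <- ft$tensor[[1]]
  expect_equal(tn[1, ], c(50, 25))     # frame-1 DC bins
  expect_equal(tn[101, ], c(50, 25))   # frame-2 DC bins
  expect_equal(sum(abs(tn[-c(1, 101), ])), 0, tolerance = 1e-9)

  # FFT_RMS: the output frame's RMS equals the raw frame's time-domain RMS
  withr::with_seed(17, {
    rrec <- emg_recording(matrix(runif(200 * 6), ncol = 6), fs = 2000,
                          gesture_label = 2L)
  })
  fr <- build_feature_tensors(rrec, "FFT_RMS")$tensor[[1]]
  m <- rec_matrix_for_tests(rrec)
  for (ch in 1:6) {
    expect_equal(rms_of(fr[1:100, ch]), rms_of(m[1:100, ch]), tolerance = 1e-9)
    expect_equal(rms_of(fr[101:200, ch]), rms_of(m[101:200, ch]),
                 tolerance = 1e-9)
  }

  # scalar-feature tensors: 101 values then zero padding
  mv <- build_feature_tensors(rrec, "MAV")$tensor[[1]]
  expect_equal(dim(mv), c(200, 6))
  expect_true(all(mv[102:200, ] == 0))
  expect_equal(mv[1, 1], emg_mav(m[1:100, 1]))
  expect_equal(mv[101, 4], emg_mav(m[101:200, 4]))
})

test_that("unlabelled or out-of-range windows are rejected", {
  rec <- emg_recording(matrix(runif(400), ncol = 2), fs = 2000)
  expect_error(build_feature_tensors(rec, "RAW"), "label")
  labels <- tibble::tibble(trial_id = "t", subject_id = "s", experiment = 1L,
                           gesture_label = 1L, start_sample = 0L,
                           end_sample = 500L)
  expect_error(build_feature_tensors(rec, "RAW", labels = labels), "beyond")
})

test_that("feature store round-trips losslessly", {
  withr::with_seed(41, {
    rec <- emg_recording(matrix(runif(600 * 6), ncol = 6), fs = 2000,
                         gesture_label = 5L, trial_id = "t9",
                         subject_id = "S2")
  })
  tensors <- build_feature_tensors(rec, "FFT_RMS",
                                   window_spec(window_len = 200, step = 100))
  path <- withr::local_tempdir()
  save_features(tensors, path)
  back <- load_features(path)
  expect_identical(back$tensor, tensors$tensor)
  expect_identical(back$label, tensors$label)
  expect_identical(back$window_start, tensors$window_start)
  expect_identical(attr(back, "feature_kind"), "FFT_RMS")
  expect_identical(attr(back, "window_spec"), attr(tensors, "window_spec"))

  # empty set is a valid store
  empty <- tensors[0, ]
  empty <- emgrec:::new_emg_tensors(empty, "RAW", window_spec())
  p2 <- withr::local_tempdir()
  save_features(empty, p2)
  expect_equal(nrow(load_features(p2)), 0)

  # corrupting the manifest dims is caught on load
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  meta$dims <- c(100L, 6L)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE)
  expect_error(load_features(path), "expected")
})
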