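# Shared fixtures: tiny recordings, brute-force feature oracles, and a quick
# separable tensor set for training tests. Everything is generated in code.

tone_recording <- function(freq, n = 4000, fs = 2000, channels = 6) {
  t <- (seq_len(n) - 1) / fs
  emg_recording(matrix(rep(sin(2 * pi * freq * t), channels), ncol = channels),
                fs = fs)
}

rms_of <- function(x) sqrt(mean(x^2))

rec_matrix_for_tests <- function(rec) emgrec:::rec_matrix(rec)

default_activation_matrix_for_tests <- function() {
  emgrec:::default_activation_matrix()
}

# Brute-force loop oracles for the scalar features (independent of the
# vectorised implementations).
oracle_mav <- function(x) {
  s <- 0
  for (v in x) s <- s + abs(v)
  s / length(x)
}
oracle_rms <- function(x) {
  s <- 0
  for (v in x) s <- s + v^2
  sqrt(s / length(x))
}
oracle_wl <- function(x) {
  s <- 0
  for (k in 2:length(x)) s <- s + abs(x[k] - x[k - 1])
  s
}
oracle_ssc <- function(x, eps = 0) {
  n <- length(x)
  cnt <- 0
  for (k in 2:(n - 1)) {
    a <- x[k] - x[k - 1]
    b <- x[k] - x[k + 1]
    if (a * b > 0 && abs(a) > eps && abs(b) > eps) cnt <- cnt + 1
  }
  cnt
}
oracle_zc <- function(x, eps = 0) {
  cnt <- 0
  for (k in 2:length(x)) {
    if (sign(x[k]) != sign(x[k - 1]) && abs(x[k] - x[k - 1]) >= eps) {
      cnt <- cnt + 1
    }
  }
  cnt
}

# O(N^2) DFT magnitude oracle.
naive_dft_mag <- function(x) {
  n <- length(x)
  sapply(seq_len(n) - 1, function(k) {
    Mod(sum(x * exp(-2i * pi * k * (seq_len(n) - 1) / n)))
  })
}

# A small architecture that trains in seconds: one valid conv collapsing the
# 40x6 input to a single step, then an 8-unit LSTM.
tiny_arch <- function(n_classes = 2) {
  build_architecture("CNN_LSTM", input_shape = c(40L, 6L, 1L),
                     n_classes = n_classes, conv1_maps = 8L, lstm_units = 8L)
}

# Linearly separable two-class tensor set: per-class constant level plus
# small noise, organised as trials so the splitters work on it.
separable_tensors <- function(n_per_class = 30, dims = c(40L, 6L), seed = 99) {
  withr::local_seed(seed)
  rows <- purrr::map_dfr(1:2, function(cls) {
    tibble::tibble(
      tensor = lapply(seq_len(n_per_class), function(i) {
        matrix(0.2 + 0.6 * (cls - 1) + rnorm(prod(dims), sd = 0.05),
               nrow = dims[1])
      }),
      label = cls,
      subject_id = "S1",
      trial_id = sprintf("t%d", cls),
      experiment = 1L,
      window_start = (seq_len(n_per_class) - 1L) * dims[1]
    )
  })
  emgrec:::new_emg_tensors(rows, "RAW", window_spec(window_len = dims[1],
                                                    step = dims[1]))
}

# Small, fast protocol for integration tests: 4 classes, shorter trials.
quick_protocol <- function(...) {
  gesture_protocol(
    n_classes = 4, n_channels = 6, fs = 2000,
    trial_duration_s = 1.2, rest_duration_s = 0.3, repetitions = 2,
    activation_matrix = matrix(c(
      1.0, 0.1, 0.0, 0.0, 0.0, 0.0,
      0.0, 0.0, 1.0, 0.1, 0.0, 0.0,
      0.0, 0.0, 0.0, 0.0, 1.0, 0.1,
      0.5, 0.5, 0.5, 0.5, 0.5, 0.5), nrow = 4, byrow = TRUE),
    carrier_bands = cbind(c(30, 120, 210, 300), c(80, 170, 260, 350)),
    ...
  )
}
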