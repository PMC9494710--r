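# Default 16-gesture x 6-channel activation design. Rows are gestures,
# columns electrode channels; weights scale each channel's carrier RMS.
# Gestures 7 and 8 are deliberately near-identical (shared musculature),
# mimicking the index/middle-finger pinch pair that dominates real
# confusion matrices.
default_activation_matrix <- function() {
  m <- matrix(c(
    1.0, 0.2, 0.0, 0.0, 0.0, 0.0,
    0.0, 1.0, 0.2, 0.0, 0.0, 0.0,
    0.0, 0.0, 1.0, 0.2, 0.0, 0.0,
    0.0, 0.0, 0.0, 1.0, 0.2, 0.0,
    0.0, 0.0, 0.0, 0.0, 1.0, 0.2,
    0.2, 0.0, 0.0, 0.0, 0.0, 1.0,
    0.9, 0.8, 0.0, 0.0, 0.30, 0.0,
    0.9, 0.7, 0.0, 0.0, 0.45, 0.0,
    0.0, 0.9, 0.9, 0.0, 0.0, 0.0,
    0.0, 0.0, 0.9, 0.9, 0.0, 0.0,
    0.0, 0.0, 0.0, 0.9, 0.9, 0.0,
    0.0, 0.0, 0.0, 0.0, 0.9, 0.9,
    0.9, 0.0, 0.0, 0.9, 0.0, 0.0,
    0.0, 0.9, 0.0, 0.0, 0.9, 0.0,
    0.0, 0.0, 0.9, 0.0, 0.0, 0.9,
    0.6, 0.6, 0.6, 0.6, 0.6, 0.6
  ), nrow = 16, byrow = TRUE)
  rownames(m) <- paste0("g", 1:16)
  m
}

# Per-gesture carrier bands inside the physiological 20-450 Hz sEMG band.
# Gesture 8 shares gesture 7's band (the confusable pair).
default_carrier_bands <- function(n_classes = 16) {
  lo <- 30 + 24 * (seq_len(n_classes) - 1)
  hi <- lo + 50
  bands <- cbind(low_hz = lo, high_hz = hi)
  if (n_classes >= 8) bands[8, ] <- bands[7, ]
  bands
}

#' Synthetic acquisition protocol
#'
#' Describes a seeded stand-in for a multichannel sEMG acquisition session:
#' 16 gestures, 6 channels at 2 kHz, each gesture held for 3 s with 1 s rest,
#' the whole sequence repeated 3 times (each repetition is one "experiment").
#' Each gesture excites each channel with a band-limited Gaussian carrier
#' scaled by a per-gesture, per-channel activation weight and a raised-cosine
#' on/off envelope; a white noise floor is present throughout. Two gestures
#' (7 and 8) share their carrier band and have near-identical activations, so
#' they are intrinsically confusable.
#'
#' @param n_classes,n_channels,fs Protocol dimensions and sampling rate (Hz).
#' @param trial_duration_s,rest_duration_s,repetitions Timing of the session.
#' @param activation_matrix `n_classes x n_channels` weights in `[0, 1]`;
#'   rows must be pairwise distinct (L1 distance > 0.2).
#' @param carrier_bands `n_classes x 2` matrix of (low, high) band edges in
#'   Hz, strictly inside (20, fs/2).
#' @param noise_floor Relative RMS of the ever-present white noise.
#' @param onset_s Raised-cosine onset/offset ramp length in seconds.
#' @param seed Default seed used by [simulate_semg()].
#' @return A list of class `gesture_protocol`.
#' @export
gesture_protocol <- function(n_classes = 16, n_channels = 6, fs = 2000,
                             trial_duration_s = 3, rest_duration_s = 1,
                             repetitions = 3,
                             activation_matrix = NULL,
                             carrier_bands = NULL,
                             noise_floor = 0.05, onset_s = 0.2, seed = 1L) {
  if (is.null(activation_matrix)) {
    activation_matrix <- default_activation_matrix()[
      seq_len(n_classes), seq_len(n_channels), drop = FALSE]
  }
  if (is.null(carrier_bands)) carrier_bands <- default_carrier_bands(n_classes)
  stopifnot(nrow(activation_matrix) == n_classes,
            ncol(activation_matrix) == n_channels,
            all(activation_matrix >= 0 & activation_matrix <= 1),
            nrow(carrier_bands) == n_classes)
  if (any(carrier_bands[, 1] <= 20) || any(carrier_bands[, 2] >= fs / 2) ||
      any(carrier_bands[, 2] <= carrier_bands[, 1])) {
    abort("carrier bands must be ordered and lie strictly inside (20, fs/2) Hz")
  }
  d <- as.matrix(stats::dist(activation_matrix, method = "manhattan"))
  diag(d) <- Inf
  if (min(d) <= 0.2) {
    worst <- which(d == min(d), arr.ind = TRUE)[1, ]
    abort(sprintf("activation rows %d and %d are too similar (L1 = %.3f <= 0.2)",
                  worst[1], worst[2], min(d)))
  }
  structure(list(n_classes = as.integer(n_classes),
                 n_channels = as.integer(n_channels), fs = fs,
                 trial_duration_s = trial_duration_s,
                 rest_duration_s = rest_duration_s,
                 repetitions = as.integer(repetitions),
                 activation_matrix = activation_matrix,
                 carrier_bands = carrier_bands,
                 noise_floor = noise_floor, onset_s = onset_s,
                 seed = as.integer(seed)),
            class = "gesture_protocol")
}

raised_cosine_envelope <- function(n, ramp_n) {
  env <- rep(1, n)
  if (ramp_n > 0 && 2 * ramp_n <= n) {
    up <- 0.5 * (1 - cos(pi * seq_len(ramp_n) / ramp_n))
    env[seq_len(ramp_n)] <- up
    env[(n - ramp_n + 1):n] <- rev(up)
  }
  env
}

# Unit-RMS Gaussian noise band-limited to [low, high] Hz.
bandlimited_carrier <- function(n, low, high, fs) {
  filt <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  x <- signal::filtfilt(filt, rnorm(n))
  x / sqrt(mean(x^2))
}

#' Generate a synthetic sEMG session
#'
#' Produces one recording per protocol repetition plus the label sidecar in
#' the exact dialect the preprocessing stage reads. Deterministic given the
#' seed.
#'
#' @param protocol A [gesture_protocol()].
#' @param seed Overrides `protocol$seed`.
#' @return A list with `recordings` (list of [emg_recording()], one per
#'   repetition) and `labels` (sidecar tibble with a `recording` index
#'   column).
#' @export
simulate_semg <- function(protocol = gesture_protocol(), seed = NULL) {
  seed <- seed %||% protocol$seed
  withr::local_seed(seed)
  fs <- protocol$fs
  n_trial <- round(protocol$trial_duration_s * fs)
  n_rest <- round(protocol$rest_duration_s * fs)
  ramp_n <- round(protocol$onset_s * fs)
  block <- n_trial + n_rest
  n_total <- protocol$n_classes * block
  env <- raised_cosine_envelope(n_trial, ramp_n)

  recordings <- vector("list", protocol$repetitions)
  labels <- list()
  for (r in seq_len(protocol$repetitions)) {
    m <- matrix(rnorm(n_total * protocol$n_channels, sd = protocol$noise_floor),
                nrow = n_total, ncol = protocol$n_channels)
    for (g in seq_len(protocol$n_classes)) {
      start <- (g - 1L) * block
      band <- protocol$carrier_bands[g, ]
      for (ch in seq_len(protocol$n_channels)) {
        w <- protocol$activation_matrix[g, ch]
        if (w == 0) next
        carrier <- bandlimited_carrier(n_trial, band[1], band[2], fs)
        rows <- (start + 1):(start + n_trial)
        m[rows, ch] <- m[rows, ch] + w * env * carrier
      }
      labels[[length(labels) + 1]] <- tibble::tibble(
        trial_id = sprintf("r%d_g%02d", r, g),
        subject_id = "S1",
        experiment = r,
        gesture_label = g,
        start_sample = start,
        end_sample = start + n_trial,
        recording = r
      )
    }
    recordings[[r]] <- emg_recording(m, fs = fs, subject_id = "S1",
                                     trial_id = sprintf("rep%d", r))
  }
  list(recordings = recordings, labels = dplyr::bind_rows(labels))
}
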