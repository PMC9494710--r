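#' Filter settings for sEMG conditioning
#'
#' Defaults follow common sEMG practice: a third-order 20 Hz Butterworth
#' high-pass removes motion artifact and electrode drift, and a narrow 50 Hz
#' notch (biquad, Q = 30) suppresses power-line interference. The low-pass
#' stage is disabled by default: the acquisition chain's anti-aliasing filter
#' is analog, and any digital cutoff must sit strictly below Nyquist. All
#' filters are applied forward-backward (zero phase), so channels stay
#' time-aligned.
#'
#' @param highpass_cutoff_hz High-pass cutoff in Hz; `NULL` disables the stage.
#' @param highpass_order Butterworth order of the high-pass.
#' @param lowpass_cutoff_hz Low-pass cutoff in Hz; `NULL` (default) disables.
#' @param lowpass_order Butterworth order of the low-pass.
#' @param notch_freq_hz Notch centre frequency in Hz; `NULL` disables.
#' @param notch_quality Dimensionless notch Q (centre / -3 dB bandwidth).
#' @param normalize Apply per-channel min-max scaling onto `[0, 1]`.
#'
#' @return A list of class `filter_settings`.
#' @export
filter_settings <- function(highpass_cutoff_hz = 20, highpass_order = 3,
                            lowpass_cutoff_hz = NULL, lowpass_order = 3,
                            notch_freq_hz = 50, notch_quality = 30,
                            normalize = TRUE) {
  stopifnot(is.null(highpass_cutoff_hz) || highpass_cutoff_hz > 0,
            is.null(lowpass_cutoff_hz) || lowpass_cutoff_hz > 0,
            is.null(notch_freq_hz) || notch_freq_hz > 0,
            highpass_order >= 1, lowpass_order >= 1, notch_quality > 0,
            is.logical(normalize))
  structure(list(
    highpass_cutoff_hz = highpass_cutoff_hz,
    highpass_order = highpass_order,
    lowpass_cutoff_hz = lowpass_cutoff_hz,
    lowpass_order = lowpass_order,
    notch_freq_hz = notch_freq_hz,
    notch_quality = notch_quality,
    normalize = isTRUE(normalize)
  ), class = "filter_settings")
}

check_cutoff <- function(cutoff, fs, what) {
  if (cutoff >= fs / 2) {
    abort(sprintf(
      "%s cutoff %g Hz is not below the Nyquist frequency %g Hz (fs = %g Hz)",
      what, cutoff, fs / 2, fs))
  }
}

# Zero-phase application of one filter to every channel independently.
# Signals are extended by odd reflection before filtfilt and trimmed after,
# so start-up transients decay inside the padding, not inside the data.
apply_filtfilt <- function(rec, filt, pad_s = 0.5) {
  m <- rec_matrix(rec)
  n <- nrow(m)
  p <- min(n - 1L, max(12L, round(pad_s * emg_fs(rec))))
  out <- apply(m, 2, function(x) {
    if (p < 1L) return(signal::filtfilt(filt, x))
    xp <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
    signal::filtfilt(filt, xp)[(p + 1):(p + n)]
  })
  rec_replace(rec, matrix(out, nrow = n, dimnames = dimnames(m)))
}

#' Butterworth high-pass stage
#'
#' @param rec An [emg_recording()].
#' @param settings A [filter_settings()] object.
#' @return The filtered recording (same shape).
#' @export
emg_highpass <- function(rec, settings = filter_settings()) {
  fc <- settings$highpass_cutoff_hz
  if (is.null(fc)) return(rec)
  check_cutoff(fc, emg_fs(rec), "high-pass")
  filt <- signal::butter(settings$highpass_order, fc / (emg_fs(rec) / 2),
                         type = "high")
  apply_filtfilt(rec, filt)
}

#' Butterworth low-pass stage
#'
#' Disabled unless a cutoff below Nyquist is configured; see
#' [filter_settings()].
#'
#' @inheritParams emg_highpass
#' @return The filtered recording (same shape).
#' @export
emg_lowpass <- function(rec, settings = filter_settings()) {
  fc <- settings$lowpass_cutoff_hz
  if (is.null(fc)) return(rec)
  check_cutoff(fc, emg_fs(rec), "low-pass")
  filt <- signal::butter(settings$lowpass_order, fc / (emg_fs(rec) / 2),
                         type = "low")
  apply_filtfilt(rec, filt)
}

# RBJ audio-cookbook biquad notch: b = [1, -2 cos w0, 1] (gain-normalised),
# a = [1 + alpha, -2 cos w0, 1 - alpha], alpha = sin(w0) / (2 Q).
notch_biquad <- function(freq_hz, fs, q) {
  w0 <- 2 * pi * freq_hz / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  signal::Arma(b = b, a = a)
}

#' Power-line notch stage
#'
#' @inheritParams emg_highpass
#' @return The filtered recording (same shape).
#' @export
emg_notch <- function(rec, settings = filter_settings()) {
  f0 <- settings$notch_freq_hz
  if (is.null(f0)) return(rec)
  check_cutoff(f0, emg_fs(rec), "notch")
  apply_filtfilt(rec, notch_biquad(f0, emg_fs(rec), settings$notch_quality))
}

#' Per-channel min-max normalization
#'
#' Maps each channel affinely onto `[0, 1]` over the whole recording. The
#' original per-channel ranges are stored in the `norm_ranges` attribute so
#' the mapping is invertible. A constant channel (max equals min) is mapped to
#' 0.5 everywhere, with a warning.
#'
#' @param rec An [emg_recording()].
#' @return The normalized recording.
#' @export
emg_normalize <- function(rec) {
  m <- rec_matrix(rec)
  lo <- unname(apply(m, 2, min))
  hi <- unname(apply(m, 2, max))
  flat <- hi == lo
  if (any(flat)) {
    warn(sprintf("constant channel(s) mapped to 0.5: %s",
                 paste(colnames(m)[flat], collapse = ", ")))
  }
  scale <- ifelse(flat, 1, hi - lo)
  out <- sweep(sweep(m, 2, lo), 2, scale, "/")
  out[, flat] <- 0.5
  res <- rec_replace(rec, out)
  attr(res, "norm_ranges") <- tibble::tibble(
    channel = colnames(m), min = lo, max = hi)
  res
}

#' Full preprocessing pipeline
#'
#' Applies, in order: high-pass, low-pass (when enabled), notch, min-max
#' normalization. Run this after any train/test split so normalization
#' statistics never leak between splits.
#'
#' @inheritParams emg_highpass
#' @param verbose Log the applied stage order to stderr.
#' @return The conditioned recording.
#' @export
emg_preprocess <- function(rec, settings = filter_settings(), verbose = FALSE) {
  stages <- c(
    if (!is.null(settings$highpass_cutoff_hz)) "highpass",
    if (!is.null(settings$lowpass_cutoff_hz)) "lowpass",
    if (!is.null(settings$notch_freq_hz)) "notch",
    if (settings$normalize) "normalize"
  )
  if (verbose) message("preprocess order: ", paste(stages, collapse = " -> "))
  out <- emg_highpass(rec, settings)
  out <- emg_lowpass(out, settings)
  out <- emg_notch(out, settings)
  if (settings$normalize) out <- emg_normalize(out)
  out
}
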