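#' Construct a multichannel sEMG recording
#'
#' An `emg_recording` is a tibble with one column per electrode channel and one
#' row per sample, carrying the sampling frequency and provenance identifiers
#' as attributes. All preprocessing and feature functions accept and return
#' this class, so pipelines compose with the pipe.
#'
#' @param data A data frame, matrix, or tibble of amplitudes; rows are samples,
#'   columns are channels. All values must be finite.
#' @param fs Sampling frequency in Hz (the hardware described here samples at
#'   2000 Hz).
#' @param channel_names Optional channel labels; defaults to existing column
#'   names or `ch1..chK`.
#' @param subject_id,trial_id,gesture_label Optional provenance identifiers.
#'
#' @return A tibble of class `emg_recording`.
#' @export
#' @examples
#' rec <- emg_recording(matrix(rnorm(600), ncol = 6), fs = 2000)
#' n_samples(rec)
emg_recording <- function(data, fs,
                          channel_names = NULL,
                          subject_id = NA_character_,
                          trial_id = NA_character_,
                          gesture_label = NA_integer_) {
  if (is.matrix(data)) data <- as.data.frame(data)
  data <- tibble::as_tibble(data, .name_repair = "minimal")
  if (nrow(data) < 1L) abort("a recording needs at least one sample")
  if (!all(vapply(data, is.numeric, logical(1)))) {
    abort("all channels must be numeric")
  }
  if (!all(vapply(data, function(x) all(is.finite(x)), logical(1)))) {
    abort("recording contains missing or non-finite values")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    abort("`fs` must be a single positive number (Hz)")
  }
  if (is.null(channel_names)) {
    channel_names <- names(data)
    if (is.null(channel_names) || any(channel_names == "")) {
      channel_names <- paste0("ch", seq_len(ncol(data)))
    }
  }
  stopifnot(length(channel_names) == ncol(data))
  names(data) <- channel_names

  structure(data,
    fs = as.numeric(fs),
    subject_id = subject_id,
    trial_id = trial_id,
    gesture_label = gesture_label,
    class = c("emg_recording", class(tibble::tibble()))
  )
}

#' @rdname emg_recording
#' @param rec An `emg_recording`.
#' @export
emg_fs <- function(rec) attr(rec, "fs")

#' @rdname emg_recording
#' @export
n_samples <- function(rec) nrow(rec)

#' @rdname emg_recording
#' @export
n_channels <- function(rec) ncol(rec)

# Signal values as an n_samples x n_channels matrix.
rec_matrix <- function(rec) {
  m <- as.matrix(as.data.frame(unclass(rec))[names(rec)])
  dimnames(m) <- list(NULL, names(rec))
  m
}

# Rebuild a recording around new sample values, keeping metadata.
rec_replace <- function(rec, values) {
  out <- tibble::as_tibble(as.data.frame(values, optional = TRUE),
                           .name_repair = "minimal")
  names(out) <- names(rec)
  for (a in c("fs", "subject_id", "trial_id", "gesture_label", "norm_ranges")) {
    attr(out, a) <- attr(rec, a)
  }
  class(out) <- class(rec)
  out
}

# Contiguous sample slice [from, to) in 0-based coordinates.
rec_slice <- function(rec, from, to) {
  stopifnot(from >= 0, to <= nrow(rec), to > from)
  rec_replace(rec, rec_matrix(rec)[(from + 1L):to, , drop = FALSE])
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf("<emg_recording> %d samples x %d channels @ %g Hz\n",
              nrow(x), ncol(x), emg_fs(x)))
  if (!is.na(attr(x, "trial_id"))) {
    cat(sprintf("  trial %s, subject %s, gesture %s\n",
                attr(x, "trial_id"), attr(x, "subject_id"),
                attr(x, "gesture_label")))
  }
  NextMethod()
}

#' Plot recording channels over time
#'
#' @param object An `emg_recording`.
#' @param ... Unused.
#' @return A ggplot object with one facet per channel.
#' @export
autoplot.emg_recording <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(unclass(object))) |>
    dplyr::mutate(time_s = (dplyr::row_number() - 1) / emg_fs(object)) |>
    tidyr::pivot_longer(-"time_s", names_to = "channel", values_to = "amplitude")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_s, .data$amplitude)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel)) +
    ggplot2::labs(x = "time [s]", y = "amplitude")
}
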