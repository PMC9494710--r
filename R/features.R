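#' Windowing parameters
#'
#' Network-input windows are 200 samples (100 ms at 2 kHz) slid without
#' overlap by default. Inside each window, FFT frames are 100 samples at step
#' 100 (two non-overlapping frames), and scalar time-domain features stream
#' over 100-sample sub-windows at step 1. `zc_epsilon` is the amplitude
#' threshold that gates zero-crossing and slope-sign-change counts against
#' noise, expressed on the normalized `[0, 1]` scale.
#'
#' @param window_len Network-input window length in samples.
#' @param step Step between consecutive network-input windows in samples.
#' @param frame_len,frame_step FFT frame length and step within a window.
#' @param scalar_len,scalar_step Sub-window length and step for scalar
#'   features within a window.
#' @param zc_epsilon Noise-rejection threshold for ZC and SSC.
#' @return A list of class `window_spec`.
#' @export
window_spec <- function(window_len = 200, step = 200,
                        frame_len = 100, frame_step = 100,
                        scalar_len = 100, scalar_step = 1,
                        zc_epsilon = 0.01) {
  stopifnot(window_len >= 1, step >= 1, step <= window_len,
            frame_len >= 1, frame_step >= 1,
            scalar_len >= 1, scalar_step >= 1, zc_epsilon >= 0)
  structure(list(window_len = as.integer(window_len), step = as.integer(step),
                 frame_len = as.integer(frame_len),
                 frame_step = as.integer(frame_step),
                 scalar_len = as.integer(scalar_len),
                 scalar_step = as.integer(scalar_step),
                 zc_epsilon = zc_epsilon),
            class = "window_spec")
}

# 0-based half-open window starts for a signal of length n.
window_starts <- function(n, window_len, step) {
  if (n < window_len) {
    abort(sprintf("signal of %d samples is shorter than the window (%d)",
                  n, window_len))
  }
  seq(0L, n - window_len, by = step)
}

#' Segment a recording into sliding windows
#'
#' Windows are half-open sample ranges `[start, start + window_len)` in
#' 0-based coordinates; their count per channel is
#' `floor((n_samples - window_len) / step) + 1`.
#'
#' @param rec An [emg_recording()].
#' @param spec A [window_spec()]; `window_len` and `step` are used.
#' @return A tibble with one row per (channel, window): columns `channel`,
#'   `window_start`, and the list-column `values`.
#' @export
sliding_windows <- function(rec, spec = window_spec()) {
  starts <- window_starts(n_samples(rec), spec$window_len, spec$step)
  m <- rec_matrix(rec)
  tidyr::expand_grid(channel = colnames(m), window_start = starts) |>
    dplyr::mutate(values = purrr::map2(
      .data$channel, .data$window_start,
      function(ch, s) m[(s + 1):(s + spec$window_len), ch]
    ))
}

#' Time-domain scalar features
#'
#' The five classical windowed sEMG descriptors. `emg_mav` is the mean
#' absolute amplitude (contraction level); `emg_rms` the root mean square
#' (average power); `emg_wl` the waveform length, i.e. the cumulative absolute
#' first difference; `emg_ssc` counts slope-sign changes whose adjacent
#' differences both exceed `epsilon`; `emg_zc` counts sign changes whose jump
#' is at least `epsilon`.
#'
#' @param x Numeric vector: the samples of one window.
#' @param epsilon Noise-rejection threshold for `emg_ssc` / `emg_zc`.
#' @return A single non-negative number.
#' @export
#' @examples
#' emg_mav(c(3, -4))   # 3.5
#' emg_rms(c(3, -4))   # sqrt(12.5)
#' emg_wl(c(0, 1, 0))  # 2
emg_mav <- function(x) {
  if (length(x) < 1) abort("empty window")
  mean(abs(x))
}

#' @rdname emg_mav
#' @export
emg_rms <- function(x) {
  if (length(x) < 1) abort("empty window")
  sqrt(mean(x^2))
}

#' @rdname emg_mav
#' @export
emg_wl <- function(x) {
  if (length(x) < 2) abort("waveform length needs at least 2 samples")
  sum(abs(diff(x)))
}

#' @rdname emg_mav
#' @export
emg_ssc <- function(x, epsilon = 0) {
  n <- length(x)
  if (n < 3) abort("slope sign change needs at least 3 samples")
  d_prev <- x[2:(n - 1)] - x[1:(n - 2)]
  d_next <- x[2:(n - 1)] - x[3:n]
  sum(d_prev * d_next > 0 & abs(d_prev) > epsilon & abs(d_next) > epsilon)
}

#' @rdname emg_mav
#' @export
emg_zc <- function(x, epsilon = 0) {
  n <- length(x)
  if (n < 2) abort("zero crossing needs at least 2 samples")
  s <- sign(x)
  sum(s[-1] != s[-n] & abs(diff(x)) >= epsilon)
}

#' N-point DFT magnitude of a window
#'
#' Unnormalized two-sided magnitude spectrum in standard DFT bin order
#' (bin 1 = DC).
#'
#' @param x Numeric vector.
#' @return Numeric vector of `length(x)` magnitudes.
#' @export
fft_magnitude <- function(x) Mod(fft(x))

scalar_feature_fns <- function(epsilon) {
  list(
    MAV = emg_mav,
    WL = emg_wl,
    SSC = function(x) emg_ssc(x, epsilon),
    ZC = function(x) emg_zc(x, epsilon),
    RMS = emg_rms
  )
}

#' Stream scalar features over a recording
#'
#' Computes the selected scalar features on sliding sub-windows
#' (`scalar_len` samples at `scalar_step`) for every channel, returning a tidy
#' table — the exploratory view of what [build_feature_tensors()] packs into
#' network inputs.
#'
#' @param rec An [emg_recording()].
#' @param spec A [window_spec()].
#' @param features Subset of `c("MAV", "WL", "SSC", "ZC", "RMS")`.
#' @return A tibble with columns `channel`, `window_start`, `feature`,
#'   `value`.
#' @export
window_features <- function(rec, spec = window_spec(),
                            features = c("MAV", "WL", "SSC", "ZC", "RMS")) {
  features <- match.arg(features, several.ok = TRUE)
  fns <- scalar_feature_fns(spec$zc_epsilon)[features]
  starts <- window_starts(n_samples(rec), spec$scalar_len, spec$scalar_step)
  m <- rec_matrix(rec)
  purrr::map_dfr(colnames(m), function(ch) {
    purrr::map_dfr(names(fns), function(fname) {
      vals <- vapply(starts, function(s) {
        fns[[fname]](m[(s + 1):(s + spec$scalar_len), ch])
      }, numeric(1))
      tibble::tibble(channel = ch, window_start = starts,
                     feature = fname, value = vals)
    })
  })
}

feature_kinds <- c("RAW", "MAV", "WL", "SSC", "ZC", "RMS", "FFT", "FFT_RMS")

# One window_len x n_channels feature matrix from one raw window matrix.
window_to_tensor <- function(wm, feature_kind, spec) {
  N <- nrow(wm)
  dimnames(wm) <- NULL
  out <- switch(feature_kind,
    RAW = wm,
    FFT = apply(wm, 2, function(x) {
      starts <- window_starts(N, spec$frame_len, spec$frame_step)
      unlist(lapply(starts, function(s) {
        fft_magnitude(x[(s + 1):(s + spec$frame_len)])
      }))
    }),
    FFT_RMS = apply(wm, 2, function(x) {
      starts <- window_starts(N, spec$frame_len, spec$frame_step)
      unlist(lapply(starts, function(s) {
        frame <- x[(s + 1):(s + spec$frame_len)]
        mag <- fft_magnitude(frame)
        mag_rms <- emg_rms(mag)
        if (mag_rms == 0) return(mag)   # silent frame: keep zeros
        mag / mag_rms * emg_rms(frame)
      }))
    }),
    { # scalar feature stream, zero-padded to the window length
      fn <- scalar_feature_fns(spec$zc_epsilon)[[feature_kind]]
      apply(wm, 2, function(x) {
        starts <- window_starts(N, spec$scalar_len, spec$scalar_step)
        vals <- vapply(starts, function(s) {
          fn(x[(s + 1):(s + spec$scalar_len)])
        }, numeric(1))
        c(vals, numeric(N - length(vals)))
      })
    }
  )
  dimnames(out) <- NULL
  out
}

#' Build network-input feature tensors
#'
#' Cuts each channel into `window_len`-sample windows and converts every
#' window into a `window_len x n_channels` feature matrix (conceptually
#' `window_len x n_channels x 1`, the network's input shape):
#'
#' * `RAW`: the preprocessed samples as-is.
#' * `FFT`: each window is split into non-overlapping `frame_len` frames and
#'   each frame replaced by its DFT magnitudes.
#' * `FFT_RMS`: as `FFT`, but each frame's magnitude vector is rescaled to
#'   unit RMS and multiplied by the raw frame's time-domain RMS, fusing
#'   spectral shape with contraction intensity.
#' * `MAV`/`WL`/`SSC`/`ZC`/`RMS`: the scalar streamed over `scalar_len`
#'   sub-windows at `scalar_step`, zero-padded to `window_len`.
#'
#' When a label table is supplied, windows are cut per labelled segment (so no
#' window straddles segments) and labelled accordingly; without labels the
#' recording's own `gesture_label` attribute is used, and windows span the
#' whole recording.
#'
#' @param rec A preprocessed [emg_recording()].
#' @param feature_kind One of
#'   `r paste0('\x60', c("RAW","MAV","WL","SSC","ZC","RMS","FFT","FFT_RMS"), '\x60', collapse = ", ")`.
#' @param spec A [window_spec()].
#' @param labels Optional label sidecar tibble (see [read_labels_csv()]).
#' @return A tibble of class `emg_tensors`: list-column `tensor` plus
#'   `label`, `subject_id`, `trial_id`, `experiment`, `window_start`.
#' @export
build_feature_tensors <- function(rec, feature_kind = "RAW",
                                  spec = window_spec(), labels = NULL) {
  feature_kind <- match.arg(feature_kind, feature_kinds)
  m <- rec_matrix(rec)

  segments <- if (is.null(labels)) {
    lbl <- attr(rec, "gesture_label")
    if (is.null(lbl) || is.na(lbl)) {
      abort("recording carries no gesture label; pass `labels` or set one")
    }
    tibble::tibble(trial_id = attr(rec, "trial_id"),
                   subject_id = attr(rec, "subject_id"),
                   experiment = NA_integer_,
                   gesture_label = as.integer(lbl),
                   start_sample = 0L, end_sample = nrow(m))
  } else {
    if (max(labels$end_sample) > nrow(m)) {
      abort("label ranges extend beyond the recording")
    }
    labels
  }

  rows <- purrr::pmap_dfr(segments, function(trial_id, subject_id, experiment,
                                             gesture_label, start_sample,
                                             end_sample, ...) {
    seg <- m[(start_sample + 1):end_sample, , drop = FALSE]
    starts <- window_starts(nrow(seg), spec$window_len, spec$step)
    tibble::tibble(
      tensor = lapply(starts, function(s) {
        window_to_tensor(seg[(s + 1):(s + spec$window_len), , drop = FALSE],
                         feature_kind, spec)
      }),
      label = as.integer(gesture_label),
      subject_id = as.character(subject_id),
      trial_id = as.character(trial_id),
      experiment = as.integer(experiment),
      window_start = as.integer(start_sample + starts)
    )
  })
  new_emg_tensors(rows, feature_kind, spec)
}

new_emg_tensors <- function(rows, feature_kind, spec) {
  structure(rows,
            feature_kind = feature_kind,
            window_spec = spec,
            class = c("emg_tensors", class(tibble::tibble())))
}

#' @export
print.emg_tensors <- function(x, ...) {
  dims <- if (nrow(x) > 0) paste(dim(x$tensor[[1]]), collapse = "x") else "-"
  cat(sprintf("<emg_tensors> %d windows, kind %s, tensor %s\n",
              nrow(x), attr(x, "feature_kind"), dims))
  NextMethod()
}

tensors_feature_kind <- function(tensors) attr(tensors, "feature_kind")

store_schema_version <- 1L

#' Persist feature tensors
#'
#' Writes the tensor set into a directory: a Parquet table holding the
#' flattened tensors and provenance, plus a JSON manifest with the feature
#' kind, tensor dimensions, window spec and schema version. The round trip
#' through [load_features()] is lossless.
#'
#' @param tensors An `emg_tensors` tibble from [build_feature_tensors()].
#' @param path Directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
save_features <- function(tensors, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  dims <- if (nrow(tensors) > 0) dim(tensors$tensor[[1]]) else
    c(attr(tensors, "window_spec")$window_len, 0L)
  flat <- tibble::tibble(
    values = lapply(tensors$tensor, as.vector),
    label = tensors$label,
    subject_id = tensors$subject_id,
    trial_id = tensors$trial_id,
    experiment = tensors$experiment,
    window_start = tensors$window_start
  )
  arrow::write_parquet(flat, file.path(path, "features.parquet"))
  meta <- list(schema_version = store_schema_version,
               feature_kind = attr(tensors, "feature_kind"),
               dims = as.integer(dims),
               window_spec = unclass(attr(tensors, "window_spec")))
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_features
#' @export
load_features <- function(path) {
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) {
    abort(sprintf("not a feature store (missing meta.json): %s", path))
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(as.integer(meta$schema_version), store_schema_version)) {
    abort(sprintf("feature store schema version %s is not supported",
                  meta$schema_version))
  }
  flat <- arrow::read_parquet(file.path(path, "features.parquet"))
  dims <- as.integer(meta$dims)
  rows <- tibble::tibble(
    tensor = lapply(flat$values, function(v) {
      v <- as.numeric(v)
      if (length(v) != prod(dims)) {
        abort(sprintf("stored tensor has %d values, expected %dx%d",
                      length(v), dims[1], dims[2]))
      }
      matrix(v, nrow = dims[1], ncol = dims[2])
    }),
    label = as.integer(flat$label),
    subject_id = as.character(flat$subject_id),
    trial_id = as.character(flat$trial_id),
    experiment = as.integer(flat$experiment),
    window_start = as.integer(flat$window_start)
  )
  ws <- meta$window_spec
  new_emg_tensors(rows, meta$feature_kind, do.call(window_spec, as.list(ws)))
}
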