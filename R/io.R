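#' Read a raw sEMG recording from CSV
#'
#' One row per sample, one numeric column per channel (optionally with a
#' header). The acquisition hardware this package targets writes six channels
#' sampled at 2 kHz.
#'
#' @param path CSV file path.
#' @param fs Sampling frequency in Hz.
#' @param n_channels Expected channel count; a mismatching file is an error.
#' @param header Whether the file carries a header row; `NA` (default)
#'   auto-detects by attempting a numeric parse of the first row.
#' @inheritParams emg_recording
#' @return An [emg_recording()].
#' @export
read_emg_csv <- function(path, fs = 2000, n_channels = 6, header = NA,
                         subject_id = NA_character_, trial_id = NA_character_) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (is.na(header)) {
    first <- utils::read.csv(path, header = FALSE, nrows = 1,
                             colClasses = "character")
    header <- any(is.na(suppressWarnings(as.numeric(unlist(first)))))
  }
  df <- utils::read.csv(path, header = header, colClasses = "character")
  if (ncol(df) != n_channels) {
    abort(sprintf("expected %d channels but %s has %d columns",
                  n_channels, path, ncol(df)))
  }
  num <- as.data.frame(lapply(df, function(x) suppressWarnings(as.numeric(x))))
  bad <- which(!stats::complete.cases(num))
  if (length(bad) > 0) {
    abort(sprintf("non-numeric or missing cells in rows: %s",
                  paste(head(bad, 5), collapse = ", ")))
  }
  emg_recording(num, fs = fs, subject_id = subject_id, trial_id = trial_id)
}

#' Write a recording to CSV
#'
#' Values are written with 12 significant digits so a write/read round trip
#' reproduces the signal to that precision.
#'
#' @param rec An [emg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_emg_csv <- function(rec, path) {
  m <- rec_matrix(rec)
  df <- as.data.frame(signif(m, 12))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

labels_cols <- c("trial_id", "subject_id", "experiment", "gesture_label",
                 "start_sample", "end_sample")

#' Read / write the trial label sidecar
#'
#' The sidecar marks labelled trial segments inside a recording:
#' `trial_id, subject_id, experiment, gesture_label (1..n_classes),
#' start_sample, end_sample`, with 0-based half-open sample ranges
#' `[start_sample, end_sample)`. `experiment` identifies the protocol
#' repetition, used by inter-experiment splits.
#'
#' @param path CSV file path.
#' @return A tibble with one row per labelled trial segment.
#' @export
read_labels_csv <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- tibble::as_tibble(utils::read.csv(path, header = TRUE))
  missing_cols <- setdiff(labels_cols, names(df))
  if (length(missing_cols) > 0) {
    abort(sprintf("label sidecar is missing columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (any(df$end_sample <= df$start_sample)) {
    abort("label ranges must satisfy end_sample > start_sample")
  }
  df[labels_cols]
}

#' @rdname read_labels_csv
#' @param labels A label tibble as documented above.
#' @export
write_labels_csv <- function(labels, path) {
  utils::write.csv(as.data.frame(labels[labels_cols]), path, row.names = FALSE)
  invisible(path)
}

#' Load a run configuration
#'
#' A YAML file with (all optional) sections `seed`, `preprocess`, `windows`,
#' `training`, and `protocol`, whose keys must match the arguments of
#' [filter_settings()], [window_spec()], [train_config()] and
#' [gesture_protocol()] respectively. Unknown sections or keys are rejected so
#' typos never pass silently.
#'
#' @param path YAML file path.
#' @return A named list of class `emg_run_config` with fully-resolved settings.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- list(
    seed = NULL,
    preprocess = names(formals(filter_settings)),
    windows = names(formals(window_spec)),
    training = names(formals(train_config)),
    protocol = names(formals(gesture_protocol))
  )
  bad_sections <- setdiff(names(cfg), names(known))
  if (length(bad_sections) > 0) {
    abort(sprintf("unknown config section(s): %s",
                  paste(bad_sections, collapse = ", ")))
  }
  for (sec in setdiff(names(cfg), "seed")) {
    bad_keys <- setdiff(names(cfg[[sec]]), known[[sec]])
    if (length(bad_keys) > 0) {
      abort(sprintf("unknown key(s) in section '%s': %s",
                    sec, paste(bad_keys, collapse = ", ")))
    }
  }
  resolved <- list(
    seed = cfg$seed %||% 1L,
    preprocess = do.call(filter_settings, cfg$preprocess %||% list()),
    windows = do.call(window_spec, cfg$windows %||% list()),
    training = do.call(train_config, cfg$training %||% list()),
    protocol = do.call(gesture_protocol, cfg$protocol %||% list())
  )
  structure(resolved, class = "emg_run_config")
}
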