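#' Flash-budget size accounting for an architecture
#'
#' Estimates the flash footprint of a model the way embedded deployments of
#' this family budget it against a 2 MB limit: a convolution layer counts
#' `kernel_time * kernel_channel * n_out_maps * n_in_maps` entries, the
#' reshape stage counts the product of its output dimensions, and an LSTM
#' counts its flattened input length times its hidden size. Biases, LSTM gate
#' quadrupling and the dense head are deliberately outside this convention —
#' it is a coarse flash estimate, not a trainable-parameter count (see
#' [true_param_count()] for that). A literal list of training-time variables
#' is added to the total, and kilobytes assume 4 bytes per entry.
#'
#' For the default `CNN2D_LSTM` architecture this yields 30720 (conv1) +
#' 122880 (conv2) + 1448 (reshape to 181x8) + 46336 (LSTM input) + the
#' training variables 128 + 20 + 32 = 201564 entries, i.e. 787.36 kb.
#'
#' @param arch An `emg_architecture` from [build_architecture()].
#' @param training_variables Extra counts produced during training, added to
#'   the total as-is.
#' @return A list of class `emg_size_report` with elements `per_layer`
#'   (tibble: `layer`, `kind`, `flash_size`), `training_variables`,
#'   `flash_total`, `flash_kilobytes`, `true_trainable_params`, and
#'   `serialized_bytes` (`NA` until a trained model exists).
#' @export
#' @examples
#' rep <- flash_size_estimate(build_architecture("CNN2D_LSTM"))
#' glance(rep)
flash_size_estimate <- function(arch, training_variables = c(128, 20, 32)) {
  shapes <- arch_shapes(arch)
  n_in_maps <- arch$input_shape[3]
  sizes <- numeric(length(arch$layers))
  for (i in seq_along(arch$layers)) {
    l <- arch$layers[[i]]
    dims_in <- shapes$dims_in[[i]]
    dims_out <- shapes$dims_out[[i]]
    sizes[i] <- switch(l$kind,
      conv = {
        s <- prod(l$kernel) * l$n_out * n_in_maps
        n_in_maps <- l$n_out
        s
      },
      reshape = prod(dims_out),
      lstm = prod(dims_in) * l$units,
      0
    )
  }
  per_layer <- tibble::tibble(layer = seq_along(sizes),
                              kind = shapes$kind,
                              flash_size = sizes)
  total <- sum(sizes) + sum(training_variables)
  structure(list(
    per_layer = per_layer,
    training_variables = training_variables,
    flash_total = total,
    flash_kilobytes = total * 4 / 1024,
    true_trainable_params = true_param_count(arch),
    serialized_bytes = NA_real_,
    variant = arch$variant
  ), class = "emg_size_report")
}

#' Exact trainable-parameter count
#'
#' Standard counting with biases and LSTM gate quadrupling: conv
#' `(kh*kw*n_in + 1)*n_out`, dense `(in + 1)*out`, LSTM
#' `4*((in + hidden + 1)*hidden)`. This equals, entry for entry, the number
#' of weights the training engine materialises (asserted in the test suite),
#' and is the number to trust for deployment decisions.
#'
#' @param arch An `emg_architecture`.
#' @return Integer parameter count.
#' @export
true_param_count <- function(arch) {
  shapes <- arch_shapes(arch)
  n_in_maps <- arch$input_shape[3]
  total <- 0
  for (i in seq_along(arch$layers)) {
    l <- arch$layers[[i]]
    dims_in <- shapes$dims_in[[i]]
    total <- total + switch(l$kind,
      conv = {
        s <- (prod(l$kernel) * n_in_maps + 1) * l$n_out
        n_in_maps <- l$n_out
        s
      },
      lstm = 4 * ((dims_in[2] + l$units + 1) * l$units),
      dense = (dims_in[1] + 1) * l$n_out,
      0
    )
  }
  as.integer(total)
}

#' @export
print.emg_size_report <- function(x, ...) {
  cat(sprintf("<emg_size_report> %s\n", x$variant))
  print(dplyr::filter(x$per_layer, .data$flash_size > 0))
  cat(sprintf("  training variables: %s\n",
              paste(x$training_variables, collapse = " + ")))
  cat(sprintf("  flash estimate: %d entries = %.2f kb\n",
              x$flash_total, x$flash_kilobytes))
  cat(sprintf("  true trainable parameters: %d\n", x$true_trainable_params))
  if (!is.na(x$serialized_bytes)) {
    cat(sprintf("  serialized artifact: %d bytes\n", x$serialized_bytes))
  }
  invisible(x)
}

#' @export
tidy.emg_size_report <- function(x, ...) x$per_layer

#' @export
glance.emg_size_report <- function(x, ...) {
  tibble::tibble(variant = x$variant,
                 flash_total = x$flash_total,
                 flash_kilobytes = x$flash_kilobytes,
                 true_trainable_params = x$true_trainable_params,
                 serialized_bytes = x$serialized_bytes)
}

#' Size report as JSON
#'
#' @param x An `emg_size_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_size_report <- function(x, path) {
  jsonlite::write_json(list(
    variant = x$variant,
    per_layer = x$per_layer,
    training_variables = x$training_variables,
    flash_total = x$flash_total,
    flash_kilobytes = x$flash_kilobytes,
    true_trainable_params = x$true_trainable_params,
    serialized_bytes = x$serialized_bytes
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
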