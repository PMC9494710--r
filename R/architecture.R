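#' Declare one network layer
#'
#' @param kind One of `"conv"`, `"maxpool"`, `"reshape"`, `"flatten"`,
#'   `"lstm"`, `"dropout"`, `"dense"`, `"leaky_relu"`, `"softmax"`.
#' @param kernel Integer pair (time, channel) kernel size for `conv`.
#' @param n_out Output feature maps (`conv`) or units (`dense`).
#' @param padding `"same"` (along both axes) or `"valid"` for `conv`.
#' @param pool Pool length along time for `maxpool` (1 = identity).
#' @param units Hidden state size for `lstm`.
#' @param return_seq Whether an `lstm` layer emits its full hidden sequence
#'   (needed when another `lstm` follows) or only the final state.
#' @param rate Drop probability for `dropout`.
#' @param alpha Negative-slope coefficient for `leaky_relu`.
#' @return A list of class `layer_spec`.
#' @export
layer_spec <- function(kind, kernel = NULL, n_out = NULL,
                       padding = c("valid", "same"), pool = 1L,
                       units = NULL, return_seq = FALSE,
                       rate = 0.2, alpha = 0.01) {
  kind <- match.arg(kind, c("conv", "maxpool", "reshape", "flatten", "lstm",
                            "dropout", "dense", "leaky_relu", "softmax"))
  padding <- match.arg(padding)
  if (kind == "conv") {
    stopifnot(length(kernel) == 2, all(kernel >= 1), n_out >= 1)
  }
  if (kind == "lstm") stopifnot(units >= 1)
  if (kind == "dense") stopifnot(n_out >= 1)
  if (kind == "dropout") stopifnot(rate >= 0, rate < 1)
  structure(list(kind = kind, kernel = kernel, n_out = n_out,
                 padding = padding, pool = as.integer(pool), units = units,
                 return_seq = return_seq, rate = rate, alpha = alpha),
            class = "layer_spec")
}

#' Build one of the four CNN/LSTM gesture classifiers
#'
#' The default `CNN2D_LSTM` variant is the embedded-deployment model: a
#' same-padded 40x6 convolution with 128 feature maps over the 200x6x1 input,
#' a valid 20x6 convolution down to 8 maps, a reshape of the resulting 181x8
#' map stack into a length-181 feature sequence, a 32-unit LSTM, dropout,
#' and a dense + leaky-ReLU + softmax classifier over 16 gestures. Each conv
#' block is convolution + leaky-ReLU + max pool; the pool defaults to length
#' 1 (identity) and can be widened via `pool`.
#'
#' Variants: `CNN` drops recursion (single valid conv + flatten classifier),
#' `CNN_LSTM` feeds a single conv's map sequence to a 32-unit LSTM,
#' `CNN2D_LSTM2D` stacks a second 16-unit LSTM on the default.
#'
#' @param variant One of `"CNN2D_LSTM"`, `"CNN"`, `"CNN_LSTM"`,
#'   `"CNN2D_LSTM2D"`.
#' @param input_shape Integer triple (window length, channels, 1).
#' @param n_classes Number of gesture classes.
#' @param conv1_maps,conv2_maps Feature-map counts of the conv layers.
#' @param lstm_units,lstm2_units Hidden sizes of the LSTM layers.
#' @param dropout Drop probability of the classifier dropout layer.
#' @param pool Max-pool length after each conv (1 disables pooling).
#' @return A list of class `emg_architecture`.
#' @export
#' @examples
#' arch <- build_architecture("CNN2D_LSTM")
#' arch_shapes(arch)
build_architecture <- function(variant = c("CNN2D_LSTM", "CNN", "CNN_LSTM",
                                           "CNN2D_LSTM2D"),
                               input_shape = c(200L, 6L, 1L),
                               n_classes = 16L,
                               conv1_maps = 128L, conv2_maps = 8L,
                               lstm_units = 32L, lstm2_units = 16L,
                               dropout = 0.2, pool = 1L) {
  variant <- match.arg(variant)
  ch <- input_shape[2]
  # one conv block = convolution + leaky-ReLU + (optional) max pool
  conv_block <- function(kernel, maps, padding) {
    list(layer_spec("conv", kernel = kernel, n_out = maps, padding = padding),
         layer_spec("leaky_relu"),
         layer_spec("maxpool", pool = pool))
  }
  classifier <- list(
    layer_spec("dropout", rate = dropout),
    layer_spec("dense", n_out = n_classes),
    layer_spec("leaky_relu"),
    layer_spec("softmax")
  )
  layers <- switch(variant,
    CNN = c(
      conv_block(c(40L, ch), conv1_maps, "valid"),
      list(layer_spec("flatten")),
      classifier),
    CNN_LSTM = c(
      conv_block(c(40L, ch), conv1_maps, "valid"),
      list(layer_spec("reshape"),
           layer_spec("lstm", units = lstm_units)),
      classifier),
    CNN2D_LSTM = c(
      conv_block(c(40L, ch), conv1_maps, "same"),
      conv_block(c(20L, ch), conv2_maps, "valid"),
      list(layer_spec("reshape"),
           layer_spec("lstm", units = lstm_units)),
      classifier),
    CNN2D_LSTM2D = c(
      conv_block(c(40L, ch), conv1_maps, "same"),
      conv_block(c(20L, ch), conv2_maps, "valid"),
      list(layer_spec("reshape"),
           layer_spec("lstm", units = lstm_units, return_seq = TRUE),
           layer_spec("lstm", units = lstm2_units)),
      classifier)
  )
  arch <- structure(list(variant = variant,
                         input_shape = as.integer(input_shape),
                         n_classes = as.integer(n_classes),
                         layers = layers),
                    class = "emg_architecture")
  arch_shapes(arch)  # validate the chain at build time
  arch
}

conv_pads <- function(kernel, padding) {
  if (padding == "same") {
    tot_t <- kernel[1] - 1L
    tot_c <- kernel[2] - 1L
    c(pt0 = tot_t %/% 2L, pt1 = tot_t - tot_t %/% 2L,
      pc0 = tot_c %/% 2L, pc1 = tot_c - tot_c %/% 2L)
  } else {
    c(pt0 = 0L, pt1 = 0L, pc0 = 0L, pc1 = 0L)
  }
}

#' Trace layer shapes through an architecture
#'
#' Validates that layer shapes chain consistently from the input to a softmax
#' over `n_classes`, returning the per-layer input and output shapes. Conv
#' stages are tracked as (time, channel, maps); sequence stages as
#' (steps, features); dense stages as a flat length.
#'
#' @param arch An `emg_architecture`.
#' @return A tibble with columns `layer`, `kind`, `shape_in`, `shape_out`
#'   (shape columns are printable strings; the integer shapes are attached as
#'   list-columns `dims_in`, `dims_out`).
#' @export
arch_shapes <- function(arch) {
  shape <- list(stage = "cube",
                dims = c(arch$input_shape[1], arch$input_shape[2],
                         arch$input_shape[3]))
  rows <- list()
  for (i in seq_along(arch$layers)) {
    l <- arch$layers[[i]]
    dims_in <- shape$dims
    shape <- switch(l$kind,
      conv = {
        if (shape$stage != "cube") {
          abort(sprintf("layer %d (conv): needs a (time, channel, maps) input", i))
        }
        p <- conv_pads(l$kernel, l$padding)
        to <- dims_in[1] + p["pt0"] + p["pt1"] - l$kernel[1] + 1L
        co <- dims_in[2] + p["pc0"] + p["pc1"] - l$kernel[2] + 1L
        if (to < 1 || co < 1) {
          abort(sprintf("layer %d (conv): kernel %dx%d does not fit input %dx%d",
                        i, l$kernel[1], l$kernel[2], dims_in[1], dims_in[2]))
        }
        list(stage = "cube", dims = as.integer(c(to, co, l$n_out)))
      },
      maxpool = {
        if (shape$stage != "cube") abort(sprintf("layer %d (maxpool): needs conv input", i))
        list(stage = "cube",
             dims = as.integer(c(dims_in[1] %/% l$pool, dims_in[2], dims_in[3])))
      },
      reshape = {
        if (shape$stage != "cube" || dims_in[2] != 1L) {
          abort(sprintf(
            "layer %d (reshape): needs a (time, 1, maps) conv output, got %s",
            i, paste(dims_in, collapse = "x")))
        }
        list(stage = "seq", dims = as.integer(c(dims_in[1], dims_in[3])))
      },
      flatten = {
        if (shape$stage != "cube") abort(sprintf("layer %d (flatten): needs conv input", i))
        list(stage = "flat", dims = as.integer(prod(dims_in)))
      },
      lstm = {
        if (shape$stage != "seq") {
          abort(sprintf("layer %d (lstm): needs a (steps, features) sequence", i))
        }
        if (l$return_seq) list(stage = "seq", dims = as.integer(c(dims_in[1], l$units)))
        else list(stage = "flat", dims = as.integer(l$units))
      },
      dropout = {
        if (shape$stage != "flat") {
          abort(sprintf("layer %d (%s): placed outside the flat classifier head",
                        i, l$kind))
        }
        shape
      },
      leaky_relu = shape,  # elementwise; any stage
      dense = {
        if (shape$stage != "flat") abort(sprintf("layer %d (dense): needs flat input", i))
        list(stage = "flat", dims = as.integer(l$n_out))
      },
      softmax = {
        if (shape$stage != "flat" || dims_in[1] != arch$n_classes) {
          abort(sprintf("layer %d (softmax): expects %d logits, got %s",
                        i, arch$n_classes, paste(dims_in, collapse = "x")))
        }
        shape
      }
    )
    rows[[i]] <- tibble::tibble(
      layer = i, kind = l$kind,
      shape_in = paste(dims_in, collapse = "x"),
      shape_out = paste(shape$dims, collapse = "x"),
      dims_in = list(dims_in), dims_out = list(shape$dims)
    )
  }
  if (arch$layers[[length(arch$layers)]]$kind != "softmax") {
    abort("architecture must end in a softmax layer")
  }
  dplyr::bind_rows(rows)
}

#' @export
print.emg_architecture <- function(x, ...) {
  cat(sprintf("<emg_architecture> %s: input %s, %d classes\n",
              x$variant, paste(x$input_shape, collapse = "x"), x$n_classes))
  print(arch_shapes(x)[c("layer", "kind", "shape_in", "shape_out")], n = 30)
  invisible(x)
}
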