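test_that("the default 2D CNN+LSTM chains to the documented shapes", {
  arch <- build_architecture("CNN2D_LSTM")
  shapes <- arch_shapes(arch)
  reshape_out <- shapes$dims_out[[which(shapes$kind == "reshape")]]
  expect_equal(reshape_out, c(181L, 8L))
  conv1_out <- shapes$dims_out[[1]]
  expect_equal(conv1_out, c(200L, 6L, 128L))  # same padding preserves 200x6
  expect_equal(shapes$dims_out[[nrow(shapes)]], 16L)
})

test_that("variants carry their documented layer structure", {
  cnn <- build_architecture("CNN")
  kinds <- vapply(cnn$layers, function(l) l$kind, character(1))
  expect_equal(sum(kinds == "conv"), 1)       # single conv block
  expect_false("lstm" %in% kinds)

  cl <- build_architecture("CNN_LSTM")
  expect_equal(sum(vapply(cl$layers, function(l) l$kind, character(1)) == "conv"), 1)
  lstm_units <- purrr::map_int(purrr::keep(cl$layers, ~ .x$kind == "lstm"),
                               ~ as.integer(.x$units))
  expect_equal(lstm_units, 32L)

  c2l2 <- build_architecture("CNN2D_LSTM2D")
  lstm_units <- purrr::map_int(purrr::keep(c2l2$layers, ~ .x$kind == "lstm"),
                               ~ as.integer(.x$units))
  expect_equal(lstm_units, c(32L, 16L))
})

test_that("inconsistent overrides fail chain validation with the layer named", {
  expect_error(build_architecture("CNN2D_LSTM", input_shape = c(10L, 6L, 1L)),
               "conv")
})

test_that("flash accounting reproduces the reference arithmetic exactly", {
  rep <- flash_size_estimate(build_architecture("CNN2D_LSTM"))
  conv_sizes <- rep$per_layer$flash_size[rep$per_layer$kind == "conv"]
  expect_equal(conv_sizes, c(40 * 6 * 128 * 1, 20 * 6 * 8 * 128))
  expect_equal(conv_sizes, c(30720, 122880))
  expect_equal(rep$per_layer$flash_size[rep$per_layer$kind == "reshape"], 1448)
  expect_equal(rep$per_layer$flash_size[rep$per_layer$kind == "lstm"], 46336)
  expect_equal(rep$flash_total, 201564)
  expect_equal(rep$flash_kilobytes, 787.36, tolerance = 0.01 / 787.36)
  # internal consistency invariants
  expect_equal(rep$flash_total,
               sum(rep$per_layer$flash_size) + sum(rep$training_variables))
  expect_equal(rep$flash_kilobytes, rep$flash_total * 4 / 1024)
})

test_that("flash conv accounting is linear in the output map count", {
  base <- flash_size_estimate(build_architecture("CNN2D_LSTM"))
  doubled <- flash_size_estimate(build_architecture("CNN2D_LSTM",
                                                    conv1_maps = 256L))
  c1 <- function(r) r$per_layer$flash_size[r$per_layer$kind == "conv"][1]
  expect_equal(c1(doubled), 2 * c1(base))
})

test_that("flash total ignores dropout rate", {
  a <- flash_size_estimate(build_architecture("CNN2D_LSTM", dropout = 0.0))
  b <- flash_size_estimate(build_architecture("CNN2D_LSTM", dropout = 0.7))
  expect_equal(a$flash_total, b$flash_total)
})

test_that("true_param_count follows standard counting rules", {
  # dense(10 -> 16): (10 + 1) * 16
  dense_only <- structure(list(
    variant = "CNN", input_shape = c(10L, 1L, 1L), n_classes = 16L,
    layers = list(emgrec:::layer_spec("flatten"),
                  emgrec:::layer_spec("dense", n_out = 16L),
                  emgrec:::layer_spec("softmax"))),
    class = "emg_architecture")
  expect_equal(true_param_count(dense_only), 176L)

  # conv(2x2, 1 -> 1): 4 weights + 1 bias
  conv_only <- structure(list(
    variant = "CNN", input_shape = c(4L, 2L, 1L), n_classes = 3L,
    layers = list(emgrec:::layer_spec("conv", kernel = c(2L, 2L), n_out = 1L,
                                      padding = "valid"),
                  emgrec:::layer_spec("flatten"),
                  emgrec:::layer_spec("dense", n_out = 3L),
                  emgrec:::layer_spec("softmax"))),
    class = "emg_architecture")
  shapes <- arch_shapes(conv_only)
  conv_params <- true_param_count(conv_only) -
    (prod(shapes$dims_out[[2]]) + 1) * 3
  expect_equal(conv_params, 5)
})

test_that("true_param_count equals the engine's materialised weight count", {
  for (v in c("CNN", "CNN_LSTM", "CNN2D_LSTM", "CNN2D_LSTM2D")) {
    arch <- build_architecture(v)
    withr::with_seed(1, {
      params <- emgrec:::nn_init(arch)
    })
    expect_equal(emgrec:::engine_param_count(params), true_param_count(arch),
                 info = v)
  }
})

test_that("size report tidiers expose totals and per-layer rows", {
  rep <- flash_size_estimate(build_architecture("CNN2D_LSTM"))
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_equal(sum(td$flash_size), 201564 - 180)
  gl <- glance(rep)
  expect_equal(gl$flash_total, 201564)
  expect_equal(gl$true_trainable_params, true_param_count(
    build_architecture("CNN2D_LSTM")))
})
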