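# Network assembly, forward contracts, introspection, checkpointing.

test_that("scaled-down model builds and traces the expected shape algebra", {
  set.seed(10)
  model <- build_model(network_config(base_channels = 8))
  s <- summarize_architecture(model, input_size = 64L)
  expect_equal(s$encoder_count, 4L)
  expect_equal(s$decoder_count, 4L)
  expect_equal(s$aspp_rates, c(6L, 12L, 18L))
  expect_equal(s$output_channels, 3L)
  expect_equal(unname(s$stage_shapes$encoder4), c(64L, 8L, 8L))
  expect_equal(unname(s$stage_shapes$bottleneck), c(128L, 8L, 8L))
  expect_equal(unname(s$stage_shapes$output), c(3L, 64L, 64L))

  x <- array(runif(3 * 64 * 64), c(3, 64, 64))
  lg <- forward_pass(model, x)
  expect_equal(dim(lg), c(3L, 64L, 64L))
  expect_true(all(is.finite(lg)))
})

test_that("forward pass enforces divisibility and channel contracts", {
  set.seed(11)
  model <- build_model(tiny_net_config())
  expect_error(forward_pass(model, array(0, c(3, 100, 102))), "divisible")
  expect_error(forward_pass(model, array(0, c(5, 16, 16))), "channels")
  # 2^depth divisibility is about the configured depth, not a constant
  expect_silent(forward_pass(model, array(0, c(3, 20, 20))))
})

test_that("evaluation-mode forward passes are deterministic", {
  set.seed(12)
  model <- build_model(tiny_net_config())
  x <- array(runif(3 * 16 * 16), c(3, 16, 16))
  expect_identical(forward_pass(model, x), forward_pass(model, x))
})

test_that("predict_mask takes the per-pixel argmax with ties to the lowest class", {
  set.seed(13)
  model <- build_model(tiny_net_config())
  x <- array(runif(3 * 16 * 16), c(3, 16, 16))
  pm <- predict_mask(model, x)
  expect_true(all(pm %in% 0:2))
  lg <- forward_pass(model, x)
  expect_equal(pm[1, 1], which.max(lg[, 1, 1]) - 1L)
  # all-equal logits (zeroed head) tie-break to class 0
  zero_parameters(model$head, bypass_norm = FALSE)
  expect_true(all(predict_mask(model, x) == 0L))
})

test_that("ablation switches change the live module graph", {
  set.seed(14)
  plain <- build_model(tiny_net_config(use_res_cbam = FALSE,
                                       use_modified_aspp = FALSE))
  expect_null(plain$enc[[1]]$at)
  expect_null(plain$bottleneck$branches)
  s <- summarize_architecture(plain, 16L)
  expect_length(s$aspp_rates, 0L)
  # shapes are unchanged by the ablations
  expect_equal(unname(s$stage_shapes$output), c(3L, 16L, 16L))
})

test_that("end-to-end loss gradients match finite differences", {
  set.seed(16)
  model <- build_model(tiny_net_config())
  x <- array(runif(12 * 12 * 3 * 2), c(12, 12, 3, 2))
  mask <- array(sample(0:2, 12 * 12 * 2, TRUE), c(12, 12, 2))
  fw <- leafseg:::net_fwd(model, x, train = TRUE)
  ls <- leafseg:::wc_loss_grad(fw$logits, mask, gamma = 2)
  layers <- leafseg:::collect_layers(model)
  leafseg:::zero_grads(layers)
  leafseg:::net_bwd(model, fw$cache, ls$glogits)
  loss_fn <- function() {
    f <- leafseg:::net_fwd(model, x, train = TRUE)
    leafseg:::wc_loss_grad(f$logits, mask, 2, want_grad = FALSE)$mean
  }
  check_param_gradients(model, loss_fn, n_checks = 1L, tol = 1e-4)
})

test_that("checkpoints round-trip parameters and predictions exactly", {
  set.seed(15)
  model <- build_model(tiny_net_config())
  x <- array(runif(3 * 16 * 16), c(3, 16, 16))
  dir <- file.path(tempdir(), "ckpt-test")
  save_checkpoint(model, dir)
  model2 <- load_checkpoint(dir)
  expect_identical(forward_pass(model, x), forward_pass(model2, x))
  cfgj <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  expect_equal(cfgj$base_channels, 4L)
  # incompatible architecture is rejected
  other <- build_model(tiny_net_config(base_channels = 8L))
  st <- readRDS(file.path(dir, "params.rds"))
  expect_error(
    leafseg:::layers_restore(leafseg:::collect_layers(other), st),
    "incompatible")
  unlink(dir, recursive = TRUE)
})
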