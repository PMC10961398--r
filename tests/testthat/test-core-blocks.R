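# Unit and property tests for the encoder building blocks.

test_that("conv_block maps channels and preserves spatial size", {
  set.seed(1)
  x <- random_chw(3, 20, 24)
  y <- conv_block(x, 3, 8)
  expect_equal(dim(y), c(8L, 20L, 24L))
  expect_error(conv_block(x, 5, 8), "5")
})

test_that("zeroed parameters propagate the zero map through every block", {
  set.seed(2)
  x0 <- array(0, c(4, 12, 12))
  y <- conv_block(x0, 4, 6)
  p <- zero_parameters(attr(y, "params"))
  expect_true(all(conv_block(x0, 4, 6, params = p) == 0))

  y <- residual_block(x0, 4, 6)
  p <- zero_parameters(attr(y, "params"))
  expect_true(all(residual_block(x0, 4, 6, params = p) == 0))

  y <- modified_aspp(x0, 8)
  p <- zero_parameters(attr(y, "params"))
  expect_true(all(modified_aspp(x0, 8, params = p) == 0))

  # a zero input is annihilated by the attention products regardless of
  # the (untouched) attention weights
  expect_true(all(res_cbam(x0, mlp_reduction = 2, spatial_kernel = 3) == 0))
})

test_that("residual block reduces to the identity when F is zeroed and g is identity", {
  set.seed(3)
  cch <- 5L
  x <- random_chw(cch, 10, 10)
  p <- leafseg:::residual_block_params(cch, cch)
  zero_parameters(p$f)
  p$g_bn$bypass <- TRUE
  p$g_conv$w <- diag(cch)      # 1x1 kernel, identity channel map
  p$g_conv$b <- numeric(cch)
  y <- residual_block(x, cch, cch, params = p)
  expect_equal(unclass(y), x, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("channel attention: shape, open-interval range, and the constant-input closed form", {
  set.seed(4)
  x <- random_chw(8, 16, 16)
  w <- channel_attention(x, mlp_reduction = 4)
  expect_equal(dim(w), c(8L, 1L, 1L))
  expect_true(all(w > 0 & w < 1))
  expect_error(channel_attention(random_chw(2, 4, 4), mlp_reduction = 4),
               "mlp_reduction")

  # spatially constant input: max-pool and avg-pool agree, so the output
  # is sigmoid(2 * MLP(v)) with v the per-channel constants
  v <- rnorm(8)
  xc <- array(rep(v, times = 16 * 16), c(8, 16, 16)) # v[c] at every pixel
  w <- channel_attention(xc, mlp_reduction = 4)
  p <- attr(w, "params")
  mlp <- p$mlp2$w %*% pmax(p$mlp1$w %*% v + p$mlp1$b, 0) + p$mlp2$b
  expect_equal(as.vector(w), as.vector(1 / (1 + exp(-2 * mlp))),
               tolerance = 1e-12)
})

test_that("spatial attention: shape, range, zero-conv closed form, odd-kernel contract", {
  set.seed(5)
  x <- random_chw(6, 12, 18)
  w <- spatial_attention(x, spatial_kernel = 5)
  expect_equal(dim(w), c(1L, 12L, 18L))
  expect_true(all(w > 0 & w < 1))
  expect_error(spatial_attention(x, spatial_kernel = 4), "odd")

  p <- attr(w, "params")
  p$sconv$w <- p$sconv$w * 0
  p$sconv$b <- p$sconv$b * 0
  w0 <- spatial_attention(x, spatial_kernel = 5, params = p)
  expect_equal(as.vector(w0), rep(0.5, 12 * 18), tolerance = 1e-15)
})

test_that("res_cbam output keeps the input shape and obeys the fusion identity", {
  set.seed(6)
  x <- random_chw(8, 14, 14)
  y <- res_cbam(x, mlp_reduction = 4, spatial_kernel = 3)
  expect_equal(dim(y), dim(x))
  # with both attention maps forced to 1, O = T + 1*T + 1*1*T = 3T
  y3 <- res_cbam(x, channel_weights = rep(1, 8),
                 spatial_weights = matrix(1, 14, 14))
  expect_equal(unclass(y3), 3 * x, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("modified ASPP: shape contract, rate validation, dilation-preserving padding", {
  set.seed(7)
  x <- random_chw(8, 64, 64)
  y <- modified_aspp(x, 16)
  expect_equal(dim(y), c(16L, 64L, 64L))
  expect_error(modified_aspp(x, 16, rates = c(6, 12)), "3 dilation rates")
  # output-size algebra H + 2p - d(k-1) = H holds for every branch
  p <- attr(y, "params")
  for (b in p$branches) {
    expect_equal(64 + 2 * b$conv$dilation - b$conv$dilation * 2, 64)
  }
  # non-default rates are honored by the live layers
  y2 <- modified_aspp(x, 16, rates = c(2, 4, 8))
  r <- vapply(attr(y2, "params")$branches, function(b) b$conv$dilation, 1L)
  expect_equal(r, c(2L, 4L, 8L))
})

test_that("shape preservation and attention boundedness hold over randomized sizes", {
  set.seed(8)
  for (i in 1:5) {
    h <- sample(seq(16L, 128L, by = 2L), 1)
    w <- sample(seq(16L, 128L, by = 2L), 1)
    cch <- sample(c(2L, 4L, 8L), 1)
    x <- array(rnorm(cch * h * w), c(cch, h, w))
    expect_equal(dim(conv_block(x, cch, 4))[2:3], c(h, w))
    expect_equal(dim(residual_block(x, cch, 4))[2:3], c(h, w))
    expect_equal(dim(res_cbam(x, mlp_reduction = 2, spatial_kernel = 3)),
                 dim(x))
    expect_equal(dim(modified_aspp(x, 4))[2:3], c(h, w))
    ca <- channel_attention(x, mlp_reduction = 2)
    sa <- spatial_attention(x, spatial_kernel = 3)
    expect_true(all(ca > 0 & ca < 1) && all(sa > 0 & sa < 1))
  }
})

test_that("backpropagation through each block matches finite differences", {
  set.seed(9)
  x <- array(rnorm(4 * 8 * 8 * 2), c(8, 8, 4, 2))
  gy_seed <- array(rnorm(8 * 8 * 6 * 2), c(8, 8, 6, 2))

  run_block <- function(pars, fwd, bwd, out_ch = 6L) {
    gy <- if (out_ch == 6L) gy_seed else
      array(rnorm(8 * 8 * out_ch * 2), c(8, 8, out_ch, 2))
    loss_fn <- function() sum(fwd(pars, x, TRUE)$y * gy)
    r <- fwd(pars, x, TRUE)
    leafseg:::zero_grads(leafseg:::collect_layers(pars))
    gx <- bwd(pars, r$cache, gy)
    check_param_gradients(pars, loss_fn, n_checks = 2L)
    expect_true(any(gx != 0)) # gradient flows back to the input
  }

  run_block(leafseg:::conv_block_params(4, 6), leafseg:::cb_fwd,
            leafseg:::cb_bwd)
  run_block(leafseg:::residual_block_params(4, 6), leafseg:::rb_fwd,
            leafseg:::rb_bwd)
  run_block(leafseg:::cbam_params(4, 2, 3), leafseg:::cbam_fwd,
            leafseg:::cbam_bwd, out_ch = 4L)
  run_block(leafseg:::aspp_params(4, 6, c(1, 2, 3), 4), leafseg:::aspp_fwd,
            leafseg:::aspp_bwd)
})
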