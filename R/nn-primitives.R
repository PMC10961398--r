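# Neural-network primitives with hand-derived backpropagation.
#
# All layers hold their parameters, gradients and optimizer state in an
# environment of class "leafseg_layer", so a single object is shared by the
# model graph, the backward pass and the SGD update. Batches are 4-D arrays
# with dims (H, W, C, N); the C++ kernels in src/nnops.cpp work per sample
# on (H, W, C) cubes.
#
# Every *_fwd() returns list(y = output, cache = what backward needs);
# every *_bwd() takes (layer, cache, gy) and returns the input gradient,
# accumulating parameter gradients into the layer environment.

new_layer <- function(.kind, ...) {
  e <- new.env(parent = emptyenv())
  e$kind <- .kind
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- "leafseg_layer"
  e
}

# ---- convolution -----------------------------------------------------------

# He-normal initialization; weight layout (k*k*Cin) x Cout, row index
# ci*k^2 + kj*k + ki (see src/nnops.cpp).
layer_conv <- function(k, in_ch, out_ch, dilation = 1L) {
  fan_in <- k * k * in_ch
  new_layer("conv",
    k = as.integer(k), dilation = as.integer(dilation),
    in_ch = as.integer(in_ch), out_ch = as.integer(out_ch),
    w = matrix(rnorm(fan_in * out_ch, sd = sqrt(2 / fan_in)),
               nrow = fan_in, ncol = out_ch),
    b = numeric(out_ch))
}

conv_fwd <- function(l, x, train = FALSE) {
  d <- dim(x)
  assert_that_(d[3L] == l$in_ch,
    "conv layer expects %d input channels, got %d", l$in_ch, d[3L])
  y <- conv2d_fwd_cpp(x, l$w, l$b, l$k, l$dilation)
  list(y = y, cache = if (train) x else NULL)
}

conv_bwd <- function(l, cache, gy) {
  r <- conv2d_bwd_cpp(cache, l$w, gy, l$k, l$dilation)
  l$g_w <- if (is.null(l$g_w)) r$gw else l$g_w + r$gw
  l$g_b <- if (is.null(l$g_b)) r$gb else l$g_b + r$gb
  r$gx
}

# ---- batch normalization ---------------------------------------------------

layer_bn <- function(ch, eps = 1e-5, momentum = 0.1) {
  new_layer("bn",
    ch = as.integer(ch), eps = eps, momentum = momentum,
    gamma = rep(1, ch), beta = numeric(ch),
    run_mean = numeric(ch), run_var = rep(1, ch),
    bypass = FALSE)
}

bn_fwd <- function(l, x, train = FALSE) {
  if (isTRUE(l$bypass)) return(list(y = x, cache = list(bypass = TRUE)))
  d <- dim(x)
  ch <- d[3L]
  nrm <- d[1L] * d[2L] * d[4L]
  if (train) {
    mu <- chan_sum_cpp(x, ch) / nrm
    va <- chan_dot_cpp(x, x, ch) / nrm - mu * mu
    l$run_mean <- (1 - l$momentum) * l$run_mean + l$momentum * mu
    l$run_var  <- (1 - l$momentum) * l$run_var  + l$momentum * va
  } else {
    mu <- l$run_mean
    va <- l$run_var
  }
  inv <- 1 / sqrt(va + l$eps)
  xhat <- channel_affine_cpp(x, inv, -mu * inv)
  y <- channel_affine_cpp(xhat, l$gamma, l$beta)
  list(y = y,
       cache = list(xhat = if (train) xhat else NULL, inv = inv, d = d,
                    train = train))
}

bn_bwd <- function(l, cache, gy) {
  if (isTRUE(cache$bypass)) return(gy)
  d <- cache$d
  ch <- d[3L]
  nrm <- d[1L] * d[2L] * d[4L]
  if (!cache$train) {
    return(channel_affine_cpp(gy, l$gamma * cache$inv, numeric(ch)))
  }
  xhat <- cache$xhat
  dgamma <- chan_dot_cpp(gy, xhat, ch)
  dbeta <- chan_sum_cpp(gy, ch)
  l$g_gamma <- if (is.null(l$g_gamma)) dgamma else l$g_gamma + dgamma
  l$g_beta  <- if (is.null(l$g_beta))  dbeta  else l$g_beta + dbeta
  dxhat <- channel_affine_cpp(gy, l$gamma, numeric(ch))
  s1 <- chan_sum_cpp(dxhat, ch)
  s2 <- chan_dot_cpp(dxhat, xhat, ch)
  bn_input_grad_cpp(xhat, dxhat, cache$inv, s1 / nrm, s2 / nrm)
}

# ---- dense (used by the channel-attention MLP) -----------------------------

layer_dense <- function(in_n, out_n) {
  new_layer("dense",
    in_n = as.integer(in_n), out_n = as.integer(out_n),
    w = matrix(rnorm(in_n * out_n, sd = sqrt(2 / in_n)), out_n, in_n),
    b = numeric(out_n))
}

# v: (in_n x N) matrix of column vectors
dense_fwd <- function(l, v, train = FALSE) {
  list(y = l$w %*% v + l$b, cache = if (train) v else NULL)
}

dense_bwd <- function(l, cache, gy) {
  gw <- gy %*% t(cache)
  gb <- rowSums(gy)
  l$g_w <- if (is.null(l$g_w)) gw else l$g_w + gw
  l$g_b <- if (is.null(l$g_b)) gb else l$g_b + gb
  t(l$w) %*% gy
}

# ---- parameter-free ops ----------------------------------------------------

# the output doubles as the backward cache: y > 0 iff the input was > 0
relu_fwd <- function(x, train = FALSE) {
  y <- relu_fwd_cpp(x)
  list(y = y, cache = if (train) y else NULL)
}
relu_bwd <- function(cache, gy) relu_bwd_cpp(cache, gy)

sigmoid_fwd <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(y = y, cache = y)
}
sigmoid_bwd <- function(cache, gy) gy * cache * (1 - cache)

maxpool_fwd <- function(x, train = FALSE) {
  r <- maxpool2_fwd_cpp(x)
  list(y = r$y, cache = list(idx = if (train) r$idx, d = dim(x)))
}

maxpool_bwd <- function(cache, gy) {
  maxpool2_bwd_cpp(gy, cache$idx)
}

upsample_fwd <- function(x) {
  list(y = upsample2_fwd_cpp(x), cache = dim(x))
}

upsample_bwd <- function(cache, gy) {
  upsample2_bwd_cpp(gy)
}

# global pooling over space: (H, W, C, N) -> (C x N) matrix
gap_fwd <- function(x) {
  d <- dim(x)
  hw <- d[1L] * d[2L]
  y <- colSums(matrix(x, nrow = hw)) / hw
  list(y = matrix(y, d[3L], d[4L]), cache = d)
}

gap_bwd <- function(cache, gy) {
  d <- cache
  hw <- d[1L] * d[2L]
  g <- array(0, d)
  for (i in seq_len(d[4L]))
    g[, , , i] <- array(rep(gy[, i] / hw, each = hw), d[1:3])
  g
}

gmp_fwd <- function(x) {
  d <- dim(x)
  hw <- d[1L] * d[2L]
  x3 <- array(x, c(hw, d[3L], d[4L]))
  y <- matrix(0, d[3L], d[4L])
  idx <- matrix(0L, d[3L], d[4L])
  for (i in seq_len(d[4L])) {
    xm <- x3[, , i, drop = FALSE]
    dim(xm) <- c(hw, d[3L])
    j <- max.col(t(xm), ties.method = "first")
    idx[, i] <- j
    y[, i] <- xm[cbind(j, seq_len(d[3L]))]
  }
  list(y = y, cache = list(idx = idx, d = d))
}

gmp_bwd <- function(cache, gy) {
  d <- cache$d
  hw <- d[1L] * d[2L]
  g3 <- array(0, c(hw, d[3L], d[4L]))
  for (i in seq_len(d[4L]))
    g3[cbind(cache$idx[, i], seq_len(d[3L]), i)] <- gy[, i]
  array(g3, d)
}

# channel-wise max and mean: (H, W, C, N) -> two (H, W, 1, N) maps
chpool_fwd <- function(x, train = FALSE) {
  d <- dim(x)
  m <- cmat(x) # (HW*N) x C, rows ordered (H, W, N)
  j <- max.col(m, ties.method = "first")
  mx <- m[cbind(seq_len(nrow(m)), j)]
  mn <- rowMeans(m)
  stack <- array(c(mx, mn), c(d[1L], d[2L], d[4L], 2L))
  list(y = aperm(stack, c(1L, 2L, 4L, 3L)),
       cache = list(j = if (train) j, d = d))
}

chpool_bwd <- function(cache, gy) {
  d <- cache$d
  gst <- aperm(gy, c(1L, 2L, 4L, 3L)) # (H, W, N, 2)
  hwn <- d[1L] * d[2L] * d[4L]
  gmx <- array(gst[, , , 1L], c(hwn))
  gmn <- array(gst[, , , 2L], c(hwn))
  gm <- matrix(gmn / d[3L], nrow = hwn, ncol = d[3L])
  gm[cbind(seq_len(hwn), cache$j)] <-
    gm[cbind(seq_len(hwn), cache$j)] + gmx
  uncmat(gm, d)
}

# ---- parameter traversal and SGD ------------------------------------------

collect_layers <- function(x) {
  out <- list()
  walk <- function(o) {
    if (inherits(o, "leafseg_layer")) {
      out[[length(out) + 1L]] <<- o
    } else if (is.list(o)) {
      for (el in o) walk(el)
    }
  }
  walk(x)
  out
}

param_fields <- function(l) {
  switch(l$kind,
    conv = c("w", "b"),
    dense = c("w", "b"),
    bn = c("gamma", "beta"),
    character(0))
}

zero_grads <- function(layers) {
  for (l in layers) for (f in param_fields(l)) assign(paste0("g_", f), NULL, envir = l)
  invisible(NULL)
}

#' @noRd
sgd_step <- function(layers, lr, momentum = 0.9) {
  for (l in layers) {
    for (f in param_fields(l)) {
      g <- get0(paste0("g_", f), envir = l, ifnotfound = NULL)
      if (is.null(g)) next
      vf <- paste0("v_", f)
      v <- get0(vf, envir = l, ifnotfound = NULL)
      if (is.null(v)) v <- g * 0
      v <- momentum * v - lr * g
      assign(vf, v, envir = l)
      assign(f, get(f, envir = l) + v, envir = l)
    }
  }
  invisible(NULL)
}

# serialize / restore parameter state (checkpointing)
layers_state <- function(layers) {
  lapply(layers, function(l) {
    fs <- c(param_fields(l), if (l$kind == "bn") c("run_mean", "run_var"))
    setNames(lapply(fs, function(f) get(f, envir = l)), fs)
  })
}

layers_restore <- function(layers, state) {
  assert_that_(length(layers) == length(state),
    "checkpoint has %d parameter groups but the model has %d",
    length(state), length(layers))
  for (i in seq_along(layers)) {
    for (f in names(state[[i]])) {
      cur <- get0(f, envir = layers[[i]])
      assert_that_(!is.null(cur) && length(cur) == length(state[[i]][[f]]),
        "checkpoint parameter group %d field '%s' is incompatible", i, f)
      assign(f, state[[i]][[f]], envir = layers[[i]])
    }
  }
  invisible(NULL)
}

# test hook: zero every parameter and bypass all normalization layers
set_zero_and_bypass <- function(x) {
  for (l in collect_layers(x)) {
    for (f in param_fields(l)) {
      v <- get(f, envir = l)
      assign(f, v * 0, envir = l)
    }
    if (l$kind == "bn") l$bypass <- TRUE
  }
  invisible(x)
}
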