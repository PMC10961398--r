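# Building blocks of the encoder/decoder: double-convolution block, modified
# residual block, channel + spatial attention (CBAM), residual attention
# fusion, and the modified dilated-convolution pyramid bottleneck.
#
# Public functions take channels-first (C, H, W) arrays so a feature map
# reads like its shape contract; internally everything runs on (H, W, C, N)
# batches through the primitives in nn-primitives.R. Each composite block has
# an internal *_fwd()/*_bwd() pair used by the full network's training loop.

#' Feature map constructor
#'
#' A feature map is a dense real array with channels-first layout
#' `(channels, height, width)`. The constructor validates finiteness and
#' positive extents and is mainly a contract checkpoint for user inputs.
#'
#' @param values numeric array with `dim` of length 3, `(C, H, W)`.
#' @return the validated array, classed `"feature_map"`.
#' @export
feature_map <- function(values) {
  assert_that_(is.array(values) && length(dim(values)) == 3L,
    "a feature map must be a 3-d (channels, height, width) array")
  assert_that_(all(dim(values) > 0L), "feature map extents must be positive")
  assert_that_(all(is.finite(values)), "feature map entries must be finite")
  structure(values, class = c("feature_map", class(values)))
}

#' Block hyperparameter bundle
#'
#' Collects the hyperparameters shared by the encoder blocks: channel
#' extents, the channel-attention MLP reduction, the spatial-attention
#' kernel size, and the dilation rates / branch width of the pyramid
#' bottleneck.
#'
#' @param in_channels,out_channels positive integers.
#' @param mlp_reduction channel-attention bottleneck divisor (default 16,
#'   the usual CBAM setting).
#' @param spatial_kernel odd kernel size of the spatial-attention
#'   convolution (default 7).
#' @param aspp_rates strictly increasing dilation rates of the three
#'   pyramid branches (default 6, 12, 18).
#' @param aspp_branch_channels channels produced by each pyramid branch
#'   (default `in_channels`).
#' @return a list of class `"block_config"`.
#' @export
block_config <- function(in_channels, out_channels,
                         mlp_reduction = 16L, spatial_kernel = 7L,
                         aspp_rates = c(6L, 12L, 18L),
                         aspp_branch_channels = in_channels) {
  assert_that_(is_count(in_channels) && is_count(out_channels),
    "in_channels and out_channels must be positive integers")
  assert_that_(is_count(mlp_reduction), "mlp_reduction must be a positive integer")
  assert_that_(is_count(spatial_kernel) && spatial_kernel %% 2L == 1L,
    "spatial_kernel must be an odd positive integer, got %s",
    format(spatial_kernel))
  assert_that_(all(aspp_rates > 0) && all(diff(aspp_rates) > 0),
    "aspp_rates must be strictly increasing positive integers")
  assert_that_(is_count(aspp_branch_channels),
    "aspp_branch_channels must be a positive integer")
  structure(list(
    in_channels = as.integer(in_channels),
    out_channels = as.integer(out_channels),
    mlp_reduction = as.integer(mlp_reduction),
    spatial_kernel = as.integer(spatial_kernel),
    aspp_rates = as.integer(aspp_rates),
    aspp_branch_channels = as.integer(aspp_branch_channels)),
    class = "block_config")
}

check_channels <- function(x, expected, what) {
  d <- dim(x)
  assert_that_(is.array(x) && length(d) == 3L,
    "%s expects a (channels, height, width) array", what)
  assert_that_(d[1L] == expected,
    "%s: input has %d channels but %d were declared", what, d[1L], expected)
  invisible(d)
}

# ---- double convolution ----------------------------------------------------

#' @noRd
conv_block_params <- function(in_channels, out_channels) {
  list(conv1 = layer_conv(3L, in_channels, out_channels),
       bn1 = layer_bn(out_channels),
       conv2 = layer_conv(3L, out_channels, out_channels),
       bn2 = layer_bn(out_channels))
}

cb_fwd <- function(p, x, train = FALSE) {
  c1 <- conv_fwd(p$conv1, x, train)
  b1 <- bn_fwd(p$bn1, c1$y, train)
  r1 <- relu_fwd(b1$y, train)
  c2 <- conv_fwd(p$conv2, r1$y, train)
  b2 <- bn_fwd(p$bn2, c2$y, train)
  r2 <- relu_fwd(b2$y, train)
  list(y = r2$y, cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                              c2 = c2$cache, b2 = b2$cache, r2 = r2$cache))
}

cb_bwd <- function(p, cache, gy) {
  g <- relu_bwd(cache$r2, gy)
  g <- bn_bwd(p$bn2, cache$b2, g)
  g <- conv_bwd(p$conv2, cache$c2, g)
  g <- relu_bwd(cache$r1, g)
  g <- bn_bwd(p$bn1, cache$b1, g)
  conv_bwd(p$conv1, cache$c1, g)
}

#' Double 3x3 convolution block
#'
#' Two same-padded 3x3 convolutions, each followed by batch normalization
#' and ReLU. The spatial size is preserved; only the channel count changes.
#'
#' @param x a `(C, H, W)` feature-map array.
#' @param in_channels,out_channels declared channel extents; `x` must carry
#'   `in_channels` channels.
#' @param params parameters from an earlier call (list with `$params`),
#'   or `NULL` to initialize fresh He-normal weights using the current RNG.
#' @param train logical; `TRUE` uses batch statistics in the normalization
#'   layers (single-sample batch), `FALSE` uses running statistics.
#' @return a `(out_channels, H, W)` array with attribute `"params"` carrying
#'   the layer parameters for reuse.
#' @export
conv_block <- function(x, in_channels, out_channels, params = NULL,
                       train = FALSE) {
  check_channels(x, in_channels, "conv_block")
  if (is.null(params)) params <- conv_block_params(in_channels, out_channels)
  r <- cb_fwd(params, chw_to_batch(x), train)
  structure(batch_to_chw(r$y), params = params)
}

# ---- modified residual block ----------------------------------------------

#' @noRd
residual_block_params <- function(in_channels, out_channels) {
  list(f = conv_block_params(in_channels, out_channels),
       g_conv = layer_conv(1L, in_channels, out_channels),
       g_bn = layer_bn(out_channels))
}

rb_fwd <- function(p, x, train = FALSE) {
  f <- cb_fwd(p$f, x, train)
  gc <- conv_fwd(p$g_conv, x, train)
  gb <- bn_fwd(p$g_bn, gc$y, train)
  list(y = f$y + gb$y,
       cache = list(f = f$cache, gc = gc$cache, gb = gb$cache))
}

rb_bwd <- function(p, cache, gy) {
  gxf <- cb_bwd(p$f, cache$f, gy)
  g <- bn_bwd(p$g_bn, cache$gb, gy)
  gxg <- conv_bwd(p$g_conv, cache$gc, g)
  gxf + gxg
}

#' Modified residual block
#'
#' Sum of a two-convolution main path `F(x)` (3x3 conv + BN + ReLU, twice)
#' and a projection shortcut `g(x)` (1x1 convolution + BN) that tunes the
#' channel count so both paths agree. No activation follows the sum.
#'
#' @inheritParams conv_block
#' @return a `(out_channels, H, W)` array with attribute `"params"`.
#' @export
residual_block <- function(x, in_channels, out_channels, params = NULL,
                           train = FALSE) {
  check_channels(x, in_channels, "residual_block")
  if (is.null(params)) params <- residual_block_params(in_channels, out_channels)
  r <- rb_fwd(params, chw_to_batch(x), train)
  structure(batch_to_chw(r$y), params = params)
}

# ---- channel attention -----------------------------------------------------

#' @noRd
cbam_params <- function(channels, mlp_reduction = 16L, spatial_kernel = 7L) {
  hidden <- max(1L, channels %/% mlp_reduction)
  list(mlp1 = layer_dense(channels, hidden),
       mlp2 = layer_dense(hidden, channels),
       sconv = layer_conv(as.integer(spatial_kernel), 2L, 1L))
}

ca_fwd <- function(p, x, train = FALSE) {
  a <- gap_fwd(x)
  m <- gmp_fwd(x)
  ha <- dense_fwd(p$mlp1, a$y, train); ra <- relu_fwd(ha$y, train)
  oa <- dense_fwd(p$mlp2, ra$y, train)
  hm <- dense_fwd(p$mlp1, m$y, train); rm <- relu_fwd(hm$y, train)
  om <- dense_fwd(p$mlp2, rm$y, train)
  s <- sigmoid_fwd(oa$y + om$y)
  list(w = s$y,   # (C x N), entries strictly in (0, 1)
       cache = list(a = a$cache, m = m$cache, ha = ha$cache, ra = ra$cache,
                    oa = oa$cache, hm = hm$cache, rm = rm$cache,
                    om = om$cache, s = s$cache))
}

ca_bwd <- function(p, cache, gw) {
  gs <- sigmoid_bwd(cache$s, gw)
  g <- dense_bwd(p$mlp2, cache$oa, gs)
  g <- relu_bwd(cache$ra, g)
  ga <- dense_bwd(p$mlp1, cache$ha, g)
  g <- dense_bwd(p$mlp2, cache$om, gs)
  g <- relu_bwd(cache$rm, g)
  gm <- dense_bwd(p$mlp1, cache$hm, g)
  gap_bwd(cache$a, ga) + gmp_bwd(cache$m, gm)
}

#' Channel attention weights
#'
#' Global max pooling and global average pooling each reduce the map to a
#' per-channel descriptor; both pass through one shared two-layer
#' perceptron (`C -> C/mlp_reduction -> C`, ReLU between), the two outputs
#' are summed and squashed by a sigmoid. Every weight is strictly in (0,1).
#'
#' @param x a `(C, H, W)` feature-map array with `C >= mlp_reduction`.
#' @param mlp_reduction bottleneck divisor of the shared perceptron.
#' @param params reusable parameters, or `NULL` for fresh initialization.
#' @return a `(C, 1, 1)` array of weights with attribute `"params"`.
#' @export
channel_attention <- function(x, mlp_reduction = 16L, params = NULL) {
  d <- dim(x)
  assert_that_(is.array(x) && length(d) == 3L,
    "channel_attention expects a (channels, height, width) array")
  assert_that_(d[1L] >= mlp_reduction,
    "channel_attention: channels (%d) must be >= mlp_reduction (%d)",
    d[1L], as.integer(mlp_reduction))
  if (is.null(params)) params <- cbam_params(d[1L], mlp_reduction)
  r <- ca_fwd(params, chw_to_batch(x))
  structure(array(r$w, c(d[1L], 1L, 1L)), params = params)
}

# ---- spatial attention -----------------------------------------------------

sa_fwd <- function(p, x, train = FALSE) {
  cp <- chpool_fwd(x, train)
  cv <- conv_fwd(p$sconv, cp$y, train)
  s <- sigmoid_fwd(cv$y)
  list(w = s$y,   # (H, W, 1, N)
       cache = list(cp = cp$cache, cv = cv$cache, s = s$cache))
}

sa_bwd <- function(p, cache, gw) {
  g <- sigmoid_bwd(cache$s, gw)
  g <- conv_bwd(p$sconv, cache$cv, g)
  chpool_bwd(cache$cp, g)
}

#' Spatial attention weights
#'
#' Channel-wise max and mean produce two single-channel maps; their
#' concatenation is convolved with one odd-sized same-padded kernel and
#' squashed by a sigmoid into a per-pixel weight map.
#'
#' @param x a `(C, H, W)` feature-map array.
#' @param spatial_kernel odd convolution kernel size (default 7).
#' @param params reusable parameters, or `NULL` for fresh initialization.
#' @return a `(1, H, W)` array of weights with attribute `"params"`.
#' @export
spatial_attention <- function(x, spatial_kernel = 7L, params = NULL) {
  d <- dim(x)
  assert_that_(is.array(x) && length(d) == 3L,
    "spatial_attention expects a (channels, height, width) array")
  assert_that_(spatial_kernel %% 2L == 1L,
    "spatial_attention: kernel size must be odd, got %d",
    as.integer(spatial_kernel))
  if (is.null(params)) params <- cbam_params(d[1L], spatial_kernel = spatial_kernel)
  r <- sa_fwd(params, chw_to_batch(x))
  structure(array(aperm(batch_sample(r$w, 1L), c(3L, 1L, 2L)),
                  c(1L, d[2L], d[3L])),
            params = params)
}

# ---- residual CBAM fusion --------------------------------------------------

# broadcast a (C x N) channel-weight matrix over space
bcast_channel <- function(w, d) {
  array(rep(as.vector(w), each = d[1L] * d[2L]), d)
}

# broadcast an (H, W, 1, N) spatial-weight map over channels
bcast_spatial <- function(s, d) {
  sf <- array(s, c(d[1L], d[2L], 1L, d[4L]))[, , rep.int(1L, d[3L]), ,
                                             drop = FALSE]
  dim(sf) <- d
  sf
}

cbam_fwd <- function(p, x, train = FALSE,
                     force_pc = NULL, force_ps = NULL) {
  d <- dim(x)
  hw <- d[1L] * d[2L]
  if (is.null(force_pc)) {
    ca <- ca_fwd(p, x, train)
    wc <- ca$w
  } else {
    ca <- NULL
    wc <- matrix(force_pc, d[3L], d[4L])
  }
  bf <- bcast_channel(wc, d)
  t1 <- x * bf
  if (is.null(force_ps)) {
    sa <- sa_fwd(p, t1, train)
    s <- sa$w
  } else {
    sa <- NULL
    s <- array(force_ps, c(d[1L], d[2L], 1L, d[4L]))
  }
  sf <- bcast_spatial(s, d)
  t2 <- t1 * sf
  list(y = x + t1 + t2,
       cache = if (train) list(
         x = x, wc = wc, bf = bf, t1 = t1, s = s, sf = sf,
         ca = if (!is.null(ca)) ca$cache, sa = if (!is.null(sa)) sa$cache,
         d = d, hw = hw))
}

cbam_bwd <- function(p, cache, gy) {
  d <- cache$d
  gx <- gy          # direct residual term
  gt1 <- gy         # T' residual term
  gt2 <- gy         # T'' term
  # T'' = Ps (x) T'
  gsm <- cmat(gt2 * cache$t1)
  gs <- array(rowSums(gsm), c(d[1L], d[2L], 1L, d[4L]))
  gt1 <- gt1 + gt2 * cache$sf
  if (!is.null(cache$sa)) gt1 <- gt1 + sa_bwd(p, cache$sa, gs)
  # T' = Pc (x) T
  gwc <- matrix(colSums(matrix(gt1 * cache$x, nrow = cache$hw)),
                d[3L], d[4L])
  gx <- gx + gt1 * cache$bf
  if (!is.null(cache$ca)) gx <- gx + ca_bwd(p, cache$ca, gwc)
  gx
}

#' Residual convolutional block attention
#'
#' Sequential channel-then-spatial attention with a residual fusion:
#' `T' = Pc(T) (x) T` (channel weights broadcast over space),
#' `T'' = Ps(T') (x) T'` (spatial weights broadcast over channels), and the
#' output `O = T + T' + T''`. Output shape equals input shape.
#'
#' @param x a `(C, H, W)` feature-map array.
#' @param mlp_reduction,spatial_kernel attention hyperparameters.
#' @param params reusable parameters, or `NULL` for fresh initialization.
#' @param channel_weights,spatial_weights optional fixed attention maps
#'   (length-`C` vector / `H x W` matrix) that bypass the corresponding
#'   sub-module; used to exercise the fusion identity in isolation.
#' @param train logical, batch vs running normalization statistics.
#' @return a `(C, H, W)` array with attribute `"params"`.
#' @export
res_cbam <- function(x, mlp_reduction = 16L, spatial_kernel = 7L,
                     params = NULL, channel_weights = NULL,
                     spatial_weights = NULL, train = FALSE) {
  d <- dim(x)
  assert_that_(is.array(x) && length(d) == 3L,
    "res_cbam expects a (channels, height, width) array")
  if (is.null(params)) {
    params <- cbam_params(d[1L], mlp_reduction, spatial_kernel)
  }
  sw <- spatial_weights
  if (!is.null(sw) && length(dim(sw)) == 3L) {
    sw <- array(aperm(sw, c(2L, 3L, 1L)), dim(sw)[c(2L, 3L)])
  }
  r <- cbam_fwd(params, chw_to_batch(x), train,
                force_pc = channel_weights, force_ps = sw)
  structure(batch_to_chw(r$y), params = params)
}

# ---- modified dilated-convolution pyramid ---------------------------------

#' @noRd
aspp_params <- function(in_channels, out_channels,
                        rates = c(6L, 12L, 18L),
                        branch_channels = in_channels) {
  br <- lapply(rates, function(r) {
    list(conv = layer_conv(3L, in_channels, branch_channels,
                           dilation = as.integer(r)),
         bn = layer_bn(branch_channels))
  })
  list(branches = br,
       proj = layer_conv(1L, length(rates) * branch_channels, out_channels),
       proj_bn = layer_bn(out_channels),
       rates = as.integer(rates),
       branch_channels = as.integer(branch_channels))
}

aspp_fwd <- function(p, x, train = FALSE) {
  d <- dim(x)
  nb <- length(p$branches)
  bc <- p$branch_channels
  cat_y <- array(0, c(d[1L], d[2L], nb * bc, d[4L]))
  caches <- vector("list", nb)
  for (i in seq_len(nb)) {
    cv <- conv_fwd(p$branches[[i]]$conv, x, train)
    bn <- bn_fwd(p$branches[[i]]$bn, cv$y, train)
    rl <- relu_fwd(bn$y, train)
    cat_y[, , (i - 1L) * bc + seq_len(bc), ] <- rl$y
    caches[[i]] <- list(cv = cv$cache, bn = bn$cache, rl = rl$cache)
  }
  pj <- conv_fwd(p$proj, cat_y, train)
  pb <- bn_fwd(p$proj_bn, pj$y, train)
  pr <- relu_fwd(pb$y, train)
  list(y = pr$y,
       cache = list(branches = caches, pj = pj$cache, pb = pb$cache,
                    pr = pr$cache, d = d, nb = nb, bc = bc))
}

aspp_bwd <- function(p, cache, gy) {
  g <- relu_bwd(cache$pr, gy)
  g <- bn_bwd(p$proj_bn, cache$pb, g)
  gcat <- conv_bwd(p$proj, cache$pj, g)
  bc <- cache$bc
  gx <- array(0, cache$d)
  for (i in seq_len(cache$nb)) {
    gb <- gcat[, , (i - 1L) * bc + seq_len(bc), , drop = FALSE]
    g <- relu_bwd(cache$branches[[i]]$rl, gb)
    g <- bn_bwd(p$branches[[i]]$bn, cache$branches[[i]]$bn, g)
    gx <- gx + conv_bwd(p$branches[[i]]$conv, cache$branches[[i]]$cv, g)
  }
  gx
}

#' Modified dilated-convolution pyramid
#'
#' Three parallel same-padded 3x3 convolutions with distinct dilation rates
#' (padding equals the rate, so spatial size is preserved), each followed by
#' batch normalization and ReLU; the branch outputs are concatenated along
#' the channel axis and a final 1x1 convolution (+BN+ReLU) sets the output
#' channel count.
#'
#' @param x a `(C, H, W)` feature-map array.
#' @param out_channels channels of the projected output.
#' @param rates exactly three strictly increasing dilation rates
#'   (default 6, 12, 18).
#' @param branch_channels channels produced by each branch (default: the
#'   input channel count).
#' @param params reusable parameters, or `NULL` for fresh initialization.
#' @param train logical, batch vs running normalization statistics.
#' @return a `(out_channels, H, W)` array with attribute `"params"`.
#' @export
modified_aspp <- function(x, out_channels, rates = c(6L, 12L, 18L),
                          branch_channels = NULL, params = NULL,
                          train = FALSE) {
  d <- dim(x)
  assert_that_(is.array(x) && length(d) == 3L,
    "modified_aspp expects a (channels, height, width) array")
  assert_that_(length(rates) == 3L,
    "modified_aspp requires exactly 3 dilation rates, got %d", length(rates))
  assert_that_(d[2L] >= 1L && d[3L] >= 1L,
    "modified_aspp: input must be at least 1x1 spatially")
  if (is.null(branch_channels)) branch_channels <- d[1L]
  if (is.null(params)) {
    params <- aspp_params(d[1L], out_channels, rates, branch_channels)
  }
  r <- aspp_fwd(params, chw_to_batch(x), train)
  structure(batch_to_chw(r$y), params = params)
}

#' Zero all parameters of a block or model (test/diagnostic hook)
#'
#' Sets every weight, bias and affine normalization parameter to zero and,
#' optionally, switches normalization layers to pass-through, so that
#' zero-propagation contracts of the blocks can be exercised.
#'
#' @param x a params object returned by a block, or a model.
#' @param bypass_norm also make normalization layers the identity.
#' @return `x`, modified in place (parameters live in environments).
#' @export
zero_parameters <- function(x, bypass_norm = TRUE) {
  for (l in collect_layers(x)) {
    for (f in param_fields(l)) assign(f, get(f, envir = l) * 0, envir = l)
    if (bypass_norm && l$kind == "bn") l$bypass <- TRUE
  }
  invisible(x)
}
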