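# Full encoder-decoder assembly: 4 encoder stages (double conv + modified
# residual block + residual attention), a dilated-pyramid bottleneck, 4
# decoder stages (bilinear up-convolution + skip concatenation + double conv
# + residual block) and a 1x1 classification head.
#
# Channel plan with the default base width 64 and a 512x512 input:
#   encoders 64/128/256/512, bottleneck 512 -> 1024 (then pooled to 32x32),
#   decoders 512/256/128/64, head 64 -> num_classes.

#' Network configuration
#'
#' Fully determines the architecture: input channels, base width, class
#' count, depth, pyramid dilation rates and attention hyperparameters, plus
#' the two ablation switches for the attention and pyramid modules.
#'
#' @param in_channels image channels (default 3, RGB).
#' @param base_channels width of the first encoder stage (default 64);
#'   stage `i` uses `base_channels * 2^(i-1)` channels.
#' @param num_classes output classes (default 3: background, leaf, disease).
#' @param depth number of encoder/decoder stages (default 4). The input
#'   spatial size must be divisible by `2^depth` at forward time.
#' @param aspp_rates three strictly increasing dilation rates of the
#'   bottleneck pyramid (default 6, 12, 18).
#' @param mlp_reduction channel-attention bottleneck divisor (default 16;
#'   clamped per stage so the hidden width is at least 1).
#' @param spatial_kernel odd spatial-attention kernel size (default 7).
#' @param use_res_cbam include the residual attention module in each
#'   encoder stage (ablation switch).
#' @param use_modified_aspp use the dilated pyramid at the bottleneck; when
#'   `FALSE` a plain double-convolution block doubles the channels instead.
#' @param upsample `"bilinear"` (resize then 3x3 convolution halving
#'   channels) or `"transposed"`-style nearest equivalent is not offered;
#'   bilinear avoids checkerboard artifacts.
#' @return a list of class `"network_config"`.
#' @export
network_config <- function(in_channels = 3L, base_channels = 64L,
                           num_classes = 3L, depth = 4L,
                           aspp_rates = c(6L, 12L, 18L),
                           mlp_reduction = 16L, spatial_kernel = 7L,
                           use_res_cbam = TRUE, use_modified_aspp = TRUE,
                           upsample = "bilinear") {
  assert_that_(is_count(in_channels) && is_count(base_channels) &&
    is_count(num_classes) && is_count(depth),
    "in_channels, base_channels, num_classes and depth must be positive integers")
  assert_that_(depth >= 1, "depth must be at least 1")
  assert_that_(length(aspp_rates) == 3L && all(diff(aspp_rates) > 0),
    "aspp_rates must be 3 strictly increasing integers")
  assert_that_(spatial_kernel %% 2L == 1L, "spatial_kernel must be odd")
  assert_that_(identical(upsample, "bilinear"),
    "only bilinear upsampling is implemented")
  structure(list(
    in_channels = as.integer(in_channels),
    base_channels = as.integer(base_channels),
    num_classes = as.integer(num_classes),
    depth = as.integer(depth),
    aspp_rates = as.integer(aspp_rates),
    mlp_reduction = as.integer(mlp_reduction),
    spatial_kernel = as.integer(spatial_kernel),
    use_res_cbam = isTRUE(use_res_cbam),
    use_modified_aspp = isTRUE(use_modified_aspp),
    upsample = upsample), class = "network_config")
}

#' Build the segmentation model
#'
#' Assembles encoder stages (2x2 max-pool for stages after the first, then
#' double convolution, modified residual block and, unless ablated,
#' residual attention), the bottleneck (dilated pyramid doubling the
#' channels, then 2x2 max-pool), mirrored decoder stages (bilinear
#' up-convolution halving channels, concatenation with the matching encoder
#' output, double convolution, residual block) and a 1x1 output head.
#' Parameter initialization uses the current RNG state; seed it for
#' reproducible models.
#'
#' @param cfg a [network_config()].
#' @return an object of class `"ra_unet"`.
#' @export
build_model <- function(cfg = network_config()) {
  assert_that_(inherits(cfg, "network_config"),
    "cfg must be a network_config object")
  widths <- cfg$base_channels * 2L^(seq_len(cfg$depth) - 1L)
  enc <- vector("list", cfg$depth)
  in_ch <- cfg$in_channels
  for (i in seq_len(cfg$depth)) {
    w <- widths[i]
    enc[[i]] <- list(
      cb = conv_block_params(in_ch, w),
      rb = residual_block_params(w, w),
      at = if (cfg$use_res_cbam)
        cbam_params(w, min(cfg$mlp_reduction, w), cfg$spatial_kernel))
    in_ch <- w
  }
  wb <- 2L * widths[cfg$depth]
  bottleneck <- if (cfg$use_modified_aspp) {
    aspp_params(widths[cfg$depth], wb, cfg$aspp_rates,
                branch_channels = widths[cfg$depth])
  } else {
    conv_block_params(widths[cfg$depth], wb)
  }
  dec <- vector("list", cfg$depth)
  ch <- wb
  for (j in seq_len(cfg$depth)) {
    half <- ch %/% 2L
    dec[[j]] <- list(
      up_conv = layer_conv(3L, ch, half),
      up_bn = layer_bn(half),
      cb = conv_block_params(ch, half),
      rb = residual_block_params(half, half))
    ch <- half
  }
  head <- layer_conv(1L, cfg$base_channels, cfg$num_classes)
  structure(list(cfg = cfg, enc = enc, bottleneck = bottleneck,
                 dec = dec, head = head),
            class = "ra_unet")
}

# internal forward over an (H, W, C, N) batch; returns logits, per-stage
# shape records and (in train mode) all caches needed for net_bwd()
net_fwd <- function(model, x, train = FALSE) {
  cfg <- model$cfg
  d <- dim(x)
  div <- 2L^cfg$depth
  assert_that_(d[1L] %% div == 0L && d[2L] %% div == 0L,
    "input spatial size %dx%d must be divisible by %d", d[1L], d[2L], div)
  assert_that_(d[3L] == cfg$in_channels,
    "input has %d channels, the model expects %d", d[3L], cfg$in_channels)

  shapes <- list()
  rec <- function(name, y) {
    dd <- dim(y)
    shapes[[name]] <<- c(channels = dd[3L], height = dd[1L], width = dd[2L])
  }

  skips <- vector("list", cfg$depth)
  caches <- list(enc = vector("list", cfg$depth),
                 dec = vector("list", cfg$depth))
  h <- x
  for (i in seq_len(cfg$depth)) {
    st <- model$enc[[i]]
    cc <- list()
    if (i > 1L) {
      mp <- maxpool_fwd(h, train); h <- mp$y; cc$mp <- mp$cache
    }
    cb <- cb_fwd(st$cb, h, train); h <- cb$y; cc$cb <- cb$cache
    rb <- rb_fwd(st$rb, h, train); h <- rb$y; cc$rb <- rb$cache
    if (!is.null(st$at)) {
      at <- cbam_fwd(st$at, h, train); h <- at$y; cc$at <- at$cache
    }
    skips[[i]] <- h
    caches$enc[[i]] <- cc
    rec(paste0("encoder", i), h)
  }

  if (cfg$use_modified_aspp) {
    bt <- aspp_fwd(model$bottleneck, h, train)
  } else {
    bt <- cb_fwd(model$bottleneck, h, train)
  }
  h <- bt$y
  caches$bt <- bt$cache
  rec("bottleneck", h)
  bp <- maxpool_fwd(h, train); h <- bp$y; caches$bp <- bp$cache
  rec("bottleneck_pooled", h)

  for (j in seq_len(cfg$depth)) {
    st <- model$dec[[j]]
    cc <- list()
    up <- upsample_fwd(h); cc$up <- up$cache
    uc <- conv_fwd(st$up_conv, up$y, train); cc$uc <- uc$cache
    ub <- bn_fwd(st$up_bn, uc$y, train); cc$ub <- ub$cache
    ur <- relu_fwd(ub$y, train); cc$ur <- ur$cache
    skip <- skips[[cfg$depth - j + 1L]]
    dd <- dim(ur$y)
    half <- dd[3L]
    cat_y <- array(0, c(dd[1L], dd[2L], 2L * half, dd[4L]))
    cat_y[, , seq_len(half), ] <- ur$y
    cat_y[, , half + seq_len(half), ] <- skip
    cc$half <- half
    cb <- cb_fwd(st$cb, cat_y, train); cc$cb <- cb$cache
    rb <- rb_fwd(st$rb, cb$y, train); cc$rb <- rb$cache
    h <- rb$y
    caches$dec[[j]] <- cc
    rec(paste0("decoder", j), h)
  }

  hd <- conv_fwd(model$head, h, train)
  caches$head <- hd$cache
  rec("output", hd$y)
  list(logits = hd$y, shapes = shapes, cache = if (train) caches)
}

# backward pass; returns nothing useful, accumulates parameter gradients
net_bwd <- function(model, cache, glogits) {
  cfg <- model$cfg
  g <- conv_bwd(model$head, cache$head, glogits)
  gskips <- vector("list", cfg$depth)
  for (j in rev(seq_len(cfg$depth))) {
    st <- model$dec[[j]]
    cc <- cache$dec[[j]]
    g <- rb_bwd(st$rb, cc$rb, g)
    gcat <- cb_bwd(st$cb, cc$cb, g)
    half <- cc$half
    gup <- gcat[, , seq_len(half), , drop = FALSE]
    gskips[[cfg$depth - j + 1L]] <- gcat[, , half + seq_len(half), ,
                                         drop = FALSE]
    g <- relu_bwd(cc$ur, gup)
    g <- bn_bwd(st$up_bn, cc$ub, g)
    g <- conv_bwd(st$up_conv, cc$uc, g)
    g <- upsample_bwd(cc$up, g)
  }
  g <- maxpool_bwd(cache$bp, g)
  if (cfg$use_modified_aspp) {
    g <- aspp_bwd(model$bottleneck, cache$bt, g)
  } else {
    g <- cb_bwd(model$bottleneck, cache$bt, g)
  }
  for (i in rev(seq_len(cfg$depth))) {
    st <- model$enc[[i]]
    cc <- cache$enc[[i]]
    g <- g + gskips[[i]]
    if (!is.null(st$at)) g <- cbam_bwd(st$at, cc$at, g)
    g <- rb_bwd(st$rb, cc$rb, g)
    g <- cb_bwd(st$cb, cc$cb, g)
    if (i > 1L) g <- maxpool_bwd(cc$mp, g)
  }
  invisible(g)
}

# accept public (C, H, W) or (N, C, H, W) arrays, return internal batch
as_internal_batch <- function(x) {
  d <- dim(x)
  assert_that_(is.array(x) && length(d) %in% c(3L, 4L),
    "input must be a (C, H, W) array or an (N, C, H, W) batch")
  if (length(d) == 3L) {
    list(x = chw_to_batch(x), batched = FALSE)
  } else {
    list(x = aperm(x, c(3L, 4L, 2L, 1L)), batched = TRUE)
  }
}

internal_to_public <- function(y, batched) {
  if (batched) aperm(y, c(4L, 3L, 1L, 2L)) else batch_to_chw(y)
}

#' Forward pass
#'
#' Runs the model in evaluation mode (running normalization statistics) and
#' returns per-class logits at the input resolution.
#'
#' @param model an `"ra_unet"` from [build_model()].
#' @param x a `(C, H, W)` array or an `(N, C, H, W)` batch; spatial size
#'   must be divisible by `2^depth`.
#' @return logits with `num_classes` channels, same layout as the input.
#' @export
forward_pass <- function(model, x) {
  b <- as_internal_batch(x)
  r <- net_fwd(model, b$x, train = FALSE)
  internal_to_public(r$logits, b$batched)
}

#' @export
predict.ra_unet <- function(object, x, type = c("logits", "mask"), ...) {
  type <- match.arg(type)
  if (type == "logits") forward_pass(object, x) else predict_mask(object, x)
}

#' Predict a label mask
#'
#' Per-pixel argmax over the class logits; ties break toward the lowest
#' class index. Labels are integers in `0 .. num_classes - 1`.
#'
#' @inheritParams forward_pass
#' @return an `H x W` integer matrix (or `(N, H, W)` array for a batch).
#' @export
predict_mask <- function(model, x) {
  b <- as_internal_batch(x)
  r <- net_fwd(model, b$x, train = FALSE)
  lg <- r$logits
  d <- dim(lg)
  n <- d[4L]
  masks <- array(0L, c(n, d[1L], d[2L]))
  for (i in seq_len(n)) {
    m <- matrix(batch_sample(lg, i), nrow = d[1L] * d[2L])
    lab <- max.col(m, ties.method = "first") - 1L
    masks[i, , ] <- matrix(lab, d[1L], d[2L])
  }
  if (b$batched) masks else matrix(masks[1L, , ], d[1L], d[2L])
}

#' Architecture summary
#'
#' Introspects the live module graph: stage counts, the dilation rates read
#' off the bottleneck's convolution layers (not the config), the output
#' channel count of the head, and the per-stage output shapes measured by a
#' real forward pass on a zero image of the given size.
#'
#' @param model an `"ra_unet"`.
#' @param input_size spatial size of the probe input (default 64; must be
#'   divisible by `2^depth`).
#' @return a list of class `"architecture_summary"` with fields
#'   `encoder_count`, `decoder_count`, `aspp_rates`, `output_channels` and
#'   `stage_shapes`.
#' @export
summarize_architecture <- function(model, input_size = 64L) {
  assert_that_(inherits(model, "ra_unet"), "model must be an ra_unet")
  rates <- if (model$cfg$use_modified_aspp) {
    vapply(model$bottleneck$branches, function(b) b$conv$dilation, integer(1))
  } else {
    integer(0)
  }
  probe <- array(0, c(input_size, input_size, model$cfg$in_channels, 1L))
  r <- net_fwd(model, probe, train = FALSE)
  structure(list(
    encoder_count = length(model$enc),
    decoder_count = length(model$dec),
    aspp_rates = rates,
    output_channels = model$head$out_ch,
    stage_shapes = r$shapes), class = "architecture_summary")
}

#' @export
print.architecture_summary <- function(x, ...) {
  cat(sprintf("encoder stages: %d, decoder stages: %d\n",
              x$encoder_count, x$decoder_count))
  if (length(x$aspp_rates)) {
    cat("bottleneck dilation rates:", paste(x$aspp_rates, collapse = ", "), "\n")
  }
  cat(sprintf("output channels: %d\n", x$output_channels))
  for (nm in names(x$stage_shapes)) {
    s <- x$stage_shapes[[nm]]
    cat(sprintf("  %-18s %4d x %4d x %4d\n", nm, s[1L], s[2L], s[3L]))
  }
  invisible(x)
}

#' @export
print.ra_unet <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(
    "residual-attention atrous U-Net: depth %d, base %d, %d classes\n",
    cfg$depth, cfg$base_channels, cfg$num_classes))
  cat(sprintf("  attention: %s, dilated pyramid: %s\n",
              if (cfg$use_res_cbam) "on" else "off",
              if (cfg$use_modified_aspp)
                paste(cfg$aspp_rates, collapse = "/") else "off"))
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a directory with `params.rds` (serialized parameter
#' state) and a self-describing `config.json` sidecar holding the network
#' configuration.
#'
#' @param model an `"ra_unet"`.
#' @param path checkpoint directory (created if needed).
#' @return `save_checkpoint`: `path`, invisibly. `load_checkpoint`: the
#'   restored model.
#' @export
save_checkpoint <- function(model, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  cfg <- model$cfg
  jsonlite::write_json(unclass(cfg), file.path(path, "config.json"),
                       auto_unbox = TRUE)
  saveRDS(layers_state(collect_layers(model)), file.path(path, "params.rds"))
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  cfg_l <- jsonlite::read_json(file.path(path, "config.json"),
                               simplifyVector = TRUE)
  cfg <- network_config(
    in_channels = cfg_l$in_channels, base_channels = cfg_l$base_channels,
    num_classes = cfg_l$num_classes, depth = cfg_l$depth,
    aspp_rates = cfg_l$aspp_rates, mlp_reduction = cfg_l$mlp_reduction,
    spatial_kernel = cfg_l$spatial_kernel,
    use_res_cbam = cfg_l$use_res_cbam,
    use_modified_aspp = cfg_l$use_modified_aspp,
    upsample = cfg_l$upsample)
  model <- build_model(cfg)
  state <- readRDS(file.path(path, "params.rds"))
  layers_restore(collect_layers(model), state)
  model
}
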