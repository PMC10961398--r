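# Image/mask data pipeline: loading paired PNGs, the 3-class label
# convention (0 background, 1 leaf, 2 disease), stratified 6:2:2 splitting,
# the paired augmentation recipe (flips, crop-and-resize, photometric
# jitter) and input normalization.
#
# A sample is a plain list:
#   image: H x W x 3 integer array, 0..255
#   mask:  H x W integer matrix with values in {0, 1, 2}
#   id, disease_type, environment: strings
# Masks on disk are single-channel PNGs storing the raw class index, or
# paletted/RGB PNGs decoded through a user-supplied color -> class map.

MASK_CLASSES <- c(background = 0L, leaf = 1L, disease = 2L)

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

new_sample <- function(image, mask, id,
                       disease_type = "synthetic",
                       environment = "synthetic") {
  assert_that_(length(dim(image)) == 3L && dim(image)[3L] == 3L,
    "image must be an H x W x 3 array")
  assert_that_(all(dim(image)[1:2] == dim(mask)),
    "image (%dx%d) and mask (%dx%d) sizes differ",
    dim(image)[1L], dim(image)[2L], nrow(mask), ncol(mask))
  assert_that_(all(mask %in% MASK_CLASSES),
    "mask values outside {0,1,2}")
  list(image = image, mask = mask, id = as.character(id),
       disease_type = disease_type, environment = environment)
}

read_image_png <- function(path) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 2L) v <- array(rep(v, 3L), c(dim(v), 3L))
  if (dim(v)[3L] == 4L) v <- v[, , 1:3, drop = FALSE]
  array(as.integer(round(v * 255)), dim(v))
}

decode_mask <- function(path, palette = NULL) {
  v <- png::readPNG(path)
  if (length(dim(v)) == 2L) {
    m <- matrix(as.integer(round(v * 255)), nrow(v), ncol(v))
    bad <- setdiff(unique(as.vector(m)), MASK_CLASSES)
    assert_that_(length(bad) == 0L,
      "mask %s contains values outside the class map: %s", basename(path),
      paste(bad, collapse = ", "))
    return(m)
  }
  assert_that_(!is.null(palette),
    "mask %s is multi-channel; supply a color -> class palette",
    basename(path))
  hx <- toupper(grDevices::rgb(v[, , 1L], v[, , 2L], v[, , 3L]))
  names(palette) <- toupper(names(palette))
  missing <- unique(hx[!hx %in% names(palette)])
  assert_that_(length(missing) == 0L,
    "mask %s contains colors absent from the palette: %s", basename(path),
    paste(missing, collapse = ", "))
  matrix(unlist(palette[hx], use.names = FALSE), nrow(v), ncol(v))
}

#' Load paired image/mask samples
#'
#' Pairs are matched by filename stem (`x.png`/`x.jpg` image with `x.png`
#' mask) or described by a manifest CSV with columns
#' `id,image_path,mask_path,disease_type,environment`. Samples are sorted
#' by id for determinism.
#'
#' @param image_dir,mask_dir directories of images and single-channel
#'   label masks (PNG; images may also be loaded from a manifest).
#' @param manifest path to a manifest CSV; overrides the directory pair.
#' @param palette optional named list mapping `"#RRGGBB"` colors to class
#'   indices, for colorized masks.
#' @return a list of samples.
#' @export
load_samples <- function(image_dir = NULL, mask_dir = NULL,
                         manifest = NULL, palette = NULL) {
  if (!is.null(manifest)) {
    mf <- read.csv(manifest, stringsAsFactors = FALSE)
    base <- dirname(manifest)
    resolve <- function(p) ifelse(file.exists(p), p, file.path(base, p))
    samples <- lapply(seq_len(nrow(mf)), function(i) {
      new_sample(read_image_png(resolve(mf$image_path[i])),
                 decode_mask(resolve(mf$mask_path[i]), palette),
                 mf$id[i],
                 mf$disease_type[i] %||% "unknown",
                 mf$environment[i] %||% "unknown")
    })
  } else {
    assert_that_(dir.exists(image_dir), "image_dir %s not found", image_dir)
    assert_that_(dir.exists(mask_dir), "mask_dir %s not found", mask_dir)
    imgs <- list.files(image_dir, pattern = "\\.(png|jpg|jpeg)$",
                       ignore.case = TRUE)
    stems <- sub("\\.[^.]+$", "", imgs)
    mask_paths <- file.path(mask_dir, paste0(stems, ".png"))
    orphans <- imgs[!file.exists(mask_paths)]
    assert_that_(length(orphans) == 0L,
      "images without a matching mask: %s", paste(orphans, collapse = ", "))
    samples <- lapply(seq_along(imgs), function(i) {
      new_sample(read_image_png(file.path(image_dir, imgs[i])),
                 decode_mask(mask_paths[i], palette), stems[i],
                 "unknown", "unknown")
    })
  }
  samples[order(vapply(samples, `[[`, "", "id"))]
}

#' Write samples to disk
#'
#' Exports `images/<id>.png`, `masks/<id>.png` (raw class indices) and a
#' `manifest.csv` consumable by [load_samples()].
#'
#' @param samples a list of samples.
#' @param dir output directory.
#' @return the manifest path, invisibly.
#' @export
export_samples <- function(samples, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(samples, function(s) {
    ip <- file.path(dir, "images", paste0(s$id, ".png"))
    mp <- file.path(dir, "masks", paste0(s$id, ".png"))
    png::writePNG(s$image / 255, ip)
    png::writePNG(s$mask / 255, mp)
    data.frame(id = s$id, image_path = file.path("images", paste0(s$id, ".png")),
               mask_path = file.path("masks", paste0(s$id, ".png")),
               disease_type = s$disease_type, environment = s$environment)
  })
  mf <- do.call(rbind, rows)
  out <- file.path(dir, "manifest.csv")
  write.csv(mf, out, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Stratified train/validation/test split
#'
#' Splits sample ids 6:2:2 by default, independently within each
#' `disease_type` stratum, after a seeded shuffle; deterministic for a
#' fixed seed. Counts use rounding, so observed fractions are within one
#' sample of the ratios per stratum.
#'
#' @param samples a list of samples.
#' @param ratios train/validation/test fractions summing to 1.
#' @param seed integer seed for the shuffle.
#' @return a list of class `"dataset_split"` with id vectors `train`,
#'   `val`, `test`, plus the ratios and seed.
#' @export
split_dataset <- function(samples, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  assert_that_(length(samples) > 0, "samples must be non-empty")
  assert_that_(length(ratios) == 3L && abs(sum(ratios) - 1) < 1e-9,
    "ratios must be three fractions summing to 1")
  ids <- vapply(samples, `[[`, "", "id")
  strata <- vapply(samples, function(s) s$disease_type %||% "unknown", "")
  tr <- va <- te <- character(0)
  for (si in seq_along(sort(unique(strata)))) {
    st <- sort(unique(strata))[si]
    sid <- sort(ids[strata == st])
    n <- length(sid)
    sid <- with_seed(seed + si, sample(sid))
    n_tr <- round(ratios[1L] * n)
    n_va <- round(ratios[2L] * n)
    n_va <- min(n_va, n - n_tr)
    tr <- c(tr, sid[seq_len(n_tr)])
    va <- c(va, sid[n_tr + seq_len(n_va)])
    te <- c(te, sid[setdiff(seq_len(n), seq_len(n_tr + n_va))])
  }
  structure(list(train = tr, val = va, test = te,
                 ratios = ratios, seed = as.integer(seed)),
            class = "dataset_split")
}

#' Augmentation configuration
#'
#' Photometric ranges follow the protocol: brightness scaled by a factor
#' in 0.5-1.2, contrast and chroma each by a factor in 0.5-2.5. Geometric
#' transforms are random horizontal/vertical flips and a random crop of
#' 0.8-1.0 of each dimension, resized back.
#'
#' @param p_hflip,p_vflip flip probabilities.
#' @param crop_scale_range,crop range of the uniform crop scale.
#' @param brightness_range,contrast_range,chroma_range photometric factor
#'   ranges.
#' @return a list of class `"augmentation_config"`.
#' @export
augmentation_config <- function(p_hflip = 0.5, p_vflip = 0.5,
                                crop_scale_range = c(0.8, 1.0),
                                brightness_range = c(0.5, 1.2),
                                contrast_range = c(0.5, 2.5),
                                chroma_range = c(0.5, 2.5)) {
  chk <- function(r, nm) assert_that_(length(r) == 2L && r[1L] <= r[2L],
    "%s must be an increasing length-2 range", nm)
  chk(crop_scale_range, "crop_scale_range")
  chk(brightness_range, "brightness_range")
  chk(contrast_range, "contrast_range")
  chk(chroma_range, "chroma_range")
  assert_that_(all(c(p_hflip, p_vflip) >= 0 & c(p_hflip, p_vflip) <= 1),
    "flip probabilities must be in [0,1]")
  structure(list(p_hflip = p_hflip, p_vflip = p_vflip,
                 crop_scale_range = crop_scale_range,
                 brightness_range = brightness_range,
                 contrast_range = contrast_range,
                 chroma_range = chroma_range),
            class = "augmentation_config")
}

# bilinear resize of an H x W (x C) numeric array to new size
resize_bilinear <- function(x, out_h, out_w) {
  d <- dim(x)
  map <- function(n_out, n_in) {
    src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
    i0 <- pmin(pmax(floor(src), 0), n_in - 1)
    i1 <- pmin(i0 + 1, n_in - 1)
    t <- pmin(pmax(src - floor(src), 0), 1)
    list(i0 = i0 + 1, i1 = i1 + 1, t = t)
  }
  mh <- map(out_h, d[1L]); mw <- map(out_w, d[2L])
  one <- function(m) {
    a <- m[mh$i0, mw$i0, drop = FALSE] * (1 - mh$t) +
         m[mh$i1, mw$i0, drop = FALSE] * mh$t
    b <- m[mh$i0, mw$i1, drop = FALSE] * (1 - mh$t) +
         m[mh$i1, mw$i1, drop = FALSE] * mh$t
    a * rep(1 - mw$t, each = out_h) + b * rep(mw$t, each = out_h)
  }
  if (length(d) == 2L) return(one(x))
  out <- array(0, c(out_h, out_w, d[3L]))
  for (ci in seq_len(d[3L])) out[, , ci] <- one(x[, , ci])
  out
}

resize_nearest <- function(m, out_h, out_w) {
  d <- dim(m)
  ih <- pmin(pmax(ceiling((seq_len(out_h) - 0.5) * d[1L] / out_h), 1), d[1L])
  iw <- pmin(pmax(ceiling((seq_len(out_w) - 0.5) * d[2L] / out_w), 1), d[2L])
  m[ih, iw, drop = FALSE]
}

# saturation scaling toward/away from the per-pixel value (HSV V = max):
# rgb' = V - f * (V - rgb) scales HSV saturation by f, preserving hue and V
scale_chroma <- function(img, f) {
  v <- pmax(img[, , 1L], pmax(img[, , 2L], img[, , 3L]))
  out <- img
  for (ci in 1:3) out[, , ci] <- v - f * (v - img[, , ci])
  out
}

#' Augment one sample
#'
#' Geometric transforms (flips, crop-and-resize) are applied identically to
#' image and mask, the mask with nearest-neighbor resampling so no new
#' labels appear; photometric transforms (brightness, contrast, chroma)
#' touch the image only. Output size equals input size.
#'
#' @param sample a sample list.
#' @param cfg an [augmentation_config()].
#' @param seed optional integer; when given, draws come from a private,
#'   reproducible RNG stream.
#' @return the augmented sample.
#' @export
augment_sample <- function(sample, cfg = augmentation_config(), seed = NULL) {
  run <- function() {
    img <- sample$image * 1.0
    msk <- sample$mask
    h <- nrow(msk); w <- ncol(msk)
    if (runif(1) < cfg$p_hflip) {
      img <- img[, w:1, , drop = FALSE]
      msk <- msk[, w:1, drop = FALSE]
    }
    if (runif(1) < cfg$p_vflip) {
      img <- img[h:1, , , drop = FALSE]
      msk <- msk[h:1, , drop = FALSE]
    }
    s <- runif(1, cfg$crop_scale_range[1L], cfg$crop_scale_range[2L])
    if (s < 1) {
      ch <- max(1L, round(s * h)); cw <- max(1L, round(s * w))
      oy <- sample.int(h - ch + 1L, 1L); ox <- sample.int(w - cw + 1L, 1L)
      img <- img[oy:(oy + ch - 1L), ox:(ox + cw - 1L), , drop = FALSE]
      msk <- msk[oy:(oy + ch - 1L), ox:(ox + cw - 1L), drop = FALSE]
      img <- resize_bilinear(img, h, w)
      msk <- resize_nearest(msk, h, w)
    }
    fb <- runif(1, cfg$brightness_range[1L], cfg$brightness_range[2L])
    img <- img * fb
    fc <- runif(1, cfg$contrast_range[1L], cfg$contrast_range[2L])
    mu <- mean(img)
    img <- (img - mu) * fc + mu
    fs <- runif(1, cfg$chroma_range[1L], cfg$chroma_range[2L])
    img <- scale_chroma(img, fs)
    img <- array(as.integer(round(pmin(pmax(img, 0), 255))), dim(img))
    out <- new_sample(img, msk, sample$id, sample$disease_type,
                      sample$environment)
    # record the drawn factors for auditability of the sampling ranges
    attr(out, "draws") <- c(brightness = fb, contrast = fc, chroma = fs,
                            crop_scale = s)
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Normalize an image to a network input
#'
#' Converts an 8-bit `H x W x 3` image to a channels-first real array in
#' `[0, 1]` by dividing by 255.
#'
#' @param image an `H x W x 3` array with values in 0..255.
#' @return a `(3, H, W)` [feature_map()].
#' @export
normalize_image <- function(image) {
  assert_that_(length(dim(image)) == 3L,
    "image must be an H x W x C array")
  feature_map(aperm(image / 255, c(3L, 1L, 2L)))
}
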