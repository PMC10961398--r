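# Loading, splitting, paired augmentation and normalization.

test_that("export then load round-trips images and masks exactly", {
  samples <- tiny_samples(3L, 32L)
  dir <- file.path(tempdir(), "ds-roundtrip")
  export_samples(samples, dir)
  got <- load_samples(manifest = file.path(dir, "manifest.csv"))
  expect_length(got, 3L)
  expect_equal(vapply(got, `[[`, "", "id"),
               sort(vapply(samples, `[[`, "", "id")))
  for (i in seq_along(got)) {
    orig <- samples[[match(got[[i]]$id, vapply(samples, `[[`, "", "id"))]]
    expect_identical(got[[i]]$mask, orig$mask)
    expect_identical(got[[i]]$image, orig$image)
  }
  # directory pairing finds the same files
  got2 <- load_samples(file.path(dir, "images"), file.path(dir, "masks"))
  expect_length(got2, 3L)
  unlink(dir, recursive = TRUE)
})

test_that("loader reports orphans and unmapped mask values", {
  dir <- file.path(tempdir(), "ds-bad")
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(array(0.5, c(8, 8, 3)), file.path(dir, "images", "a.png"))
  expect_error(load_samples(file.path(dir, "images"), file.path(dir, "masks")),
               "a.png")
  png::writePNG(matrix(7 / 255, 8, 8), file.path(dir, "masks", "a.png"))
  expect_error(load_samples(file.path(dir, "images"), file.path(dir, "masks")),
               "7")
  unlink(dir, recursive = TRUE)
})

test_that("colorized masks decode through a palette map", {
  dir <- file.path(tempdir(), "ds-palette")
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(array(0.3, c(6, 6, 3)), file.path(dir, "images", "p.png"))
  rgb_mask <- array(0, c(6, 6, 3))
  rgb_mask[, , 2] <- matrix(c(rep(1, 18), rep(0, 18)), 6)  # left half green
  rgb_mask[1, 1, ] <- c(1, 0, 0)                           # one red pixel
  png::writePNG(rgb_mask, file.path(dir, "masks", "p.png"))
  pal <- list("#000000" = 0L, "#00FF00" = 1L, "#FF0000" = 2L)
  got <- load_samples(file.path(dir, "images"), file.path(dir, "masks"),
                      palette = pal)
  expect_equal(got[[1]]$mask[1, 1], 2L)
  expect_equal(got[[1]]$mask[2, 2], 1L)
  expect_equal(got[[1]]$mask[2, 5], 0L)
  # colors outside the palette are reported
  pal2 <- list("#000000" = 0L, "#00FF00" = 1L)
  expect_error(load_samples(file.path(dir, "images"),
                            file.path(dir, "masks"), palette = pal2),
               "#FF0000")
  unlink(dir, recursive = TRUE)
})

test_that("6:2:2 split is exact per stratum, seeded, disjoint and covering", {
  mk <- function(id, type) list(image = array(0L, c(4, 4, 3)),
                                mask = matrix(0L, 4, 4), id = id,
                                disease_type = type, environment = "indoor")
  one <- lapply(1:100, function(i) mk(sprintf("s%03d", i), "rust"))
  sp <- split_dataset(one, seed = 7)
  expect_equal(lengths(sp[c("train", "val", "test")]),
               c(train = 60L, val = 20L, test = 20L))
  expect_identical(sp, split_dataset(one, seed = 7))
  expect_false(identical(sp$train, split_dataset(one, seed = 8)$train))

  two <- c(lapply(1:50, function(i) mk(sprintf("a%03d", i), "rust")),
           lapply(1:50, function(i) mk(sprintf("b%03d", i), "grey_spot")))
  sp2 <- split_dataset(two, seed = 1)
  for (part in c("train", "val", "test")) {
    n_rust <- sum(grepl("^a", sp2[[part]]))
    n_grey <- sum(grepl("^b", sp2[[part]]))
    expect_equal(n_rust, n_grey)
  }
  expect_equal(length(sp2$train), 60L)

  # disjointness and coverage at awkward sizes
  for (n in c(7, 23, 41)) {
    ss <- lapply(seq_len(n), function(i) mk(sprintf("x%03d", i), "rust"))
    sp3 <- split_dataset(ss, seed = n)
    all_ids <- c(sp3$train, sp3$val, sp3$test)
    expect_equal(sort(all_ids), sprintf("x%03d", seq_len(n)))
    expect_equal(anyDuplicated(all_ids), 0L)
  }
  expect_error(split_dataset(list(), seed = 1), "non-empty")
})

test_that("identity augmentation is a no-op", {
  s <- tiny_samples(1L, 32L)[[1]]
  cfg <- augmentation_config(p_hflip = 0, p_vflip = 0,
                             crop_scale_range = c(1, 1),
                             brightness_range = c(1, 1),
                             contrast_range = c(1, 1),
                             chroma_range = c(1, 1))
  out <- augment_sample(s, cfg, seed = 1)
  expect_identical(out$image, s$image)
  expect_identical(out$mask, s$mask)
})

test_that("geometric transforms hit image and mask identically", {
  s <- tiny_samples(1L, 32L)[[1]]
  flip_cfg <- augmentation_config(p_hflip = 1, p_vflip = 0,
                                  crop_scale_range = c(1, 1),
                                  brightness_range = c(1, 1),
                                  contrast_range = c(1, 1),
                                  chroma_range = c(1, 1))
  out <- augment_sample(s, flip_cfg, seed = 2)
  expect_identical(out$mask, s$mask[, ncol(s$mask):1])       # array oracle
  expect_identical(out$image, s$image[, ncol(s$mask):1, ])
  both <- augmentation_config(p_hflip = 1, p_vflip = 1,
                              crop_scale_range = c(1, 1),
                              brightness_range = c(1, 1),
                              contrast_range = c(1, 1),
                              chroma_range = c(1, 1))
  out2 <- augment_sample(s, both, seed = 3)
  expect_identical(out2$mask, s$mask[nrow(s$mask):1, ncol(s$mask):1])
})

test_that("augmentation preserves size, label alphabet and never invents classes", {
  set.seed(40)
  for (s in tiny_samples(3L, 32L)) {
    out <- augment_sample(s, augmentation_config())
    expect_equal(dim(out$mask), dim(s$mask))
    expect_equal(dim(out$image), dim(s$image))
    expect_true(all(out$mask %in% unique(as.vector(s$mask))))
  }
})

test_that("drawn photometric factors stay inside the configured ranges", {
  set.seed(41)
  s <- tiny_samples(1L, 32L)[[1]]
  cfg <- augmentation_config()
  draws <- t(vapply(1:300, function(i)
    attr(augment_sample(s, cfg), "draws"), numeric(4)))
  expect_true(all(draws[, "brightness"] >= 0.5 & draws[, "brightness"] <= 1.2))
  expect_true(all(draws[, "contrast"] >= 0.5 & draws[, "contrast"] <= 2.5))
  expect_true(all(draws[, "chroma"] >= 0.5 & draws[, "chroma"] <= 2.5))
  expect_true(all(draws[, "crop_scale"] >= 0.8 & draws[, "crop_scale"] <= 1))
})

test_that("normalization scales 8-bit images into the unit cube, channels first", {
  img <- array(0L, c(4, 6, 3))
  expect_true(all(normalize_image(img) == 0))
  img255 <- array(255L, c(4, 6, 3))
  expect_true(all(normalize_image(img255) == 1))
  img[2, 3, 1] <- 128L
  fm <- normalize_image(img)
  expect_equal(dim(fm), c(3L, 4L, 6L))
  expect_equal(fm[1, 2, 3], 128 / 255, tolerance = 1e-12)
})
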