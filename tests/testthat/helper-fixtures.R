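# Shared fixtures, generated in code. A small memoized cache keeps the
# synthetic scenes from being regenerated in every test file.

fixture_env <- new.env(parent = emptyenv())

tiny_scene_params <- function(size = 32L) {
  scene_params(image_size = size, leaf_area_fraction = 0.35,
               disease_pixel_fraction = 0.03,
               lesion_count_range = c(2L, 5L))
}

tiny_samples <- function(n = 4L, size = 32L, seed = 300L) {
  key <- sprintf("samples_%d_%d_%d", n, size, seed)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- generate_dataset(n, tiny_scene_params(size),
                                           seed = seed)$samples
  }
  fixture_env[[key]]
}

tiny_net_config <- function(base_channels = 4L, ...) {
  network_config(base_channels = base_channels, depth = 2L,
                 mlp_reduction = 2L, spatial_kernel = 3L, ...)
}

random_chw <- function(c, h, w, seed = 1L) {
  set.seed(seed)
  array(rnorm(c * h * w), c(c, h, w))
}

# finite-difference gradient of a scalar-valued function at a few random
# parameter coordinates of a layer stack
# tol leaves room for finite-difference noise on parameters with near-zero
# gradients; real backprop defects show up as O(1) relative errors
check_param_gradients <- function(params, loss_fn, n_checks = 4L,
                                  eps = 1e-5, tol = 2e-3) {
  layers <- leafseg:::collect_layers(params)
  rel_errs <- c()
  for (l in layers) {
    for (f in leafseg:::param_fields(l)) {
      v <- get(f, envir = l)
      g <- get(paste0("g_", f), envir = l)
      for (t in sample(length(v), min(n_checks, length(v)))) {
        v[t] <- v[t] + eps; assign(f, v, envir = l)
        lp <- loss_fn()
        v[t] <- v[t] - 2 * eps; assign(f, v, envir = l)
        lm <- loss_fn()
        v[t] <- v[t] + eps; assign(f, v, envir = l)
        num <- (lp - lm) / (2 * eps)
        rel_errs <- c(rel_errs,
                      abs(num - g[t]) / max(1e-6, abs(num) + abs(g[t])))
      }
    }
  }
  expect_lt(max(rel_errs), tol)
}
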