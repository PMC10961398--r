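# Cross-entropy and weight-compression loss: frozen worked values, the
# gamma = 0 identity, ordering/monotonicity properties, the multi-class
# reduction and its gradient.

p_grid <- seq(0.01, 0.99, by = 0.01)

test_that("cross-entropy worked values", {
  expect_equal(ce_loss(0.5, 1), log(2), tolerance = 1e-12)
  expect_equal(ce_loss(0.5, 0), log(2), tolerance = 1e-12)
  expect_lt(ce_loss(1 - 1e-9, 1), 1e-8)
  expect_error(ce_loss(1.2, 1), "probability")
  expect_error(ce_loss(0, 1), "probability")
})

test_that("weight-compression loss equals the frozen oracle value and limits", {
  # (1 - atan(1/2))^2 * log 2, computed with an arbitrary-precision oracle
  expect_equal(wc_loss_binary(0.5, 1, 2), 0.199400343923891598,
               tolerance = 1e-12)
  expect_lt(wc_loss_binary(1 - 1e-9, 1, 2), 1e-8)
  expect_error(wc_loss_binary(0.5, 2, 2), "y must be")
})

test_that("gamma = 0 recovers cross-entropy exactly on both label branches", {
  for (y in c(0, 1)) {
    expect_equal(wc_loss_binary(p_grid, y, 0), ce_loss(p_grid, y),
                 tolerance = 1e-12)
  }
})

test_that("modulation factor ranges and loss orderings hold on a dense grid", {
  a <- atan(p_grid)
  expect_true(all(a > 0 & a < pi / 4))
  expect_true(all(1 - a > 1 - pi / 4 & 1 - a < 1))
  # positive gamma strictly compresses below cross-entropy
  for (g in c(0.5, 1, 2, 4)) {
    expect_true(all(wc_loss_binary(p_grid, 1, g) < ce_loss(p_grid, 1)))
  }
  # non-increasing in gamma for fixed p
  for (p in c(0.05, 0.3, 0.7, 0.95)) {
    vals <- vapply(c(0, 0.5, 1, 2, 3, 4), function(g)
      wc_loss_binary(p, 1, g), 0)
    expect_true(all(diff(vals) <= 1e-15))
  }
  # strictly decreasing in p for the positive branch, at every gamma
  for (g in c(0, 1, 2, 3, 4)) {
    expect_true(all(diff(wc_loss_binary(p_grid, 1, g)) < 0))
  }
  expect_true(all(is.finite(wc_loss_binary(p_grid, 1, 2))) &&
              all(wc_loss_binary(p_grid, 1, 2) >= 0))
})

test_that("multi-class loss reduces per-pixel binary values of the true class", {
  set.seed(20)
  lg <- array(rnorm(3 * 2 * 2), c(3, 2, 2))
  mask <- matrix(c(0L, 2L, 1L, 1L), 2, 2)
  # per-pixel brute force: softmax then the y = 1 branch formula
  manual <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    z <- lg[, i, j]
    pr <- exp(z - max(z)) / sum(exp(z - max(z)))
    pt <- pr[mask[i, j] + 1]
    manual[i, j] <- -(1 - atan(pt))^2 * log(pt)
  }
  expect_equal(wc_loss_multiclass(lg, mask, loss_config(gamma = 2)),
               mean(manual), tolerance = 1e-12)
  expect_equal(wc_loss_multiclass(lg, mask, loss_config(2, "sum")),
               sum(manual), tolerance = 1e-12)
  expect_equal(wc_loss_multiclass(lg, mask, loss_config(2, "none")),
               manual, tolerance = 1e-12)
  # gamma = 0 equals the softmax cross-entropy
  ce_manual <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    z <- lg[, i, j]
    pr <- exp(z - max(z)) / sum(exp(z - max(z)))
    ce_manual[i, j] <- -log(pr[mask[i, j] + 1])
  }
  expect_equal(wc_loss_multiclass(lg, mask, loss_config(gamma = 0)),
               mean(ce_manual), tolerance = 1e-12)
  # confident logits drive the loss to ~0
  conf <- array(-20, c(3, 2, 2))
  for (i in 1:2) for (j in 1:2) conf[mask[i, j] + 1, i, j] <- 20
  expect_lt(wc_loss_multiclass(conf, mask, loss_config()), 1e-3)
  expect_error(wc_loss_multiclass(lg, matrix(3L, 2, 2), loss_config()),
               "labels")
  expect_error(wc_loss_multiclass(lg, matrix(0L, 3, 3), loss_config()),
               "does not match")
})

test_that("loss gradient with respect to logits matches finite differences", {
  set.seed(21)
  lg <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  mask <- array(sample(0:2, 32, TRUE), c(4, 4, 2))
  for (g in c(0, 2)) {
    r <- leafseg:::wc_loss_grad(lg, mask, g)
    eps <- 1e-6
    for (t in sample(length(lg), 6)) {
      lp <- lg; lp[t] <- lp[t] + eps
      lm <- lg; lm[t] <- lm[t] - eps
      num <- (leafseg:::wc_loss_grad(lp, mask, g, want_grad = FALSE)$mean -
              leafseg:::wc_loss_grad(lm, mask, g, want_grad = FALSE)$mean) /
        (2 * eps)
      expect_equal(r$glogits[t], num, tolerance = 1e-5)
    }
  }
})

test_that("gamma sweep produces one deterministic row per exponent", {
  samples <- tiny_samples(4L, 32L)
  factory <- function() build_model(tiny_net_config())
  cfg <- train_config(learning_rate = 0.05, epochs = 0, seed = 5)
  # zero-epoch runs: every exponent reports the untrained model's metrics
  sweep0 <- gamma_sweep(samples, c(0, 1, 2, 3, 4), factory, cfg)
  expect_equal(nrow(sweep0), 5L)
  expect_equal(sweep0$gamma, c(0, 1, 2, 3, 4))
  expect_true(all(sweep0$status == "ok"))
  expect_equal(sweep0$mIoU, rep(sweep0$mIoU[1], 5))

  cfg1 <- train_config(learning_rate = 0.05, epochs = 1, seed = 5)
  s1 <- gamma_sweep(samples, 2, factory, cfg1)
  s2 <- gamma_sweep(samples, 2, factory, cfg1)
  expect_equal(s1, s2)
  csv <- file.path(tempdir(), "sweep.csv")
  gamma_sweep(samples, c(0, 2), factory, cfg, out_csv = csv)
  got <- read.csv(csv)
  expect_equal(names(got), c("gamma", "mIoU", "mPA", "accuracy"))
  expect_equal(nrow(got), 2L)
  unlink(csv)
})
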