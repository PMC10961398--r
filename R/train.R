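# Training loop (SGD with momentum, cosine or step learning-rate decay),
# evaluation against the confusion-matrix metric suite, and the ablation
# harness. Everything is seeded: parameter initialization, data order and
# augmentation draw from the seed in the training configuration, so a rerun
# with the same configuration reproduces the loss sequence exactly.

#' Training configuration
#'
#' Defaults mirror the experimental protocol: SGD with momentum 0.9,
#' initial learning rate 1e-4, batch size 4, 200 epochs, weight-compression
#' loss with exponent 2, cosine learning-rate decay. Scaled-down harnesses
#' (tests, sweeps) override the budget fields.
#'
#' @param learning_rate initial learning rate (> 0).
#' @param momentum SGD momentum.
#' @param batch_size images per optimization step.
#' @param epochs full passes over the training set (>= 0).
#' @param optimizer only `"sgd"`.
#' @param lr_schedule `"cosine"` (annealed to ~0), `"step"` (x0.1 at 1/3
#'   and 2/3 of the budget) or `"none"`.
#' @param loss `"wc"` (weight-compression) or `"ce"` (plain cross-entropy,
#'   i.e. the exponent forced to 0).
#' @param gamma modulation exponent of the weight-compression loss.
#' @param seed integer seed for initialization, shuffling, augmentation.
#' @param augment apply the augmentation recipe to training samples.
#' @param max_steps optional cap on total optimization steps (for short
#'   sanity runs); `NULL` for no cap.
#' @param eval_every validate every this many epochs (the final epoch is
#'   always validated); intermediate epochs log `NA` validation fields.
#' @return a list of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 1e-4, momentum = 0.9,
                         batch_size = 4L, epochs = 200L,
                         optimizer = "sgd",
                         lr_schedule = c("cosine", "step", "none"),
                         loss = c("wc", "ce"), gamma = 2, seed = 1L,
                         augment = FALSE, max_steps = NULL,
                         eval_every = 1L) {
  lr_schedule <- match.arg(lr_schedule)
  loss <- match.arg(loss)
  assert_that_(learning_rate > 0, "learning_rate must be positive")
  assert_that_(is_count(batch_size), "batch_size must be >= 1")
  assert_that_(is.numeric(epochs) && epochs >= 0 && epochs == round(epochs),
    "epochs must be a non-negative integer")
  assert_that_(identical(optimizer, "sgd"), "only SGD is implemented")
  assert_that_(gamma >= 0, "gamma must be non-negative")
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), optimizer = optimizer,
                 lr_schedule = lr_schedule, loss = loss, gamma = gamma,
                 seed = as.integer(seed), augment = isTRUE(augment),
                 max_steps = max_steps, eval_every = as.integer(eval_every)),
            class = "train_config")
}

lr_at_epoch <- function(cfg, epoch) {
  e <- max(cfg$epochs, 1L)
  switch(cfg$lr_schedule,
    cosine = 0.5 * cfg$learning_rate *
      (1 + cos(pi * (epoch - 1) / max(1L, e - 1L))),
    step = cfg$learning_rate *
      0.1^(findInterval(epoch, c(ceiling(e / 3) + 1L,
                                 ceiling(2 * e / 3) + 1L))),
    none = cfg$learning_rate)
}

samples_to_batch <- function(samples, idx) {
  h <- nrow(samples[[idx[1L]]]$mask)
  w <- ncol(samples[[idx[1L]]]$mask)
  x <- array(0, c(h, w, 3L, length(idx)))
  mk <- array(0L, c(h, w, length(idx)))
  for (i in seq_along(idx)) {
    s <- samples[[idx[i]]]
    x[, , , i] <- s$image / 255
    mk[, , i] <- s$mask
  }
  list(x = x, mask = mk)
}

#' Train a model
#'
#' Mini-batch SGD with momentum over the training ids of `split` (or all
#' samples when no split is given), per-epoch validation, and selection of
#' the best checkpoint by validation mIoU. The effective loss exponent is
#' `cfg$gamma` for the weight-compression loss and 0 for plain
#' cross-entropy.
#'
#' @param model an `"ra_unet"` (its parameters are updated in place).
#' @param samples list of samples; ids must be unique.
#' @param cfg a [train_config()].
#' @param split optional [split_dataset()] result; `train` ids are used
#'   for optimization and `val` ids for model selection.
#' @param checkpoint_dir optional directory; the best checkpoint and a
#'   JSON-lines training log are written there.
#' @return a list of class `"training_run"`: `model` (with the best
#'   parameters restored), `log` (one row per epoch), `best_epoch`,
#'   `config`.
#' @export
train_model <- function(model, samples, cfg = train_config(), split = NULL,
                        checkpoint_dir = NULL) {
  ids <- vapply(samples, `[[`, "", "id")
  if (is.null(split)) {
    tr_idx <- seq_along(samples)
    va_idx <- seq_along(samples)
  } else {
    tr_idx <- match(split$train, ids)
    va_idx <- match(split$val, ids)
    assert_that_(length(tr_idx) > 0 && !anyNA(tr_idx),
      "split train ids missing from samples")
    assert_that_(length(va_idx) > 0 && !anyNA(va_idx),
      "split val ids missing from samples")
  }
  gamma <- if (cfg$loss == "ce") 0 else cfg$gamma
  layers <- collect_layers(model)
  set.seed(cfg$seed)

  log_rows <- list()
  best <- list(miou = -Inf, state = layers_state(layers), epoch = 0L)
  steps_done <- 0L
  aug_cfg <- augmentation_config()

  for (epoch in seq_len(cfg$epochs)) {
    if (!is.null(cfg$max_steps) && steps_done >= cfg$max_steps) break
    lr <- lr_at_epoch(cfg, epoch)
    order_idx <- sample(tr_idx)
    batch_losses <- c()
    for (b0 in seq(1L, length(order_idx), by = cfg$batch_size)) {
      if (!is.null(cfg$max_steps) && steps_done >= cfg$max_steps) break
      idx <- order_idx[b0:min(b0 + cfg$batch_size - 1L, length(order_idx))]
      use <- samples[idx]
      if (cfg$augment) {
        use <- lapply(use, function(s) augment_sample(s, aug_cfg))
      }
      bt <- samples_to_batch(use, seq_along(use))
      fw <- net_fwd(model, bt$x, train = TRUE)
      ls <- wc_loss_grad(fw$logits, bt$mask, gamma)
      if (!is.finite(ls$mean)) {
        stop_f("non-finite loss %g at epoch %d, batch starting %d",
               ls$mean, epoch, b0)
      }
      zero_grads(layers)
      net_bwd(model, fw$cache, ls$glogits)
      sgd_step(layers, lr, cfg$momentum)
      batch_losses <- c(batch_losses, ls$mean)
      steps_done <- steps_done + 1L
    }
    do_eval <- epoch %% cfg$eval_every == 0L || epoch == cfg$epochs ||
      (!is.null(cfg$max_steps) && steps_done >= cfg$max_steps)
    if (do_eval) {
      ev <- evaluate_model(model, samples[va_idx], loss_gamma = gamma)
      pc <- ev$report$per_class
      row <- data.frame(
        epoch = epoch, lr = lr,
        train_loss = mean(batch_losses), val_loss = ev$loss,
        acc_background = pc$recall[1L],
        acc_leaf = if (nrow(pc) > 1L) pc$recall[2L] else NA_real_,
        acc_disease = if (nrow(pc) > 2L) pc$recall[3L] else NA_real_,
        mIoU = ev$report$mIoU)
      if (ev$report$mIoU > best$miou) {
        best <- list(miou = ev$report$mIoU, state = layers_state(layers),
                     epoch = epoch)
      }
    } else {
      row <- data.frame(
        epoch = epoch, lr = lr, train_loss = mean(batch_losses),
        val_loss = NA_real_, acc_background = NA_real_,
        acc_leaf = NA_real_, acc_disease = NA_real_, mIoU = NA_real_)
    }
    log_rows[[epoch]] <- row
  }

  layers_restore(layers, best$state)
  log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(epoch = integer(), lr = numeric(), train_loss = numeric(),
               val_loss = numeric(), acc_background = numeric(),
               acc_leaf = numeric(), acc_disease = numeric(),
               mIoU = numeric())
  if (!is.null(checkpoint_dir)) {
    save_checkpoint(model, file.path(checkpoint_dir, "best"))
    jl <- file.path(checkpoint_dir, "training_log.jsonl")
    writeLines(vapply(seq_len(nrow(log)), function(i)
      as.character(jsonlite::toJSON(as.list(log[i, ]), auto_unbox = TRUE,
                                    digits = NA)), ""), jl)
  }
  structure(list(model = model, log = log, best_epoch = best$epoch,
                 config = cfg),
            class = "training_run")
}

#' Evaluate a model on labelled samples
#'
#' Aggregates a single confusion matrix of predicted vs true labels over
#' all samples and returns the full metrics report. Deterministic.
#'
#' @param model an `"ra_unet"`.
#' @param samples list of samples with masks.
#' @param loss_gamma optional exponent; when given, the mean
#'   weight-compression loss over the samples is also reported.
#' @return a list with `report` ([metrics_report()]), `confusion` and
#'   `loss` (or `NA`).
#' @export
evaluate_model <- function(model, samples, loss_gamma = NULL) {
  assert_that_(length(samples) > 0, "no samples to evaluate")
  k <- model$cfg$num_classes
  cm <- NULL
  total_loss <- 0
  for (s in samples) {
    bt <- samples_to_batch(list(s), 1L)
    fw <- net_fwd(model, bt$x, train = FALSE)
    d <- dim(fw$logits)
    m <- matrix(batch_sample(fw$logits, 1L), nrow = d[1L] * d[2L])
    pred <- matrix(max.col(m, ties.method = "first") - 1L, d[1L], d[2L])
    cmi <- confusion_from_masks(pred, s$mask, k)
    cm <- if (is.null(cm)) cmi else cm + cmi
    if (!is.null(loss_gamma)) {
      total_loss <- total_loss +
        wc_loss_grad(fw$logits, bt$mask, loss_gamma, want_grad = FALSE)$mean
    }
  }
  class(cm) <- c("confusion_matrix", "matrix", "array")
  list(report = metrics_report(cm), confusion = cm,
       loss = if (is.null(loss_gamma)) NA_real_ else
         total_loss / length(samples))
}

#' Module ablation harness
#'
#' Runs the five-configuration comparison under identical seeds and
#' budgets: plain U-Net backbone with cross-entropy, the same with the
#' weight-compression loss, then adding the residual attention module, the
#' dilated pyramid bottleneck, and both. Per-run failures are recorded in
#' the table rather than aborting the harness.
#'
#' @param samples training/evaluation samples.
#' @param base_net_cfg a [network_config()] used as the template (its
#'   ablation switches are overridden per row).
#' @param train_cfg a [train_config()] shared by all five runs.
#' @param eval_samples samples to evaluate on (default: `samples`).
#' @return a data.frame with 5 rows: configuration flags, loss identifier,
#'   accuracy, mIoU, mPA, per-class IoU, status.
#' @export
run_ablation <- function(samples, base_net_cfg = network_config(),
                         train_cfg = train_config(),
                         eval_samples = samples) {
  plan <- data.frame(
    test = 1:5,
    loss = c("ce", "wc", "wc", "wc", "wc"),
    res_cbam = c(FALSE, FALSE, TRUE, FALSE, TRUE),
    aspp = c(FALSE, FALSE, FALSE, TRUE, TRUE))
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    cfg <- train_cfg
    cfg$loss <- plan$loss[i]
    net_cfg <- base_net_cfg
    net_cfg$use_res_cbam <- plan$res_cbam[i]
    net_cfg$use_modified_aspp <- plan$aspp[i]
    tryCatch({
      set.seed(cfg$seed)
      model <- build_model(net_cfg)
      fit <- train_model(model, samples, cfg = cfg)
      ev <- evaluate_model(fit$model, eval_samples)
      pc <- ev$report$per_class
      data.frame(plan[i, ], accuracy = ev$report$accuracy,
                 mIoU = ev$report$mIoU, mPA = ev$report$mPA,
                 background_iou = pc$iou[1L],
                 leaf_iou = if (nrow(pc) > 1L) pc$iou[2L] else NA_real_,
                 disease_iou = if (nrow(pc) > 2L) pc$iou[3L] else NA_real_,
                 status = "ok")
    }, error = function(e) {
      data.frame(plan[i, ], accuracy = NA_real_, mIoU = NA_real_,
                 mPA = NA_real_, background_iou = NA_real_,
                 leaf_iou = NA_real_, disease_iou = NA_real_,
                 status = conditionMessage(e))
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
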