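# Confusion-matrix metric suite: hand-enumerated worked examples,
# algebraic invariants, and cross-validation against independent
# implementations (caret for agreement metrics, direct per-pixel set
# operations for IoU).

cm_toy <- function() {
  # truth/pred pair enumerating to counts [[4,1],[2,3]]
  truth <- c(rep(0, 5), rep(1, 5))
  pred <- c(0, 0, 0, 0, 1, 0, 0, 1, 1, 1)
  confusion_from_masks(pred, truth, 2)
}

test_that("confusion matrix counts enumerate pixels by (truth, prediction)", {
  truth <- c(0, 0, 1, 1)
  pred <- c(0, 1, 1, 1)
  cm <- confusion_from_masks(pred, truth, 2)
  expect_equal(unclass(unname(cm)), matrix(c(1, 0, 1, 2), 2),
               ignore_attr = TRUE)
  expect_equal(sum(cm), 4)
  # perfect agreement is purely diagonal
  m <- matrix(sample(0:2, 100, TRUE), 10)
  cmp <- confusion_from_masks(m, m, 3)
  expect_equal(sum(diag(cmp)), 100)
  expect_equal(sum(cmp) - sum(diag(cmp)), 0)
  # additivity over batches
  m2 <- matrix(sample(0:2, 100, TRUE), 10)
  p2 <- matrix(sample(0:2, 100, TRUE), 10)
  joint <- confusion_from_masks(c(m, p2), c(m, m2), 3)
  expect_equal(unclass(confusion_from_masks(m, m, 3) +
                       confusion_from_masks(p2, m2, 3)),
               unclass(joint), ignore_attr = TRUE)
  expect_error(confusion_from_masks(c(0, 3), c(0, 1), 2), "labels")
  expect_error(confusion_from_masks(matrix(0, 2, 2), matrix(0, 2, 3), 2),
               "identical shapes")
})

test_that("worked example: acc 0.7, class-1 P/R/F1/IoU, mIoU, kappa 0.4", {
  cm <- cm_toy()
  b <- basic_metrics(cm)
  expect_equal(b$accuracy, 0.7)
  expect_equal(b$per_class$precision[2], 0.75)
  expect_equal(b$per_class$recall[2], 0.6)
  expect_equal(b$per_class$f1[2], 2 * 0.75 * 0.6 / 1.35, tolerance = 1e-12)
  expect_equal(b$per_class$iou[2], 0.5)
  m <- mean_metrics(cm)
  expect_equal(m$mIoU, (4 / 7 + 3 / 6) / 2, tolerance = 1e-12)
  expect_equal(m$mPA, (4 / 5 + 3 / 5) / 2, tolerance = 1e-12)
  expect_equal(cohens_kappa(cm), 0.4, tolerance = 1e-12)
})

test_that("degenerate and perfect cases", {
  m <- matrix(sample(0:2, 64, TRUE), 8)
  cm <- confusion_from_masks(m, m, 3)
  r <- metrics_report(cm)
  expect_equal(r$accuracy, 1)
  expect_equal(r$mIoU, 1)
  expect_equal(r$mPA, 1)
  expect_equal(r$kappa, 1)
  expect_true(all(r$per_class$iou == 1))
  # single observed class, predicted perfectly: chance agreement is 1 but
  # so is observed agreement
  cm1 <- confusion_from_masks(rep(0, 10), rep(0, 10), 2)
  expect_equal(cohens_kappa(cm1), 1)
  r1 <- metrics_report(cm1)
  expect_equal(r1$accuracy, 1)
  expect_true(r1$per_class$absent[2])
  expect_error(basic_metrics(matrix(0, 2, 2)), "empty")
  # statistically independent prediction: kappa ~ 0
  marg <- c(60, 30, 10)
  ind <- outer(marg, marg) / sum(marg)
  class(ind) <- c("confusion_matrix", "matrix", "array")
  expect_lt(abs(cohens_kappa(ind)), 1e-12)
})

test_that("metric invariants: relabeling, weighted recall, mIoU <= mPA, kappa <= accuracy", {
  set.seed(30)
  for (i in 1:20) {
    truth <- sample(0:2, 400, TRUE, prob = c(0.7, 0.25, 0.05))
    pred <- ifelse(runif(400) < 0.3, sample(0:2, 400, TRUE), truth)
    cm <- confusion_from_masks(pred, truth, 3)
    r <- metrics_report(cm)
    # simultaneous row/column permutation leaves every metric unchanged
    perm <- sample(3)
    cmp <- cm[perm, perm]
    class(cmp) <- class(cm)
    rp <- metrics_report(cmp)
    expect_equal(sort(r$per_class$iou), sort(rp$per_class$iou))
    expect_equal(r$accuracy, rp$accuracy)
    expect_equal(r$mIoU, rp$mIoU, tolerance = 1e-12)
    expect_equal(r$kappa, rp$kappa, tolerance = 1e-12)
    # accuracy is the count-weighted mean of recalls
    expect_equal(r$accuracy,
                 sum(rowSums(cm) / sum(cm) * r$per_class$recall),
                 tolerance = 1e-12)
    expect_lte(r$mIoU, r$mPA + 1e-12)
    expect_lte(r$kappa, r$accuracy + 1e-12)
    expect_true(all(unlist(r[c("accuracy", "mPA", "mIoU")]) >= 0))
  }
})

test_that("metrics agree with caret and a per-pixel set-operation IoU oracle", {
  set.seed(31)
  for (i in 1:20) {
    truth <- matrix(sample(0:2, 256, TRUE, prob = c(0.6, 0.3, 0.1)), 16)
    pred <- matrix(ifelse(runif(256) < 0.25,
                          sample(0:2, 256, TRUE), truth), 16)
    cm <- confusion_from_masks(pred, truth, 3)
    r <- metrics_report(cm)
    lev <- factor(0:2)
    cc <- caret::confusionMatrix(factor(pred, levels = lev),
                                 factor(truth, levels = lev))
    expect_equal(unname(r$accuracy), unname(cc$overall["Accuracy"]),
                 tolerance = 1e-9)
    expect_equal(unname(r$kappa), unname(cc$overall["Kappa"]),
                 tolerance = 1e-9)
    expect_equal(r$per_class$recall,
                 unname(cc$byClass[, "Sensitivity"]), tolerance = 1e-9)
    expect_equal(r$per_class$precision,
                 unname(cc$byClass[, "Precision"]), tolerance = 1e-9)
    # IoU against direct set arithmetic on the masks
    for (k in 0:2) {
      inter <- sum(pred == k & truth == k)
      uni <- sum(pred == k | truth == k)
      expect_equal(r$per_class$iou[k + 1], inter / uni, tolerance = 1e-12)
    }
  }
})

test_that("report formats as a per-class table and serializes to JSON", {
  r <- metrics_report(cm_toy())
  lines <- format_metrics_table(r)
  expect_match(lines[1], "IoU")
  expect_length(lines, 4L) # header + 2 classes + summary
  js <- jsonlite::fromJSON(metrics_to_json(r))
  expect_equal(js$accuracy, 0.7)
  expect_equal(nrow(js$per_class), 2L)
})
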