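# Evaluation suite computed from a pixel confusion matrix: accuracy,
# per-class precision / recall / F1 / IoU, mean pixel accuracy (mPA), mean
# IoU, the column-sum variants mPrecision / mRecall, and Cohen's kappa.
#
# Orientation convention: rows are ground truth, columns are prediction, so
# counts[t, p] is the number of pixels whose true class is t and predicted
# class is p. A class absent from both truth and prediction contributes the
# sentinel value 1 to macro averages and is flagged; a class absent from
# the truth only contributes 0 recall. This keeps macro averages NaN-free
# while making degenerate inputs visible.

#' Confusion matrix from label masks
#'
#' @param pred,truth integer matrices/arrays of equal shape with labels in
#'   `0 .. n_classes - 1`.
#' @param n_classes total class count (3 for background/leaf/disease).
#' @param class_names optional labels; default `class0 ..`, or
#'   background/leaf/disease when `n_classes == 3`.
#' @return an `n_classes x n_classes` integer matrix of class
#'   `"confusion_matrix"`, rows = truth, columns = prediction.
#' @export
confusion_from_masks <- function(pred, truth, n_classes,
                                 class_names = NULL) {
  assert_that_(length(pred) == length(truth) &&
    identical(dim(pred), dim(truth)),
    "pred and truth must have identical shapes")
  p <- as.integer(pred)
  t_ <- as.integer(truth)
  k <- as.integer(n_classes)
  bad <- c(p[p < 0L | p >= k], t_[t_ < 0L | t_ >= k])
  assert_that_(length(bad) == 0L,
    "labels outside 0..%d found (e.g. %d)", k - 1L,
    if (length(bad)) bad[1L] else 0L)
  counts <- matrix(tabulate(t_ * k + p + 1L, nbins = k * k),
                   nrow = k, ncol = k, byrow = TRUE)
  if (is.null(class_names)) {
    class_names <- if (k == 3L) c("background", "leaf", "disease")
                   else paste0("class", seq_len(k) - 1L)
  }
  dimnames(counts) <- list(truth = class_names, prediction = class_names)
  structure(counts, class = c("confusion_matrix", "matrix", "array"))
}

check_cm <- function(cm) {
  assert_that_(is.matrix(cm) && nrow(cm) == ncol(cm),
    "a confusion matrix must be square")
  assert_that_(all(cm >= 0), "confusion-matrix counts must be non-negative")
  assert_that_(sum(cm) > 0, "confusion matrix is empty")
  invisible(cm)
}

per_class_stats <- function(cm) {
  check_cm(cm)
  tp <- diag(cm)
  rs <- rowSums(cm)   # ground-truth pixels per class
  cs <- colSums(cm)   # predicted pixels per class
  absent <- rs == 0 & cs == 0
  precision <- ifelse(absent, 1, ifelse(cs > 0, tp / cs, 0))
  recall <- ifelse(absent, 1, ifelse(rs > 0, tp / rs, 0))
  f1 <- ifelse(absent, 1,
               ifelse(precision + recall > 0,
                      2 * precision * recall / (precision + recall), 0))
  denom <- rs + cs - tp
  iou <- ifelse(absent, 1, ifelse(denom > 0, tp / denom, 0))
  data.frame(class = rownames(cm) %||% paste0("class", seq_len(nrow(cm)) - 1L),
             precision = unname(precision), recall = unname(recall),
             f1 = unname(f1), iou = unname(iou),
             absent = unname(absent), row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Accuracy and per-class precision/recall/F1/IoU
#'
#' Accuracy is the trace over the total. Per class, precision divides the
#' diagonal by the prediction column sum, recall by the ground-truth row
#' sum, and IoU by their union (row + column - diagonal).
#'
#' @param cm a [confusion_from_masks()] matrix (rows truth, columns
#'   prediction).
#' @return a list with `accuracy` and a `per_class` data.frame (columns
#'   precision, recall, f1, iou, absent).
#' @export
basic_metrics <- function(cm) {
  check_cm(cm)
  list(accuracy = sum(diag(cm)) / sum(cm), per_class = per_class_stats(cm))
}

#' Macro-averaged metrics
#'
#' `mPA` is the unweighted mean over classes of per-class pixel accuracy
#' (diagonal over the ground-truth row sum); `mIoU` the mean per-class
#' intersection over union; `mPrecision` / `mRecall` the unweighted means
#' of per-class precision and recall.
#'
#' @inheritParams basic_metrics
#' @return a named list with `mPA`, `mIoU`, `mPrecision`, `mRecall`.
#' @export
mean_metrics <- function(cm) {
  st <- per_class_stats(cm)
  list(mPA = mean(st$recall), mIoU = mean(st$iou),
       mPrecision = mean(st$precision), mRecall = mean(st$recall))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between prediction and truth:
#' `kappa = (po - pe) / (1 - pe)` with `po` the observed agreement (trace
#' over total) and `pe` the agreement expected from the marginals. Returns
#' 1 for perfect agreement even when the marginals are degenerate
#' (`pe = 1` with `po = 1`); `pe = 1` with imperfect agreement is an error.
#'
#' @inheritParams basic_metrics
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(cm) {
  check_cm(cm)
  total <- sum(cm)
  po <- sum(diag(cm)) / total
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (pe >= 1 - 1e-15) {
    if (po >= 1 - 1e-15) return(1)
    stop_f("degenerate agreement: chance agreement is 1 but observed is %g", po)
  }
  (po - pe) / (1 - pe)
}

#' Full metrics report
#'
#' Bundles [basic_metrics()], [mean_metrics()] and [cohens_kappa()] into
#' one object that serializes to JSON.
#'
#' @inheritParams basic_metrics
#' @return a list of class `"metrics_report"` with fields `accuracy`,
#'   `per_class`, `mPA`, `mIoU`, `mPrecision`, `mRecall`, `kappa`.
#' @export
metrics_report <- function(cm) {
  b <- basic_metrics(cm)
  m <- mean_metrics(cm)
  structure(c(b, m, list(kappa = cohens_kappa(cm))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(format_metrics_table(x), sep = "\n")
  invisible(x)
}

#' Format a metrics report as a per-class table
#'
#' One row per class with IoU, recall, precision and F1 (percentages),
#' followed by overall accuracy, mPA, mIoU and kappa.
#'
#' @param report a [metrics_report()].
#' @return a character vector of formatted lines.
#' @export
format_metrics_table <- function(report) {
  pc <- report$per_class
  lines <- c(
    sprintf("%-12s %8s %8s %8s %8s", "Class", "IoU/%", "R/%", "P/%", "F1/%"),
    sprintf("%-12s %8.2f %8.2f %8.2f %8.2f", pc$class, 100 * pc$iou,
            100 * pc$recall, 100 * pc$precision, 100 * pc$f1),
    sprintf("accuracy %.4f  mPA %.4f  mIoU %.4f  kappa %.4f",
            report$accuracy, report$mPA, report$mIoU, report$kappa))
  lines
}

#' Serialize a metrics report to JSON
#'
#' @param report a [metrics_report()].
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
metrics_to_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
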