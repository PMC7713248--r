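#' Binary-classification metrics
#'
#' Confusion matrix at a probability threshold plus threshold-free ROC and
#' precision-recall curves with trapezoidal areas. Conventions: positives are
#' the nodular class; precision = TP / (TP + FP), recall = TP / (TP + FN),
#' accuracy = (TP + TN) / n. With a single-class truth the ROC AUC is
#' undefined and reported as `NA`.
#'
#' @param scores predicted scores in \[0, 1\] (or hard 0/1 labels).
#' @param truth true labels (logical or 0/1).
#' @param threshold score threshold for the confusion matrix; default 0.5.
#' @return object of class `classification_metrics`: `tp`, `fp`, `fn`, `tn`,
#'   `accuracy`, `precision`, `recall`, `roc` (data frame `fpr`, `tpr`),
#'   `auc_roc`, `pr` (data frame `recall`, `precision`), `auc_pr`, `n`.
#' @examples
#' # 25 test examples: 8 TP, 2 FN, 0 FP, 15 TN
#' truth <- rep(c(TRUE, FALSE), c(10, 15))
#' pred <- c(rep(1, 8), rep(0, 2), rep(0, 15))
#' m <- evaluate(pred, truth)
#' c(m$accuracy, m$precision, m$recall)  # 0.92 1.00 0.80
#' @export
evaluate <- function(scores, truth, threshold = 0.5) {
  truth <- as.logical(truth)
  scores <- as.numeric(scores)
  if (length(scores) != length(truth)) stop("length mismatch")
  if (anyNA(scores) || anyNA(truth)) stop("missing values")
  n <- length(truth)
  pred <- scores >= threshold
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  fn <- sum(!pred & truth); tn <- sum(!pred & !truth)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_

  npos <- sum(truth); nneg <- n - npos
  if (npos > 0 && nneg > 0) {
    ord <- order(scores, decreasing = TRUE)
    tps <- cumsum(truth[ord]); fps <- cumsum(!truth[ord])
    # one point per distinct threshold
    keep <- c(diff(scores[ord]) != 0, TRUE)
    tps <- tps[keep]; fps <- fps[keep]
    tpr <- c(0, tps / npos); fpr <- c(0, fps / nneg)
    auc_roc <- sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
    prec <- tps / (tps + fps); rec <- tps / npos
    rec0 <- c(0, rec); prec0 <- c(prec[1], prec)
    auc_pr <- sum(diff(rec0) * (utils::head(prec0, -1) + prec0[-1]) / 2)
    roc <- data.frame(fpr = fpr, tpr = tpr)
    pr <- data.frame(recall = rec0, precision = prec0)
  } else {
    auc_roc <- NA_real_; auc_pr <- NA_real_
    roc <- data.frame(fpr = numeric(), tpr = numeric())
    pr <- data.frame(recall = numeric(), precision = numeric())
  }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 accuracy = (tp + tn) / n, precision = precision,
                 recall = recall, roc = roc, auc_roc = auc_roc, pr = pr,
                 auc_pr = auc_pr, n = n, threshold = threshold),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(
    "n = %d | TP %d FP %d FN %d TN %d | acc %.3f prec %s rec %s\n",
    x$n, x$tp, x$fp, x$fn, x$tn, x$accuracy,
    format(round(x$precision, 3)), format(round(x$recall, 3))))
  if (!is.na(x$auc_roc))
    cat(sprintf("AUC-ROC %.3f | AUC-PR %.3f\n", x$auc_roc, x$auc_pr))
  invisible(x)
}

#' Write metrics (and curves) to disk
#'
#' @param m a [evaluate()] result.
#' @param path JSON path; ROC/PR curves are written alongside as CSV.
#' @return `path`, invisibly.
#' @export
write_metrics <- function(m, path) {
  doc <- m[c("tp", "fp", "fn", "tn", "accuracy", "precision", "recall",
             "auc_roc", "auc_pr", "n", "threshold")]
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (nrow(m$roc)) {
    data.table::fwrite(m$roc, sub("\\.json$", "_roc.csv", path))
    data.table::fwrite(m$pr, sub("\\.json$", "_pr.csv", path))
  }
  invisible(path)
}
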