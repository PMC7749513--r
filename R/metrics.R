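# Accuracy metrics: confusion matrix, per-class precision/recall/f-score,
# ROC/AUC over the pooled held-out NoGo probabilities.

#' Compute classification metrics
#'
#' Builds the confusion matrix (rows = predicted, columns = true, reported
#' both as counts and as proportions of the total), the pooled error rate
#' with its binomial standard error, per-class precision / recall /
#' f-score, and (when scores are given) the ROC curve and trapezoid AUC of
#' the NoGo probability.
#'
#' @param pred Predicted classes (factor Go/NoGo), or a 2x2 confusion count
#'   matrix with rows = predicted, columns = true, in Go/NoGo order.
#' @param truth True classes (ignored when `pred` is a matrix).
#' @param scores Optional pooled `f_nogo` scores for the ROC curve.
#' @return A `cv_metrics` list.
#' @export
compute_metrics <- function(pred, truth = NULL, scores = NULL) {
  if (is.matrix(pred)) {
    counts <- pred
    dimnames(counts) <- list(pred = c("Go", "NoGo"), true = c("Go", "NoGo"))
  } else {
    pred <- factor(pred, levels = c("Go", "NoGo"))
    truth <- factor(truth, levels = c("Go", "NoGo"))
    if (length(unique(truth)) < 2) {
      stop(errorCondition("metrics need both classes in the truth labels",
                          class = c("ersplearn_single_class", "error")))
    }
    counts <- table(pred = pred, true = truth)
  }
  n <- sum(counts)
  prop <- counts / n
  acc <- sum(diag(counts)) / n
  err <- 1 - acc
  se <- sqrt(acc * (1 - acc) / n)
  cls <- function(k) {
    tp <- counts[k, k]
    precision <- tp / sum(counts[k, ])
    recall <- tp / sum(counts[, k])
    f <- 2 * precision * recall / (precision + recall)
    c(precision = unname(precision), recall = unname(recall), f = unname(f))
  }
  out <- list(confusion_counts = unclass(counts), confusion = unclass(prop),
              n = n, accuracy = acc, error = err, se = se,
              go = cls("Go"), nogo = cls("NoGo"))
  if (!is.null(scores) && !is.matrix(pred)) {
    roc <- pROC::roc(response = truth, predictor = scores, levels = c("Go", "NoGo"),
                     direction = "<", quiet = TRUE)
    out$auc <- as.numeric(pROC::auc(roc))
    out$roc <- data.frame(fpr = 1 - roc$specificities, tpr = roc$sensitivities)
    out$roc <- out$roc[order(out$roc$fpr, out$roc$tpr), ]
  }
  structure(out, class = "cv_metrics")
}

#' @export
print.cv_metrics <- function(x, ...) {
  cat(sprintf("<cv_metrics> n = %d, accuracy = %.3f (se %.3f), error = %.3f%s\n",
              x$n, x$accuracy, x$se, x$error,
              if (!is.null(x$auc)) sprintf(", AUC = %.3f", x$auc) else ""))
  invisible(x)
}
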