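#' Multiclass confusion matrix
#'
#' @param truth,predicted equal-length integer label vectors with values in
#'   `1..n_classes`.
#' @param n_classes number of activity classes A.
#' @return A x A count matrix, rows = true class, columns = predicted class.
#' @export
confusion_matrix <- function(truth, predicted, n_classes) {
  if (length(truth) != length(predicted))
    stopf("confusion_matrix: label vectors differ in length (%d vs %d)",
          length(truth), length(predicted))
  if (any(c(truth, predicted) < 1) || any(c(truth, predicted) > n_classes))
    stopf("confusion_matrix: labels must lie in 1..%d", n_classes)
  m <- table(factor(truth, levels = seq_len(n_classes)),
             factor(predicted, levels = seq_len(n_classes)))
  unclass(unname(m))
}

#' Weighted precision, recall, accuracy and F1 from a confusion matrix
#'
#' Per class j, precision and recall come from one-vs-rest counts
#' (`P_j = TP_j / (TP_j + FP_j)`, `R_j = TP_j / (TP_j + FN_j)`); a class with
#' zero predicted (resp. true) positives gets `P_j = 0` (resp. `R_j = 0`)
#' with a warning so the weighted means stay defined. The weighted means use
#' the true class supports `N_j` as weights; accuracy is
#' `sum(TP_j) / sum(N_j)` and F1 the harmonic mean of the weighted precision
#' and recall.
#'
#' @param confusion A x A count matrix from [confusion_matrix()].
#' @return object of class `metrics_report`: list with `confusion`,
#'   `per_class` (data.frame precision/recall/support), `accuracy`,
#'   `precision`, `recall`, `f1`.
#' @export
weighted_metrics <- function(confusion) {
  total <- sum(confusion)
  if (total == 0) stopf("weighted_metrics: empty confusion matrix")
  tp <- diag(confusion)
  nj <- rowSums(confusion)  # true supports
  pp <- colSums(confusion)  # predicted positives
  p <- ifelse(pp > 0, tp / pp, 0)
  r <- ifelse(nj > 0, tp / nj, 0)
  if (any(pp == 0 & nj > 0))
    warnf("weighted_metrics: %d class(es) never predicted; precision set to 0",
          sum(pp == 0 & nj > 0))
  pbar <- sum(nj * p) / sum(nj)
  rbar <- sum(nj * r) / sum(nj)
  f1 <- if (pbar + rbar > 0) 2 * pbar * rbar / (pbar + rbar) else 0
  structure(list(
    confusion = confusion,
    per_class = data.frame(precision = p, recall = r, support = nj),
    accuracy = sum(tp) / total,
    precision = pbar, recall = rbar, f1 = f1),
    class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("<metrics_report> %d classes, %d targets\n",
              nrow(x$confusion), sum(x$confusion)))
  cat(sprintf("  accuracy %.*f | weighted precision %.*f | weighted recall %.*f | weighted F1 %.*f\n",
              digits, x$accuracy, digits, x$precision, digits, x$recall,
              digits, x$f1))
  invisible(x)
}

#' Evaluate predicted against true labels
#'
#' Convenience wrapper: confusion matrix plus weighted metrics in one call.
#'
#' @inheritParams confusion_matrix
#' @return a `metrics_report`.
#' @export
evaluate_labels <- function(truth, predicted, n_classes = max(truth, predicted)) {
  weighted_metrics(confusion_matrix(truth, predicted, n_classes))
}
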