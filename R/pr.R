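#' Precision-recall curve and average precision for binary scores
#'
#' Threshold sweep over the distinct scores (higher score = more
#' confidently positive); the area is the step-interpolated average
#' precision `sum (R_i - R_{i-1}) * P_i`.
#'
#' @param scores Numeric score vector.
#' @param labels 0/1 vector of true classes.
#' @return List of class `seqmend_pr`: `thresholds`, `precision`,
#'   `recall`, `auprc`.
#' @export
pr_curve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  P <- sum(labels == 1)
  if (P == 0) stop(errorCondition("no positive labels: PR curve undefined",
                                  class = c("seqmend_pr_undefined", "error")))
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  last <- cumsum(rle(s)$lengths)   # group ends at distinct thresholds
  tp <- cumsum(y == 1)[last]
  n_pred <- last
  prec <- tp / n_pred
  rec <- tp / P
  ap <- sum(diff(c(0, rec)) * prec)
  structure(list(thresholds = s[last], precision = prec, recall = rec,
                 auprc = ap), class = "seqmend_pr")
}

#' @export
print.seqmend_pr <- function(x, ...) {
  cat(sprintf("<PR curve: %d thresholds, AUPRC %.4f>\n",
              length(x$thresholds), x$auprc))
  invisible(x)
}

#' Precision and recall at a fixed score threshold
#'
#' Predicted positive iff `score > threshold` (strict, matching the
#' bin-change counting convention).
#'
#' @inheritParams pr_curve
#' @param threshold Score cutoff.
#' @return Named numeric vector `c(precision, recall)`.
#' @export
pr_at_threshold <- function(scores, labels, threshold) {
  pred <- scores > threshold
  tp <- sum(pred & labels == 1)
  c(precision = if (any(pred)) tp / sum(pred) else NA_real_,
    recall = tp / sum(labels == 1))
}

#' Change precision-recall curve for bin reclassification
#'
#' A "change" event is a bin whose initial candidate label differs from
#' the true label; the scores are change probabilities
#' ([change_probs()]). With no true change events the curve is undefined
#' and an error of class `seqmend_no_changes` is signalled.
#'
#' @param predictions Predicted bin probabilities (vector/matrix).
#' @param initial_labels 0/1 initial candidate labels, same shape.
#' @param true_labels 0/1 ground-truth labels, same shape.
#' @return `seqmend_pr` list as [pr_curve()].
#' @export
change_pr_curve <- function(predictions, initial_labels, true_labels) {
  stopifnot(length(predictions) == length(initial_labels),
            length(predictions) == length(true_labels))
  events <- as.numeric(initial_labels != true_labels)
  if (sum(events) == 0)
    stop(errorCondition("no change events: change-PR curve undefined",
                        class = c("seqmend_no_changes", "error")))
  cp <- change_probs(as.numeric(predictions), as.numeric(initial_labels))
  pr_curve(cp, events)
}
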