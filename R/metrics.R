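#' Confusion counts at a decision threshold
#'
#' A sample is predicted positive iff its score is greater than or equal to
#' the threshold.
#'
#' @param scores Numeric vector of positive-class scores.
#' @param labels Integer 0/1 labels.
#' @param threshold Decision threshold.
#' @return List of class `confusion_counts`: `TP`, `TN`, `FP`, `FN`,
#'   `N_total`.
#' @export
confusion_at <- function(scores, labels, threshold) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  structure(list(TP = sum(pred == 1L & labels == 1L),
                 TN = sum(pred == 0L & labels == 0L),
                 FP = sum(pred == 1L & labels == 0L),
                 FN = sum(pred == 0L & labels == 1L),
                 N_total = length(labels)),
            class = "confusion_counts")
}

.safe_ratio <- function(num, den) {
  if (den == 0) structure(0, flagged = TRUE) else num / den
}

#' Threshold-dependent classification metrics
#'
#' Accuracy, sensitivity (recall), specificity, precision, F-score and the
#' Matthews correlation coefficient from a confusion table. Any metric whose
#' denominator is zero is reported as 0 and listed in the `flagged`
#' attribute rather than propagating NaN.
#'
#' @param counts A `confusion_counts` object (or list with TP/TN/FP/FN).
#' @return Named numeric vector with attribute `flagged` naming the
#'   degenerate metrics (if any).
#' @export
classification_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  N <- TP + TN + FP + FN
  if (N < 1) stop("empty confusion table")
  vals <- list(
    accuracy = .safe_ratio(TP + TN, N),
    sensitivity = .safe_ratio(TP, TP + FN),
    specificity = .safe_ratio(TN, TN + FP),
    precision = .safe_ratio(TP, TP + FP)
  )
  pr <- as.numeric(vals$precision); rc <- as.numeric(vals$sensitivity)
  vals$f_score <- .safe_ratio(2 * pr * rc, pr + rc)
  mcc_den <- sqrt(prod(c(TP + FN, TP + FP, TN + FP, TN + FN)))
  vals$mcc <- if (mcc_den == 0) structure(0, flagged = TRUE) else
    (TP * TN - FP * FN) / mcc_den
  flagged <- names(vals)[vapply(vals, function(v)
    isTRUE(attr(v, "flagged")), logical(1))]
  out <- vapply(vals, as.numeric, numeric(1))
  attr(out, "flagged") <- flagged
  out
}

## candidate thresholds: midpoints between adjacent unique scores plus
## sentinels below and above every score
.candidate_thresholds <- function(scores) {
  u <- sort(unique(scores))
  if (length(u) == 1) c(u[1] - 1, u[1] + 1)
  else c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over the unique scores (ties grouped) and
#' integrates the resulting TPR/FPR staircase by the trapezoidal rule.
#'
#' @param scores Positive-class scores.
#' @param labels Integer 0/1 labels; both classes must be present.
#' @return List with `curve` (data.frame: threshold, fpr, tpr) and `auc`.
#' @export
roc_and_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("ROC requires both classes")
  th <- .candidate_thresholds(scores)
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  tpr <- fpr <- numeric(length(th))
  for (i in seq_along(th)) {
    pred <- scores >= th[i]
    tpr[i] <- sum(pred & labels == 1L) / npos
    fpr[i] <- sum(pred & labels == 0L) / nneg
  }
  ord <- order(fpr, tpr)
  fo <- fpr[ord]; to <- tpr[ord]
  auc <- sum(diff(fo) * (to[-1] + to[-length(to)]) / 2)
  list(curve = data.frame(threshold = th, fpr = fpr, tpr = tpr), auc = auc)
}

#' Precision-recall curve
#'
#' Precision and recall at every candidate threshold; recall is
#' nonincreasing as the threshold rises. Precision at thresholds with no
#' predicted positives is reported as 0 (flagged convention of
#' [classification_metrics()]).
#'
#' @inheritParams roc_and_auc
#' @return data.frame with columns threshold, recall, precision.
#' @export
precision_recall_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  if (sum(labels == 1L) == 0) stop("precision-recall requires positives")
  th <- .candidate_thresholds(scores)
  out <- lapply(th, function(t) {
    m <- classification_metrics(confusion_at(scores, labels, t))
    data.frame(threshold = t, recall = m[["sensitivity"]],
               precision = m[["precision"]])
  })
  do.call(rbind, out)
}

#' Threshold maximizing the Matthews correlation coefficient
#'
#' Scans the candidate thresholds (midpoints between adjacent unique scores,
#' plus sentinels below and above all scores) and returns the one with
#' maximal MCC; ties break toward the smallest threshold.
#'
#' @inheritParams roc_and_auc
#' @return The selected threshold (numeric scalar) with attribute `mcc`.
#' @export
select_threshold_max_mcc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("MCC threshold requires both classes")
  th <- .candidate_thresholds(scores)
  mccs <- vapply(th, function(t)
    classification_metrics(confusion_at(scores, labels, t))[["mcc"]],
    numeric(1))
  best <- which.max(mccs)     # first maximum = smallest threshold
  structure(th[best], mcc = mccs[best])
}

#' Paired t-test on per-iteration metrics
#'
#' Two-sided paired t-test comparing a metric across bagging iterations of
#' two methods.
#'
#' @param metric_a,metric_b Equal-length numeric vectors (>= 2), one value
#'   per iteration.
#' @return The two-sided p-value.
#' @export
paired_ttest <- function(metric_a, metric_b) {
  stopifnot(length(metric_a) == length(metric_b), length(metric_a) >= 2)
  d <- metric_a - metric_b
  if (stats::sd(d) < .Machine$double.eps) {
    stop("degenerate paired t-test: differences have zero variance")
  }
  stats::t.test(metric_a, metric_b, paired = TRUE,
                alternative = "two.sided")$p.value
}
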