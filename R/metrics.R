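# Confusion-table metrics; threshold rule: score >= threshold is positive.
.confusion_metrics <- function(scores, labels, threshold) {
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1); fn <- sum(!pred & labels == 1)
  fp <- sum(pred & labels == 0); tn <- sum(!pred & labels == 0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  npv <- if (tn + fn > 0) tn / (tn + fn) else NA_real_
  acc <- (tp + tn) / length(labels)
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else NA_real_
  list(threshold = threshold, tp = tp, fn = fn, fp = fp, tn = tn,
       sensitivity = sens, precision = prec, accuracy = acc,
       specificity = spec, npv = npv, f1 = f1)
}

#' Operating-point metrics at a fixed sensitivity
#'
#' Chooses the largest score threshold achieving sensitivity at least
#' `target_sensitivity` (samples scoring at or above the threshold are
#' called positive) and reports the full confusion-table metric row:
#' achieved sensitivity, precision, accuracy, specificity, negative
#' predictive value, and F1.
#'
#' @param scores Predicted scores/probabilities.
#' @param labels Binary labels (both classes required).
#' @param target_sensitivity Target in (0, 1].
#' @return One-row data.frame with `target_sensitivity`, `threshold`,
#'   `sensitivity`, `precision`, `accuracy`, `specificity`, `npv`, `f1`,
#'   and the confusion counts.
#' @export
metrics_at_sensitivity <- function(scores, labels, target_sensitivity) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("labels contain a single class")
  if (target_sensitivity <= 0 || target_sensitivity > 1) {
    stop("target sensitivity must be in (0, 1]")
  }
  thr <- sort(unique(scores), decreasing = TRUE)
  pos <- sum(labels == 1)
  row <- NULL
  for (th in thr) {
    sens <- sum(scores >= th & labels == 1) / pos
    if (sens >= target_sensitivity) {
      row <- .confusion_metrics(scores, labels, th)
      break
    }
  }
  if (is.null(row)) row <- .confusion_metrics(scores, labels, min(scores))
  data.frame(target_sensitivity = target_sensitivity,
             threshold = row$threshold, sensitivity = row$sensitivity,
             precision = row$precision, accuracy = row$accuracy,
             specificity = row$specificity, npv = row$npv, f1 = row$f1,
             tp = row$tp, fn = row$fn, fp = row$fp, tn = row$tn)
}

#' Fixed-sensitivity metric table
#'
#' [metrics_at_sensitivity()] over a grid of targets (default the
#' standard grid 0.70--0.95).
#'
#' @param scores,labels As in [metrics_at_sensitivity()].
#' @param targets Sensitivity targets.
#' @return data.frame with one row per target.
#' @export
sensitivity_table <- function(scores, labels,
                              targets = c(0.70, 0.75, 0.80, 0.85, 0.90, 0.95)) {
  do.call(rbind, lapply(targets, function(t) {
    metrics_at_sensitivity(scores, labels, t)
  }))
}

#' ROC and precision-recall curves with areas
#'
#' AUROC by trapezoidal integration of the ROC curve over all distinct
#' score thresholds (equal scores grouped); AUPRC as average precision
#' (step-wise summation `sum_i (R_i - R_{i-1}) * P_i` over distinct
#' thresholds).
#'
#' @param scores Predicted scores.
#' @param labels Binary labels (both classes required).
#' @return List with `roc` (data.frame `threshold`, `fpr`, `tpr`), `auroc`,
#'   `pr` (data.frame `threshold`, `recall`, `precision`), `auprc`.
#' @export
roc_pr <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("labels contain a single class")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  P <- sum(y == 1); Ng <- sum(y == 0)
  # group tied scores
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  last <- !duplicated(grp, fromLast = TRUE)
  tp <- tp[last]; fp <- fp[last]; thr <- s[last]
  tpr <- c(0, tp / P); fpr <- c(0, fp / Ng)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  rec <- tp / P
  prec <- tp / (tp + fp)
  auprc <- sum(diff(c(0, rec)) * prec)
  list(roc = data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr),
       auroc = auroc,
       pr = data.frame(threshold = thr, recall = rec, precision = prec),
       auprc = auprc)
}
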