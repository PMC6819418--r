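#' Confusion counts at a score threshold
#'
#' Tallies true/false positives and negatives for binary labels against the
#' rule "call positive iff score >= threshold" (closed on the positive side;
#' the same convention is used throughout, including net benefit). The
#' positive class is label 1 (supine preferred).
#'
#' @param scores Numeric vector of model scores (probabilities or any
#'   monotone score).
#' @param labels Binary 0/1 vector, same length.
#' @param threshold Scalar threshold.
#' @return An object of class `confusion_counts`: list with integer `tp`,
#'   `fp`, `fn`, `tn`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold) {
  if (length(scores) == 0L) stop("empty input")
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  call_pos <- scores >= threshold
  confusion_counts(tp = sum(call_pos & labels == 1),
                   fp = sum(call_pos & labels == 0),
                   fn = sum(!call_pos & labels == 1),
                   tn = sum(!call_pos & labels == 0))
}

#' @rdname confusion_at_threshold
#' @param tp,fp,fn,tn Nonnegative counts.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be nonnegative integers")
  }
  if (sum(counts) == 0) stop("total count must be positive")
  counts <- as.integer(counts)
  structure(list(tp = counts[1], fp = counts[2], fn = counts[3], tn = counts[4]),
            class = "confusion_counts")
}

#' Basic classification measures from confusion counts
#'
#' Sensitivity, specificity, positive and negative predictive value, accuracy
#' and the Youden index (sensitivity + specificity - 1). Measures whose
#' denominator is zero (e.g. sensitivity with no positive patients) are
#' returned as `NA` rather than forced to 0.
#'
#' @param counts A [confusion_counts] object.
#' @return Named list: `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy`, `youden`.
#' @export
basic_measures <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  with(counts, {
    sens <- safe_div(tp, tp + fn)
    spec <- safe_div(tn, tn + fp)
    list(sensitivity = sens,
         specificity = spec,
         ppv = safe_div(tp, tp + fp),
         npv = safe_div(tn, tn + fn),
         accuracy = (tp + tn) / (tp + fp + fn + tn),
         youden = sens + spec - 1)
  })
}

#' ROC curve, AUC and DeLong confidence interval
#'
#' Plots sensitivity against 1 - specificity over all score thresholds. The
#' area under the curve is computed as the tie-corrected Mann-Whitney
#' statistic (concordant positive-negative pairs plus half the tied pairs,
#' over all pairs) via midranks, and its 95% confidence interval by DeLong's
#' placement-value method, truncated to `[0, 1]`.
#'
#' @inheritParams confusion_at_threshold
#' @param conf_level Confidence level of the AUC interval (default 0.95).
#' @return An object of class `roc_result`: list with `points` (data frame
#'   `fpr`, `tpr`, `threshold`), `auc` and `ci95` (length-2 vector).
#' @export
roc_curve_auc <- function(scores, labels, conf_level = 0.95) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")

  # curve points: one threshold per distinct score, plus call-all/call-none
  thr <- sort(unique(scores), decreasing = TRUE)
  points <- t(vapply(c(Inf, thr), function(t) {
    cc <- confusion_at_threshold(scores, labels, t)
    c(fpr = cc$fp / n0, tpr = cc$tp / n1, threshold = t)
  }, numeric(3)))
  points <- as.data.frame(points)

  # tie-corrected Mann-Whitney AUC via midranks
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)

  # DeLong: placement values from midranks within and across classes
  rx <- rank(scores[labels == 1])
  ry <- rank(scores[labels == 0])
  v10 <- (r[labels == 1] - rx) / n0       # per-positive placements
  v01 <- 1 - (r[labels == 0] - ry) / n1   # per-negative placements
  var_auc <- stats::var(v10) / n1 + stats::var(v01) / n0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- auc + c(-1, 1) * z * sqrt(max(var_auc, 0))
  ci <- pmin(pmax(ci, 0), 1)

  structure(list(points = points, auc = auc, ci95 = ci,
                 n_pos = n1, n_neg = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%.0f%% CI %.3f-%.3f), %d positives / %d negatives\n",
              x$auc, 95, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Optimal cut-point by the Youden index
#'
#' Exhaustive scan over all midpoints between adjacent distinct scores, plus
#' -Inf/+Inf sentinels (call-all and call-none), returning the threshold
#' maximizing the Youden index. Ties between thresholds are broken toward
#' the higher threshold, i.e. toward higher specificity.
#'
#' @inheritParams confusion_at_threshold
#' @return List with `threshold`, the `measures` (from [basic_measures()])
#'   and `counts` at that threshold.
#' @export
youden_optimal_cutpoint <- function(scores, labels) {
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  s <- sort(unique(scores))
  candidates <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  youdens <- vapply(candidates, function(t) {
    basic_measures(confusion_at_threshold(scores, labels, t))$youden
  }, numeric(1))
  # ties toward the larger threshold (higher specificity)
  best <- max(which(youdens >= max(youdens) - 1e-12))
  cc <- confusion_at_threshold(scores, labels, candidates[best])
  list(threshold = candidates[best],
       measures = basic_measures(cc),
       counts = cc)
}

#' Brier score of a probability forecast
#'
#' Mean squared distance between predicted probabilities and binary
#' outcomes; lower is better. With weights, the weighted mean
#' `sum(w * (p - o)^2) / sum(w)` is returned; equal weights reproduce the
#' unweighted score exactly. Probabilities refer to class 1 (supine
#' preferred) — pass the same orientation as the labels.
#'
#' @param probs Predicted probabilities in `[0, 1]`.
#' @param outcomes Binary 0/1 outcomes.
#' @param weights Optional nonnegative weights, not all zero (e.g. the
#'   absolute dose difference, to weight errors by their clinical cost).
#' @return Scalar score in `[0, 1]`.
#' @export
brier_score <- function(probs, outcomes, weights = NULL) {
  if (length(probs) != length(outcomes)) stop("probs and outcomes differ in length")
  if (any(probs < 0 | probs > 1)) stop("probs must lie in [0, 1]")
  if (!all(outcomes %in% c(0, 1))) stop("outcomes must be 0/1")
  sq <- (probs - outcomes)^2
  if (is.null(weights)) return(mean(sq))
  if (length(weights) != length(probs)) stop("weights length mismatch")
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (sum(weights) == 0) stop("weights must not all be zero")
  if (diff(range(weights)) == 0) return(mean(sq))  # exact, not just up to rounding
  sum(weights * sq) / sum(weights)
}
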