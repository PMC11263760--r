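# Discrimination metrics: AUROC (midrank Mann-Whitney and trapezoid),
# step-wise AUPRC, thresholded confusion-matrix metrics, and a stratified
# percentile bootstrap CI for the AUROC.

#' Area under the ROC curve
#'
#' The default `"rank"` method is the Mann-Whitney formulation: the fraction
#' of (positive, negative) score pairs ranked correctly, ties counted 1/2,
#' computed via midranks. `"trapezoid"` integrates the empirical ROC curve;
#' the two agree to numerical precision.
#'
#' @param scores Numeric scores, higher = more case-like.
#' @param labels Binary labels (1 = positive).
#' @param method `"rank"` or `"trapezoid"`.
#' @return Scalar AUROC in [0, 1].
#' @export
auroc <- function(scores, labels, method = c("rank", "trapezoid")) {
  method <- match.arg(method)
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop_contract("both classes required for AUROC")
  if (method == "rank") {
    r <- rank(scores, ties.method = "average")
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else {
    ord <- order(scores, decreasing = TRUE)
    y <- labels[ord]; s <- scores[ord]
    # step only at distinct thresholds
    grp <- cumsum(!duplicated(s))
    tp <- cumsum(y); fp <- cumsum(1 - y)
    last <- !duplicated(grp, fromLast = TRUE)
    tpr <- c(0, tp[last] / n1); fpr <- c(0, fp[last] / n0)
    sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  }
}

#' Area under the precision-recall curve
#'
#' Step-wise area: scores are scanned in decreasing order and the area is
#' accumulated as `sum((R_k - R_{k-1}) * P_k)` at each distinct threshold
#' (average-precision rule; tied scores are grouped).
#'
#' @inheritParams auroc
#' @return Scalar AUPRC in [0, 1].
#' @export
auprc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  if (n1 == 0L) stop_contract("at least one positive required for AUPRC")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); pred <- seq_along(y)
  last <- !duplicated(grp, fromLast = TRUE)
  prec <- tp[last] / pred[last]
  rec <- tp[last] / n1
  sum(diff(c(0, rec)) * prec)
}

#' Accuracy, precision and F1 at a threshold
#'
#' Predicted positive iff `score >= threshold`. Precision with zero
#' predicted positives is 0 with a warning; F1 with an empty
#' precision+recall sum is 0.
#'
#' @inheritParams auroc
#' @param threshold Decision threshold.
#' @return Named vector `accuracy`, `precision`, `f1`.
#' @export
thresholded_metrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.numeric(labels)
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  acc <- (tp + tn) / length(labels)
  if (tp + fp == 0L) {
    warning("no predicted positives; precision set to 0")
    prec <- 0
  } else prec <- tp / (tp + fp)
  rec <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  c(accuracy = acc, precision = prec, f1 = f1)
}

#' Stratified percentile bootstrap CI for the AUROC
#'
#' Resamples positives and negatives separately (so every resample contains
#' both classes) and returns the (2.5, 97.5) percentiles of the resampled
#' AUROC distribution.
#'
#' @inheritParams auroc
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Seed for resampling.
#' @return `c(low, high)`.
#' @export
auroc_ci <- function(scores, labels, n_boot = 1000L, seed = 1L) {
  labels <- as.numeric(labels)
  if (n_boot < 100L) stop_contract("n_boot must be at least 100")
  i1 <- which(labels == 1); i0 <- which(labels == 0)
  if (!length(i1) || !length(i0)) stop_contract("both classes required")
  set.seed(seed)
  stat <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    s1 <- sample(i1, replace = TRUE)
    s0 <- sample(i0, replace = TRUE)
    idx <- c(s1, s0)
    stat[b] <- auroc(scores[idx], labels[idx])
  }
  qs <- stats::quantile(stat, c(0.025, 0.975), names = FALSE)
  c(low = qs[1], high = qs[2])
}

#' Full metrics report for one model
#'
#' @inheritParams auroc
#' @param threshold Decision threshold for class metrics.
#' @param n_boot Bootstrap resamples for the AUROC CI.
#' @param seed Bootstrap seed.
#' @return A `metrics_report` list: `auroc`, `auroc_ci`, `auprc`,
#'   `accuracy`, `precision`, `f1`, `n`, `n_pos`, `threshold`.
#' @export
metrics_report <- function(scores, labels, threshold = 0.5, n_boot = 1000L,
                           seed = 1L) {
  tm <- thresholded_metrics(scores, labels, threshold)
  structure(list(
    auroc = auroc(scores, labels),
    auroc_ci = auroc_ci(scores, labels, n_boot = n_boot, seed = seed),
    auprc = auprc(scores, labels),
    accuracy = tm[["accuracy"]], precision = tm[["precision"]],
    f1 = tm[["f1"]], n = length(labels), n_pos = sum(labels == 1),
    threshold = threshold), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("AUROC %.3f [%.3f, %.3f]  AUPRC %.3f  acc %.3f  prec %.3f  F1 %.3f  (n=%d, pos=%d)\n",
              x$auroc, x$auroc_ci[["low"]], x$auroc_ci[["high"]], x$auprc,
              x$accuracy, x$precision, x$f1, x$n, x$n_pos))
  invisible(x)
}
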