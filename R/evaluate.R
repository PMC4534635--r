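## Accuracy of crowd calls against a reference scorer.

#' Confusion counts from published-style summary counts
#'
#' Rebuilds the full 2x2 table from the four numbers typically printed in a
#' concordance report: the total, the number of reference positives, and the
#' two discordant counts.
#'
#' @param n_total number of paired calls.
#' @param n_ref_positive reference-positive count.
#' @param n_false_positive calls positive / reference negative.
#' @param n_false_negative calls negative / reference positive.
#' @return object of class `confusion` with fields `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_from_counts <- function(n_total, n_ref_positive,
                                  n_false_positive, n_false_negative) {
  n_total <- check_count(n_total, "n_total", 1L)
  n_ref_positive <- check_count(n_ref_positive, "n_ref_positive", 0L)
  n_false_positive <- check_count(n_false_positive, "n_false_positive", 0L)
  n_false_negative <- check_count(n_false_negative, "n_false_negative", 0L)
  if (n_ref_positive > n_total)
    stop_invalid("n_ref_positive exceeds n_total")
  if (n_false_negative > n_ref_positive)
    stop_invalid("n_false_negative exceeds n_ref_positive")
  if (n_false_positive > n_total - n_ref_positive)
    stop_invalid("n_false_positive exceeds the reference-negative count")
  structure(list(tp = n_ref_positive - n_false_negative,
                 fp = n_false_positive,
                 tn = (n_total - n_ref_positive) - n_false_positive,
                 fn = n_false_negative),
            class = "confusion")
}

#' Confusion counts from paired calls
#'
#' @param ref,call logical vectors of equal length (reference and crowd).
#' @return object of class `confusion`.
#' @export
confusion_from_calls <- function(ref, call) {
  if (length(ref) != length(call)) stop_invalid("length mismatch")
  structure(list(tp = sum(ref & call), fp = sum(!ref & call),
                 tn = sum(!ref & !call), fn = sum(ref & !call)),
            class = "confusion")
}

#' Rates derived from a confusion table
#'
#' @param x a `confusion` object.
#' @return list: `sensitivity`, `specificity`, `agreement` (overall
#'   accuracy), `ppv`, `npv`, all as proportions in `[0, 1]`.
#' @export
confusion_metrics <- function(x) {
  stopifnot(inherits(x, "confusion"))
  n <- x$tp + x$fp + x$tn + x$fn
  if (n == 0L) stop_invalid("empty confusion table")
  list(sensitivity = x$tp / (x$tp + x$fn),
       specificity = x$tn / (x$tn + x$fp),
       agreement = (x$tp + x$tn) / n,
       ppv = x$tp / (x$tp + x$fp),
       npv = x$tn / (x$tn + x$fn))
}

#' @export
print.confusion <- function(x, ...) {
  m <- confusion_metrics(x)
  cat(sprintf("confusion: tp=%d fp=%d tn=%d fn=%d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity %.1f%%  specificity %.1f%%  agreement %.1f%%\n",
              100 * m$sensitivity, 100 * m$specificity, 100 * m$agreement))
  invisible(x)
}

#' ROC curve and area under the curve
#'
#' The AUC is the Mann--Whitney probability that a random positive scores
#' above a random negative, with ties counted 1/2 (computed from mid-ranks).
#' The curve is evaluated at thresholds placed midway between consecutive
#' distinct scores (plus sentinels below and above the range), so trapezoidal
#' integration of the returned curve reproduces the rank-based AUC exactly.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels logical (or 0/1) reference labels; both classes required.
#' @return list of class `roc`: `auc`, `curve` (data frame `threshold`,
#'   `fpr`, `tpr`), `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop_invalid("length mismatch")
  if (anyNA(scores) || anyNA(labels)) stop_invalid("NA in scores or labels")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop_invalid("roc_auc needs both classes present")
  r <- rank(scores)  # mid-ranks
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  s <- sort(unique(scores))
  thr <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
           s[length(s)] + 1)
  tpr <- vapply(thr, function(t) sum(scores[labels] >= t) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores[!labels] >= t) / n_neg, 0)
  structure(list(auc = auc,
                 curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc")
}

#' @export
print.roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (%d positive, %d negative)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Trapezoidal area under a ROC curve
#'
#' @param roc a `roc` object (or any list with a `curve` data frame).
#' @return area in `[0, 1]`; equals the Mann--Whitney AUC.
#' @export
roc_auc_trapezoid <- function(roc) {
  cv <- roc$curve[order(roc$curve$fpr, roc$curve$tpr), ]
  sum(diff(cv$fpr) * (head(cv$tpr, -1) + cv$tpr[-1]) / 2)
}

#' Confidence interval for an AUC
#'
#' DeLong's placement-based variance by default; a seeded stratified
#' bootstrap as an alternative.
#'
#' @inheritParams roc_auc
#' @param method `"delong"` or `"bootstrap"`.
#' @param level confidence level.
#' @param B bootstrap replicates.
#' @param seed bootstrap seed.
#' @return list `auc`, `se`, `ci` (length-2), `method`.
#' @export
auc_ci <- function(scores, labels, method = c("delong", "bootstrap"),
                   level = 0.95, B = 2000L, seed = 1L) {
  method <- match.arg(method)
  labels <- as.logical(labels)
  r <- roc_auc(scores, labels)
  z <- qnorm(1 - (1 - level) / 2)
  if (method == "delong") {
    xs <- scores[labels]; ys <- scores[!labels]
    # placements: V10_i = P(X_i > Y) + P(X_i = Y)/2 and symmetrically
    v10 <- vapply(xs, function(x) mean((x > ys) + 0.5 * (x == ys)), 0)
    v01 <- vapply(ys, function(y) mean((xs > y) + 0.5 * (xs == y)), 0)
    se <- sqrt(var(v10) / length(xs) + var(v01) / length(ys))
  } else {
    set.seed(seed)
    ip <- which(labels); ineg <- which(!labels)
    reps <- vapply(seq_len(B), function(b) {
      i <- c(sample(ip, replace = TRUE), sample(ineg, replace = TRUE))
      roc_auc(scores[i], labels[i])$auc
    }, 0)
    se <- sd(reps)
  }
  list(auc = r$auc, se = se,
       ci = clip(c(r$auc - z * se, r$auc + z * se), 0, 1),
       method = method)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties); delegates to
#' [stats::cor()] with `method = "spearman"` after validating the input.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return value in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("length mismatch")
  if (length(x) < 3L) stop_invalid("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop_invalid("spearman_rho undefined for constant input")
  cor(x, y, method = "spearman")
}

#' Mean paired difference with a normal-approximation interval
#'
#' Summarises systematic offset between a reference scorer and the crowd as
#' mean(reference - crowd) with a 95% normal CI.
#'
#' @param ref_scores,crowd_scores paired numeric vectors.
#' @param level confidence level.
#' @return list `mean`, `ci` (length-2), `n`.
#' @export
mean_difference <- function(ref_scores, crowd_scores, level = 0.95) {
  if (length(ref_scores) != length(crowd_scores))
    stop_invalid("length mismatch")
  d <- ref_scores - crowd_scores
  n <- length(d)
  se <- if (n > 1) sd(d) / sqrt(n) else 0
  z <- qnorm(1 - (1 - level) / 2)
  list(mean = mean(d), ci = mean(d) + c(-1, 1) * z * se, n = n)
}
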