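#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) form of the AUROC: the probability that a random
#' positive outscores a random negative, ties counted one half. Equivalent to
#' the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric predicted scores (higher = more PD-like).
#' @param labels Factor with levels `control`, `PD`, or logical/0-1 vector of
#'   positives.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  pos <- as_positive(labels)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    pdb_stop("input_error", "AUROC needs both classes present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_positive <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    as.character(labels) == "PD"
  } else {
    as.logical(labels)
  }
}

#' ROC curve points
#'
#' Empirical ROC curve: one point per distinct score threshold, plus the
#' (0,0) and (1,1) endpoints, ordered by increasing false-positive rate.
#'
#' @inheritParams auroc
#' @return `data.frame` with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  pos <- as_positive(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  p <- pos[ord]
  keep <- c(s[-length(s)] != s[-1L], TRUE) # last index of each tied block
  tpr <- cumsum(p)[keep] / sum(pos)
  fpr <- cumsum(!p)[keep] / sum(!pos)
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, fpr), tpr = c(0, tpr))
}

#' Stratified bootstrap confidence interval for the AUROC
#'
#' Resamples positives and negatives independently with replacement and
#' returns percentile bounds for the AUROC.
#'
#' @inheritParams auroc
#' @param reps Bootstrap replicates (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Seed for the resampling.
#' @return Named numeric `c(lower, upper)`.
#' @export
auroc_ci <- function(scores, labels, reps = 2000L, level = 0.95, seed = 1L) {
  pos <- as_positive(labels)
  ip <- which(pos)
  im <- which(!pos)
  stats <- with_seed(seed, {
    vapply(seq_len(reps), function(b) {
      bi <- c(sample(ip, length(ip), replace = TRUE),
              sample(im, length(im), replace = TRUE))
      auroc(scores[bi], pos[bi])
    }, numeric(1))
  })
  a <- (1 - level) / 2
  stats::quantile(stats, c(a, 1 - a), names = FALSE)
}

#' Threshold classification metrics
#'
#' Accuracy, precision, recall and F1 at a fixed predicted-probability
#' cutoff (default 0.5), with PD as the positive class. Precision is NA when
#' nothing is predicted positive; F1 is NA when precision or recall is.
#'
#' @inheritParams auroc
#' @param cutoff Score cutoff (default 0.5).
#' @return Named list `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(scores, labels, cutoff = 0.5) {
  pos <- as_positive(labels)
  pred <- scores >= cutoff
  tp <- sum(pred & pos)
  fp <- sum(pred & !pos)
  fn <- sum(!pred & pos)
  tn <- sum(!pred & !pos)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  list(accuracy = (tp + tn) / length(pos),
       precision = precision, recall = recall, f1 = f1)
}
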