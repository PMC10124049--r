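#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney pair statistic: the probability that a random
#' positive outranks a random negative, with ties counted as 1/2. Equivalent
#' to trapezoidal integration of the ROC curve.
#'
#' @param scores Numeric predicted scores (higher = more likely positive).
#' @param labels 0/1 outcome labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- check_labels(scores, labels, need_both = TRUE)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  r <- rank(scores)  # midranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-interpolated area (average precision): the sum over distinct score
#' thresholds of precision times the recall increment. For an uninformative
#' classifier this tends to the positive-class prevalence.
#'
#' @inheritParams auroc
#' @return AUPRC in `(0, 1]`.
#' @export
auprc <- function(scores, labels) {
  labels <- check_labels(scores, labels, need_both = TRUE)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab)
  n_pred <- seq_along(lab)
  # evaluate at the last index of each tied score block
  last <- cumsum(rle(sc)$lengths)
  prec <- tp[last] / n_pred[last]
  rec <- tp[last] / sum(lab)
  sum(diff(c(0, rec)) * prec)
}

#' Brier score
#'
#' Mean squared difference between predicted probability and the binary
#' outcome; lower is better calibrated.
#'
#' @inheritParams auroc
#' @return Brier score in `[0, 1]`.
#' @export
brier <- function(scores, labels) {
  labels <- check_labels(scores, labels, need_both = FALSE)
  mean((scores - labels)^2)
}

#' Youden-index decision threshold
#'
#' Returns the candidate threshold maximizing `J = sensitivity +
#' specificity - 1`, where a score greater than or equal to the threshold
#' predicts the positive class. Candidates are the distinct observed scores;
#' ties in `J` resolve to the smallest threshold.
#'
#' @inheritParams auroc
#' @return Scalar threshold.
#' @export
#' @examples
#' youden_threshold(c(.1, .2, .6, .9), c(0, 0, 1, 1))  # 0.6
youden_threshold <- function(scores, labels) {
  labels <- check_labels(scores, labels, need_both = TRUE)
  u <- sort(unique(scores))
  idx <- match(scores, u)
  f1 <- tabulate(idx[labels == 1], nbins = length(u))
  f0 <- tabulate(idx[labels == 0], nbins = length(u))
  n1 <- sum(f1)
  n0 <- sum(f0)
  # at threshold u[k], positives are scores >= u[k]; J scaled by n1*n0 keeps
  # the comparison in exact integer arithmetic, so ties break reproducibly
  tp <- rev(cumsum(rev(f1)))
  fp <- rev(cumsum(rev(f0)))
  j_scaled <- tp * n0 - fp * n1
  u[which.max(j_scaled)]  # first maximum = smallest optimizing threshold
}

#' Binarize scores into Alive/Dead votes
#'
#' Scores at or above the threshold vote `"Dead"`, below it `"Alive"`.
#'
#' @param scores Numeric scores in `[0, 1]`.
#' @param threshold Decision threshold in `[0, 1]`.
#' @return Character vector of `"Alive"`/`"Dead"` votes.
#' @export
binarize <- function(scores, threshold) {
  if (!is_scalar_number(threshold) || threshold < 0 || threshold > 1) {
    stopf("threshold must be a scalar in [0, 1]")
  }
  ifelse(scores >= threshold, "Dead", "Alive")
}

check_labels <- function(scores, labels, need_both) {
  if (length(scores) != length(labels)) {
    stopf("scores and labels must have equal length")
  }
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.integer(as.character(labels) == "dead")
  }
  if (!all(labels %in% c(0, 1))) stopf("labels must be 0/1 (or alive/dead)")
  if (need_both && (all(labels == 0) || all(labels == 1))) {
    stopf("both outcome classes must be present")
  }
  labels
}
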