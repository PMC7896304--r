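#' Rank-based AUC
#'
#' Area under the ROC curve computed from ranks (Mann-Whitney form), with
#' tied scores counted half: the probability that a random presence outranks
#' a random absence.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1, logical, or `"presence"` strings).
#' @return AUC in `[0, 1]`.
#' @examples
#' evaluate_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
#' @export
evaluate_auc <- function(scores, labels) {
  y <- as_binary_label(labels)
  if (length(scores) != length(y)) abort("scores/labels length mismatch.")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    abort("AUC is undefined when only one class is present.")
  }
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity-plus-specificity maximising threshold
#'
#' Scans the observed scores as candidate thresholds (classifying
#' `score >= threshold` as presence) and returns the threshold maximising
#' sensitivity + specificity (the Youden-type rule). Exact ties are broken
#' by the lower threshold, favouring sensitivity.
#'
#' @inheritParams evaluate_auc
#' @return The selected threshold (one of the observed scores).
#' @export
select_threshold <- function(scores, labels) {
  y <- as_binary_label(labels)
  if (length(scores) != length(y)) abort("scores/labels length mismatch.")
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    abort("Threshold is undefined when only one class is present.")
  }
  # descending sweep with cumulative counts: at threshold t,
  # sens = P(score >= t | y = 1), spec = P(score < t | y = 0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  yy <- y[ord]
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  pos_ge <- cumsum(yy)[last_of_tie]
  neg_ge <- cumsum(1 - yy)[last_of_tie]
  cand <- s[last_of_tie]
  j <- pos_ge / n1 + (n0 - neg_ge) / n0
  best <- j >= max(j) - 1e-12
  min(cand[best])
}

as_binary_label <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.integer(as.character(labels) == "presence")
  } else {
    as.integer(labels != 0)
  }
}
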