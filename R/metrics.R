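## Binary-classification metrics: Matthews correlation coefficient on a
## (possibly weighted) confusion matrix, ROC AUC by the Mann-Whitney
## identity and PR AUC in the average-precision convention.

#' Confusion counts
#'
#' Weighted confusion-matrix counts from binary truth and predictions.
#'
#' @param truth logical or 0/1 observed classes (1 = pathogenic).
#' @param pred logical or 0/1 predicted classes.
#' @param w instance weights (default 1).
#' @return list with TP, FP, TN, FN.
#' @export
confusion_counts <- function(truth, pred, w = rep(1, length(truth))) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  list(TP = sum(w[truth == 1L & pred == 1L]),
       FP = sum(w[truth == 0L & pred == 1L]),
       TN = sum(w[truth == 0L & pred == 0L]),
       FN = sum(w[truth == 1L & pred == 0L]))
}

#' Matthews correlation coefficient
#'
#' MCC = (TP.TN - FP.FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).  1 is a
#' perfect prediction, 0 no better than chance, -1 a perfectly inverted
#' prediction.  When any factor of the denominator is zero (e.g. every
#' instance predicted positive) the value is 0 by convention.
#'
#' @param counts list with TP, FP, TN, FN (weighted reals allowed), as
#'   from [confusion_counts()].
#' @return real in \[-1, 1\].
#' @export
mcc <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; tn <- counts$TN; fn <- counts$FN
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' ROC AUC
#'
#' Area under the receiver-operating-characteristic curve, computed by
#' the Mann-Whitney identity: the probability that a random positive
#' scores above a random negative, with ties counting one half.
#'
#' @param scores numeric prediction scores (higher = more pathogenic).
#' @param labels binary truth (1 = pathogenic).
#' @return real in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC AUC requires both classes")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' PR AUC (average precision)
#'
#' Area under the precision-recall step curve in the average-precision
#' convention: the sum over positives of precision at each recall step,
#' swept in descending score order with tied scores grouped.
#'
#' @inheritParams roc_auc
#' @return real in \[0, 1\].
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) stop("PR AUC requires at least one positive")
  ## group tied scores: all members of a tie share the group's precision
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(rep(1L, length(y)), grp, sum)
  tp_cum <- cumsum(tp_g)
  n_cum <- cumsum(n_g)
  prec <- tp_cum / n_cum
  sum(prec * tp_g) / n_pos
}
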