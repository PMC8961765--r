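## Repeated stratified k-fold cross-validation with the preprocessing
## filters (class balancing + supervised discretisation) fitted inside
## each training fold.  Per repeat the confusion matrix is pooled across
## folds before computing MCC; mean and SD are taken over repeats.

## Stratified fold assignment: within each class, a fresh shuffle is
## dealt round-robin into folds.  Returns an integer vector of fold ids.
stratified_folds <- function(y, k) {
  y <- as.integer(y)
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Repeated stratified k-fold cross-validation
#'
#' Evaluates a classification pipeline by repeated stratified k-fold
#' cross-validation with random subsampling: each repeat reshuffles the
#' fold assignment.  Class balancing and supervised MDL discretisation
#' are fitted on each training fold only and applied to its test fold,
#' so no information leaks from held-out labels.  Per repeat, the
#' confusion matrix is pooled over the k folds and summarised as one
#' MCC; ROC and PR AUC are computed from the pooled out-of-fold scores.
#' The report carries the mean and SD over repeats.
#'
#' @param X data.frame of features.
#' @param y binary labels (1 = pathogenic).
#' @param algorithm classifier id, see [fit_classifier()].
#' @param k folds (default 10); reduced with a warning when a class has
#'   fewer than `k` members.
#' @param repeats number of repeats (default 10).
#' @param seed integer seed controlling all shuffles.
#' @param balance apply class balancing inside each training fold.
#' @param discretize fit supervised discretisation inside each training
#'   fold.
#' @param global_discretize fit the discretisation once on the full data
#'   (labels included) before cross-validation.  This deliberately leaks
#'   held-out label information and exists only to demonstrate the bias;
#'   never use it for reported results.
#' @param ... passed to [fit_classifier()].
#' @return list of class `prospr_eval`: mcc_mean, mcc_sd, roc_auc,
#'   pr_auc, per_repeat (data.frame), algorithm_id, k, repeats.
#' @export
repeated_kfold_cv <- function(X, y, algorithm = "logitboost", k = 10L,
                              repeats = 10L, seed = 1L, balance = TRUE,
                              discretize = TRUE,
                              global_discretize = FALSE, ...) {
  y <- as.integer(y)
  n_min <- min(table(y))
  if (n_min < k) {
    warning("smallest class (", n_min, ") below k; reducing k")
    k <- max(2L, n_min)
  }
  disc_global <- if (global_discretize) fit_discretizer(X, y) else NULL
  per <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    folds <- with_seed(seed + r, stratified_folds(y, k))
    pooled_truth <- integer(0)
    pooled_pred <- integer(0)
    pooled_score <- numeric(0)
    for (f in seq_len(k)) {
      tr <- folds != f
      Xtr <- X[tr, , drop = FALSE]
      ytr <- y[tr]
      w <- if (balance) class_balance(ytr) else rep(1, sum(tr))
      disc <- if (global_discretize) disc_global
              else if (discretize) fit_discretizer(Xtr, ytr, w)
              else NULL
      Xtr2 <- if (is.null(disc)) Xtr else apply_discretizer(disc, Xtr)
      Xte2 <- if (is.null(disc)) X[!tr, , drop = FALSE]
              else apply_discretizer(disc, X[!tr, , drop = FALSE])
      model <- fit_classifier(Xtr2, ytr, w, algorithm = algorithm,
                              seed = seed + 1000L * r + f, ...)
      prob <- predict_proba(model, Xte2)
      pooled_truth <- c(pooled_truth, y[!tr])
      pooled_pred <- c(pooled_pred, as.integer(prob >= 0.5))
      pooled_score <- c(pooled_score, prob)
    }
    per[[r]] <- data.frame(
      repeat_id = r,
      mcc = mcc(confusion_counts(pooled_truth, pooled_pred)),
      roc_auc = roc_auc(pooled_score, pooled_truth),
      pr_auc = pr_auc(pooled_score, pooled_truth))
  }
  per <- do.call(rbind, per)
  structure(list(
    algorithm_id = algorithm, k = k, repeats = repeats,
    mcc_mean = mean(per$mcc), mcc_sd = stats::sd(per$mcc),
    roc_auc = mean(per$roc_auc), pr_auc = mean(per$pr_auc),
    per_repeat = per), class = "prospr_eval")
}

#' @export
print.prospr_eval <- function(x, ...) {
  cat(sprintf(
    "<prospr_eval> %s, %d x %d-fold CV: MCC %.3f (SD %.3f), ROC AUC %.3f, PR AUC %.3f\n",
    x$algorithm_id, x$repeats, x$k, x$mcc_mean,
    ifelse(is.na(x$mcc_sd), 0, x$mcc_sd), x$roc_auc, x$pr_auc))
  invisible(x)
}
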