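## End-to-end per-gene pipeline: annotation -> preprocessing ->
## algorithm choice -> minimal-feature selection -> final model and
## evaluation report; plus score-table evaluation and a reproducibility
## manifest.

#' Train a gene-specific variant classifier
#'
#' Full training pipeline for one gene: restrict to labelled variants,
#' choose the best of the three algorithms by repeated stratified k-fold
#' CV on MCC (class balancing and supervised discretisation fitted
#' inside each training fold), then greedily reduce to a minimal feature
#' subset guided by correlation ranking, and fit the final model on the
#' complete (balanced, discretised) data.
#'
#' @param features annotated matrix from [annotate_gene()].
#' @param seed integer seed.
#' @param k CV folds (default 10).
#' @param cv_repeats repeats for algorithm choice and the reported
#'   evaluation (default 10).
#' @param search_repeats repeats during feature-subset search
#'   (default 3).
#' @param search_k folds during feature-subset search (default `k`).
#' @param do_select_features run the minimal-feature search
#'   (default TRUE).
#' @return list of class `prospr_fit`: `model`, `algorithm_id`,
#'   `features_used`, `report` (the winning `prospr_eval` on the full
#'   catalogue), `final_report` (CV of the reduced model), `discretizer`,
#'   `seed`.
#' @export
train_gene_model <- function(features, seed = 1L, k = 10L,
                             cv_repeats = 10L, search_repeats = 3L,
                             search_k = k, do_select_features = TRUE) {
  lab <- features$label
  keep <- lab %in% c("pathogenic", "benign")
  if (!any(lab[keep] == "pathogenic") || !any(lab[keep] == "benign"))
    stop("training requires both pathogenic and benign variants")
  X <- features[keep, feature_catalogue(), drop = FALSE]
  y <- as.integer(lab[keep] == "pathogenic")

  sel_alg <- select_algorithm(X, y, seed = seed, k = k,
                              repeats = cv_repeats)
  alg <- sel_alg$algorithm_id

  if (do_select_features) {
    sel_feat <- select_features(X, y, algorithm = alg, seed = seed,
                                repeats = search_repeats, k = search_k)
    feats <- sel_feat$features
  } else {
    feats <- names(X)
  }
  Xr <- X[, feats, drop = FALSE]
  final_report <- repeated_kfold_cv(Xr, y, algorithm = alg, k = k,
                                    repeats = cv_repeats, seed = seed)
  w <- class_balance(y)
  disc <- fit_discretizer(Xr, y, w)
  model <- fit_classifier(apply_discretizer(disc, Xr), y, w,
                          algorithm = alg, seed = seed)
  structure(list(model = model, algorithm_id = alg,
                 features_used = feats, report = sel_alg$report,
                 final_report = final_report, discretizer = disc,
                 seed = seed),
            class = "prospr_fit")
}

#' @export
print.prospr_fit <- function(x, ...) {
  cat(sprintf(
    "<prospr_fit> %s on %d/%d features; CV MCC %.3f (SD %.3f)\n",
    x$algorithm_id, length(x$features_used), length(feature_catalogue()),
    x$final_report$mcc_mean, x$final_report$mcc_sd))
  invisible(x)
}

#' Predict with a trained gene model
#'
#' Applies the stored discretisation and classifier to an annotated
#' feature matrix.
#'
#' @param fit a `prospr_fit` from [train_gene_model()].
#' @param features annotated matrix from [annotate_gene()].
#' @return numeric probabilities of the pathogenic class.
#' @export
predict_gene_model <- function(fit, features) {
  X <- features[, fit$features_used, drop = FALSE]
  predict_proba(fit$model, apply_discretizer(fit$discretizer, X))
}

#' Evaluate an external score table at a threshold
#'
#' MCC, ROC AUC and PR AUC of predictor scores against labels, with the
#' binary classification taken at `threshold` (pathogenic iff score >=
#' threshold).
#'
#' @param scores numeric scores in \[0, 1\].
#' @param labels binary truth (1 = pathogenic).
#' @param threshold classification threshold (default 0.5).
#' @return list: mcc, roc_auc, pr_auc, threshold.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  list(mcc = mcc(confusion_counts(labels,
                                  as.integer(scores >= threshold))),
       roc_auc = roc_auc(scores, labels),
       pr_auc = pr_auc(scores, labels),
       threshold = threshold)
}

#' Serialise a model fit to YAML
#'
#' Persists the algorithm id, selected features, discretisation cuts and
#' seed (logitboost / simple-logistic parameters included) so a run can
#' be audited and reproduced.
#'
#' @param fit a `prospr_fit`.
#' @param path output YAML path.
#' @export
save_gene_model <- function(fit, path) {
  obj <- list(
    algorithm_id = fit$algorithm_id,
    features_used = fit$features_used,
    seed = fit$seed,
    cuts = lapply(fit$discretizer$cuts, as.numeric),
    levels = fit$discretizer$levels,
    mcc_mean = fit$final_report$mcc_mean,
    mcc_sd = fit$final_report$mcc_sd)
  if (fit$algorithm_id == "simple_logistic")
    obj$coefficients <- c(alpha = unname(fit$model$alpha),
                          stats::setNames(as.numeric(fit$model$beta),
                                          names(fit$model$beta)))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Run manifest
#'
#' Writes a JSON manifest (configuration, seeds, package version and a
#' content hash of the supplied outputs) sufficient to check that a
#' rerun reproduces a result.
#'
#' @param config named list of run configuration values.
#' @param outputs named list of R objects whose serialised content is
#'   hashed.
#' @param path output JSON path.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(config, outputs, path) {
  hash <- content_hash(outputs)
  manifest <- list(
    package = "prospr",
    version = as.character(utils::packageVersion("prospr")),
    config = config,
    output_hash = hash)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

## Deterministic content hash of an R object: MD5 of its version-2
## serialisation with the R-version-stamped header dropped.
content_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2L, xdr = TRUE)
  raw <- raw[-seq_len(14L)]
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeBin(raw, tmp)
  unname(tools::md5sum(tmp))
}
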