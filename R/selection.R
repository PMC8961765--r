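## Correlation-based feature ranking, minimal-feature backward
## elimination, per-gene algorithm choice by MCC, and the rank-based
## statistical comparisons.

ALGORITHM_PRECEDENCE <- c("logitboost", "simple_logistic", "hoeffding_tree")

#' Correlation-based feature ranking
#'
#' Scores each feature by the absolute Pearson correlation between it
#' and the class label; factor features are one-hot expanded and scored
#' by their best level.  Constant features score 0.  Features are
#' returned in descending informativeness.
#'
#' @param X data.frame of features.
#' @param y binary labels.
#' @return data.frame (feature, score) sorted by decreasing score.
#' @export
correlation_rank <- function(X, y) {
  y <- as.integer(y)
  score <- vapply(names(X), function(nm) {
    col <- X[[nm]]
    if (is.numeric(col)) {
      m <- matrix(as.numeric(col), ncol = 1L)
    } else {
      v <- as.character(col)
      lev <- sort(unique(v[!is.na(v)]))
      if (length(lev) == 0L) return(0)
      m <- vapply(lev, function(lv) as.numeric(!is.na(v) & v == lv),
                  numeric(length(v)))
      m <- matrix(m, ncol = length(lev))
    }
    rs <- apply(m, 2L, function(x) {
      ok <- !is.na(x)
      if (sum(ok) < 2L || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
        return(0)
      abs(stats::cor(x[ok], y[ok]))
    })
    max(rs, 0)
  }, numeric(1L))
  out <- data.frame(feature = names(X), score = unname(score),
                    stringsAsFactors = FALSE)
  out[order(-out$score), , drop = FALSE]
}

#' Minimal-feature backward elimination
#'
#' Greedy search for the smallest feature subset that keeps the highest
#' cross-validated MCC: features are visited in ascending absolute
#' correlation with the class (least informative first) and a feature is
#' dropped whenever removing it does not decrease the repeated-CV MCC
#' (by more than `tolerance`).  The top-ranked feature is never dropped,
#' so the surviving set is never empty.
#'
#' @param X data.frame with the full feature catalogue.
#' @param y binary labels.
#' @param algorithm classifier id used during the search.
#' @param seed integer seed.
#' @param repeats CV repeats during the search (default 3).
#' @param k CV folds (default 10).
#' @param tolerance maximum admissible MCC decrease when dropping a
#'   feature (default 1e-9).
#' @param ... passed to [repeated_kfold_cv()].
#' @return list: `features` (surviving names), `mcc` (final CV MCC),
#'   `trace` (data.frame of the search).
#' @export
select_features <- function(X, y, algorithm = "logitboost", seed = 1L,
                            repeats = 3L, k = 10L, tolerance = 1e-9, ...) {
  ranking <- correlation_rank(X, y)
  order_asc <- rev(ranking$feature)
  keep <- names(X)
  base <- repeated_kfold_cv(X, y, algorithm = algorithm, k = k,
                            repeats = repeats, seed = seed, ...)
  best_mcc <- base$mcc_mean
  trace <- list(data.frame(feature = "<all>", action = "baseline",
                           mcc = best_mcc))
  top_feature <- ranking$feature[1L]
  for (f in order_asc) {
    if (f == top_feature && length(keep) == 1L) break
    if (!(f %in% keep) || length(keep) == 1L) next
    cand <- setdiff(keep, f)
    ev <- repeated_kfold_cv(X[, cand, drop = FALSE], y,
                            algorithm = algorithm, k = k,
                            repeats = repeats, seed = seed, ...)
    if (ev$mcc_mean >= best_mcc - tolerance) {
      keep <- cand
      best_mcc <- max(best_mcc, ev$mcc_mean)
      trace[[length(trace) + 1L]] <-
        data.frame(feature = f, action = "dropped", mcc = ev$mcc_mean)
    } else {
      trace[[length(trace) + 1L]] <-
        data.frame(feature = f, action = "kept", mcc = ev$mcc_mean)
    }
  }
  list(features = keep, mcc = best_mcc, trace = do.call(rbind, trace))
}

#' Per-gene algorithm selection
#'
#' Runs the repeated cross-validation for each of the three algorithms
#' and returns the one with the highest mean MCC.  Ties break by fixed
#' precedence: logitboost, then simple_logistic, then hoeffding_tree.
#'
#' @param X data.frame of features.
#' @param y binary labels.
#' @param seed integer seed (shared across algorithms so they see the
#'   same fold splits).
#' @param ... passed to [repeated_kfold_cv()].
#' @return list: `algorithm_id`, `report` (the winning `prospr_eval`),
#'   `all` (named list of all three reports).
#' @export
select_algorithm <- function(X, y, seed = 1L, ...) {
  reports <- lapply(ALGORITHM_PRECEDENCE, function(alg) {
    repeated_kfold_cv(X, y, algorithm = alg, seed = seed, ...)
  })
  names(reports) <- ALGORITHM_PRECEDENCE
  mccs <- vapply(reports, function(r) r$mcc_mean, numeric(1L))
  best <- ALGORITHM_PRECEDENCE[which.max(mccs)]   # first max = precedence
  list(algorithm_id = best, report = reports[[best]], all = reports)
}

#' Kruskal-Wallis rank-sum comparison
#'
#' Rank-based comparison of three or more score distributions (e.g. the
#' per-gene prediction scores of several tools), with tie correction;
#' the p-value comes from the chi-square approximation with g - 1
#' degrees of freedom.  Identical groups give H = 0, p = 1.
#'
#' @param groups list of numeric vectors.
#' @return list with `statistic` (H) and `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) > 0L))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1L)
    return(list(statistic = 0, p_value = 1))
  kt <- stats::kruskal.test(x, g)
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Wilcoxon signed-rank comparison of paired performance values
#'
#' Paired rank test for a difference between two matched samples (e.g.
#' per-repeat MCC of two classifiers on the same gene).  Zero
#' differences are dropped; the p-value is exact for 25 or fewer
#' non-zero untied differences and uses the normal approximation with
#' continuity correction otherwise.  All-zero differences give p = 1.
#'
#' @param a,b paired numeric vectors of equal length.
#' @return list with `statistic` (V) and `p_value`.
#' @export
wilcoxon_signed_rank <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0L) return(list(statistic = 0, p_value = 1))
  exact <- length(d) <= 25L && !any(duplicated(abs(d)))
  wt <- suppressWarnings(
    stats::wilcox.test(d, exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}
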