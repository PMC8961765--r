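## Shared machinery for the three classifiers: feature schema, design
## matrix encoding (one-hot factors with an explicit missing level) and
## seed-scoped randomness.

## Evaluate expr under a fixed RNG seed without disturbing the caller's
## RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Schema of a feature frame: column names, types and factor levels.
feature_schema <- function(X) {
  list(cols = names(X),
       is_factor = vapply(X, function(c) is.factor(c) || is.character(c),
                          logical(1L)),
       levels = lapply(X, function(c) if (is.factor(c)) levels(c)
                       else if (is.character(c)) sort(unique(c)) else NULL))
}

check_schema <- function(schema, X) {
  if (!identical(schema$cols, names(X)))
    stop("feature schema mismatch: expected columns ",
         paste(schema$cols, collapse = ", "))
  invisible(TRUE)
}

## Numeric design matrix: numeric columns pass through (NA preserved),
## factor/character columns expand to one 0/1 indicator per training
## level ("(missing)" included when present).
build_design <- function(X, schema) {
  check_schema(schema, X)
  cols <- list()
  for (nm in schema$cols) {
    if (schema$is_factor[[nm]]) {
      lev <- schema$levels[[nm]]
      v <- as.character(X[[nm]])
      for (lv in lev) {
        cols[[paste0(nm, "=", lv)]] <-
          as.numeric(!is.na(v) & v == lv)
      }
    } else {
      cols[[nm]] <- as.numeric(X[[nm]])
    }
  }
  mat <- do.call(cbind, cols)
  colnames(mat) <- names(cols)
  mat
}

#' Fit a gene-specific classifier
#'
#' Front door to the three interchangeable weighted probabilistic binary
#' classifiers.  All three honour per-instance weights and are
#' deterministic given the row order and `seed`.
#'
#' @param X data.frame of features (numeric and/or factor columns; a
#'   factor level `"(missing)"` represents missingness).
#' @param y binary labels (1 = pathogenic).
#' @param w positive instance weights.
#' @param algorithm one of `"logitboost"`, `"simple_logistic"`,
#'   `"hoeffding_tree"`.
#' @param seed integer seed for the algorithms that use randomness
#'   (internal cross-validation of the simple logistic).
#' @param ... algorithm-specific parameters, see [fit_logitboost()],
#'   [fit_simple_logistic()], [fit_hoeffding_tree()].
#' @return a fitted model object (class `prospr_model`).
#' @export
fit_classifier <- function(X, y, w = rep(1, nrow(X)),
                           algorithm = c("logitboost", "simple_logistic",
                                         "hoeffding_tree"),
                           seed = 1L, ...) {
  algorithm <- match.arg(algorithm)
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("single-class training data")
  switch(algorithm,
         logitboost = fit_logitboost(X, y, w, ...),
         simple_logistic = fit_simple_logistic(X, y, w, seed = seed, ...),
         hoeffding_tree = fit_hoeffding_tree(X, y, w, ...))
}

#' Predict pathogenicity probability
#'
#' @param model a fitted `prospr_model`.
#' @param X data.frame of features matching the model's schema.
#' @return numeric vector of probabilities of the pathogenic class; the
#'   classification rule is pathogenic iff probability >= 0.5.
#' @export
predict_proba <- function(model, X) {
  stopifnot(inherits(model, "prospr_model"))
  switch(model$algorithm_id,
         logitboost = predict_logitboost(model, X),
         simple_logistic = predict_simple_logistic(model, X),
         hoeffding_tree = predict_hoeffding(model, X))
}

#' @export
print.prospr_model <- function(x, ...) {
  cat(sprintf("<prospr_model> %s over %d feature(s)\n",
              x$algorithm_id, length(x$schema$cols)))
  invisible(x)
}
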