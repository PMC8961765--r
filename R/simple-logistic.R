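## Simple logistic: additive logistic regression built by LogitBoost
## with simple (single-attribute) weighted linear regressions as base
## learners, the number of boosting iterations chosen by internal
## stratified 5-fold cross-validation on the error rate.  The fitted
## model collapses to one coefficient per design column plus an
## intercept.

## One boosting pass: best simple linear regression of z on a single
## (standardised, NA-imputed-to-zero) design column, vectorised across
## columns via weighted cross-products.  Returns c(j, a, b);
## j = 0 denotes the intercept-only fallback.  `mat2` is mat^2,
## precomputed once per fit.
best_simple_regression <- function(mat, z, w, mat2 = mat * mat) {
  sw <- sum(w)
  zbar <- sum(w * z) / sw
  wx <- as.numeric(crossprod(mat, w))
  wx2 <- as.numeric(crossprod(mat2, w))
  wxz <- as.numeric(crossprod(mat, w * z))
  xbar <- wx / sw
  sxx <- wx2 - sw * xbar^2
  sxz <- wxz - sw * xbar * zbar
  ssr <- ifelse(sxx > 1e-12, sxz^2 / sxx, 0)   # SSE reduction vs intercept
  j <- which.max(ssr)
  if (ssr[j] <= 1e-12) return(c(0, zbar, 0))
  b <- sxz[j] / sxx[j]
  c(j, zbar - b * xbar[j], b)
}

## Core boosting loop; returns the per-iteration cumulative coefficient
## matrix (ncol(mat) + 1 rows: intercept then betas) so that CV can
## score every iteration count in one pass.
simple_logistic_path <- function(mat, y, w, max_iter) {
  n <- nrow(mat)
  mat2 <- mat * mat
  F <- numeric(n)
  p <- rep(0.5, n)
  coefs <- matrix(0, nrow = ncol(mat) + 1L, ncol = max_iter)
  cur <- numeric(ncol(mat) + 1L)
  for (m in seq_len(max_iter)) {
    p_cl <- pmin(pmax(p, 1e-5), 1 - 1e-5)
    z <- pmin(pmax((y - p_cl) / (p_cl * (1 - p_cl)), -3), 3)
    wm <- w * p_cl * (1 - p_cl)
    fit <- best_simple_regression(mat, z, wm, mat2)
    j <- fit[1L]; a <- fit[2L]; b <- fit[3L]
    cur[1L] <- cur[1L] + 0.5 * a
    if (j > 0) cur[j + 1L] <- cur[j + 1L] + 0.5 * b
    fx <- if (j > 0) a + b * mat[, j] else rep(a, n)
    F <- F + 0.5 * fx
    p <- 1 / (1 + exp(-2 * F))
    coefs[, m] <- cur
  }
  coefs
}

## Standardisation + zero imputation schema for the design matrix.
standardize_fit <- function(mat) {
  mu <- colMeans(mat, na.rm = TRUE)
  sd <- apply(mat, 2L, stats::sd, na.rm = TRUE)
  sd[!is.finite(sd) | sd < 1e-12] <- 1
  mu[!is.finite(mu)] <- 0
  list(mu = mu, sd = sd)
}

standardize_apply <- function(mat, std) {
  out <- sweep(sweep(mat, 2L, std$mu, "-"), 2L, std$sd, "/")
  out[is.na(out)] <- 0   # zero imputation after standardisation
  out
}

#' Simple logistic classifier
#'
#' Additive logistic regression built by LogitBoost with
#' single-attribute weighted linear regression base learners.  The
#' number of boosting iterations is chosen by internal stratified 5-fold
#' cross-validation of the classification error, which guards against
#' overfitting; the final model is refit on the full data at the chosen
#' iteration count.  Missing numeric values are zero-imputed after
#' standardisation; factors are one-hot encoded.
#'
#' @param X data.frame of features.
#' @param y binary labels (1 = pathogenic).
#' @param w positive instance weights.
#' @param max_iter maximum boosting iterations considered (default 50).
#' @param cv_folds internal folds for iteration selection (default 5).
#' @param seed seed for the internal fold split.
#' @return a `prospr_model` with per-design-column coefficients in
#'   `$beta` and intercept `$alpha` (on the standardised scale).
#' @export
fit_simple_logistic <- function(X, y, w = rep(1, nrow(X)), max_iter = 50L,
                                cv_folds = 5L, seed = 1L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("single-class training data")
  schema <- feature_schema(X)
  raw <- build_design(X, schema)
  std <- standardize_fit(raw)
  mat <- standardize_apply(raw, std)
  n <- nrow(mat)

  folds <- with_seed(seed, stratified_folds(y, min(cv_folds, min(table(y)))))
  n_folds <- max(folds)
  err <- matrix(0, nrow = n_folds, ncol = max_iter)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2L) next
    coefs <- simple_logistic_path(mat[tr, , drop = FALSE], y[tr], w[tr],
                                  max_iter)
    lin <- cbind(1, mat[!tr, , drop = FALSE]) %*% coefs
    pred <- lin >= 0   # p >= 0.5  <=>  F >= 0
    err[f, ] <- colSums(w[!tr] * (pred != y[!tr])) / sum(w[!tr])
  }
  mean_err <- colMeans(err)
  m_star <- which.min(mean_err)   # earliest minimum on ties

  coefs <- simple_logistic_path(mat, y, w, m_star)
  cur <- coefs[, m_star]
  beta <- stats::setNames(cur[-1L], colnames(mat))
  structure(list(algorithm_id = "simple_logistic", schema = schema,
                 std = std, alpha = cur[1L], beta = beta,
                 m_star = m_star, seed = seed),
            class = "prospr_model")
}

predict_simple_logistic <- function(model, X) {
  mat <- standardize_apply(build_design(X, model$schema), model$std)
  F <- as.numeric(model$alpha + mat %*% model$beta)
  1 / (1 + exp(-2 * F))
}
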