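## LogitBoost over weighted regression stumps (two-class convention
## p = 1 / (1 + exp(-2F))), and the weighted least-squares stump itself.

## Iteration-invariant per-column sort structure for the stump search:
## sorted row indices of the non-NA values, the sorted values and the
## candidate boundaries (last index of each run of equal values).
stump_layout <- function(mat) {
  lapply(seq_len(ncol(mat)), function(j) {
    x <- mat[, j]
    ok <- which(!is.na(x))
    ord <- ok[order(x[ok])]
    xs <- x[ord]
    list(ord = ord, na = which(is.na(x)), xs = xs,
         boundary = which(diff(xs) > 0))
  })
}

## Weighted regression stump on a design matrix: chooses the column and
## threshold minimising weighted squared error of the working response.
## Rows with NA in a column form their own branch.  Returns a list
## (col, cut, mu_left, mu_right, mu_na, mu_all).
fit_stump <- function(mat, z, w, layout = stump_layout(mat)) {
  n <- nrow(mat)
  wz <- w * z
  mu_all <- sum(wz) / sum(w)
  sse_all <- sum(w * (z - mu_all)^2)
  best <- list(col = NA_integer_, cut = NA_real_, mu_left = mu_all,
               mu_right = mu_all, mu_na = mu_all, mu_all = mu_all,
               sse = sse_all)
  for (j in seq_len(ncol(mat))) {
    lay <- layout[[j]]
    if (length(lay$ord) == 0L) next
    ## NA branch contribution
    if (length(lay$na) > 0L) {
      w_na <- sum(w[lay$na])
      mu_na <- sum(wz[lay$na]) / w_na
      sse_na <- sum(w[lay$na] * (z[lay$na] - mu_na)^2)
    } else {
      mu_na <- mu_all
      sse_na <- 0
    }
    xs <- lay$xs; zs <- z[lay$ord]; ws <- w[lay$ord]
    cw <- cumsum(ws)
    cwz <- cumsum(ws * zs)
    cwz2 <- cumsum(ws * zs^2)
    tot_w <- cw[length(cw)]
    tot_wz <- cwz[length(cwz)]
    tot_wz2 <- cwz2[length(cwz2)]
    last_of_run <- lay$boundary
    if (length(last_of_run) == 0L) next
    wl <- cw[last_of_run]
    wzl <- cwz[last_of_run]
    wz2l <- cwz2[last_of_run]
    wr <- tot_w - wl
    wzr <- tot_wz - wzl
    wz2r <- tot_wz2 - wz2l
    sse <- (wz2l - wzl^2 / wl) + (wz2r - wzr^2 / wr) + sse_na
    k <- which.min(sse)
    if (sse[k] < best$sse - 1e-12) {
      i <- last_of_run[k]
      best <- list(col = j, cut = (xs[i] + xs[i + 1L]) / 2,
                   mu_left = wzl[k] / wl[k], mu_right = wzr[k] / wr[k],
                   mu_na = mu_na, mu_all = mu_all, sse = sse[k])
    }
  }
  best
}

predict_stump <- function(stump, mat) {
  if (is.na(stump$col)) return(rep(stump$mu_all, nrow(mat)))
  x <- mat[, stump$col]
  out <- ifelse(is.na(x), stump$mu_na,
                ifelse(x <= stump$cut, stump$mu_left, stump$mu_right))
  out
}

#' LogitBoost with decision stumps
#'
#' Standard two-class LogitBoost (additive logistic regression): starting
#' from F = 0 and p = 1/2, each iteration computes working responses
#' z = (y - p) / (p(1 - p)) (probabilities clamped to \[1e-5, 1 - 1e-5\],
#' responses capped at +/- 3), case weights w.p(1 - p), fits one weighted
#' least-squares regression stump and updates F by half the stump,
#' with p = 1 / (1 + exp(-2F)).
#'
#' @param X data.frame of features.
#' @param y binary labels (1 = pathogenic).
#' @param w positive instance weights.
#' @param M number of boosting iterations (default 10).
#' @return a `prospr_model`.
#' @export
fit_logitboost <- function(X, y, w = rep(1, nrow(X)), M = 10L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("single-class training data")
  schema <- feature_schema(X)
  mat <- build_design(X, schema)
  n <- nrow(mat)
  F <- numeric(n)
  p <- rep(0.5, n)
  stumps <- vector("list", M)
  layout <- stump_layout(mat)
  for (m in seq_len(M)) {
    p_cl <- pmin(pmax(p, 1e-5), 1 - 1e-5)
    z <- (y - p_cl) / (p_cl * (1 - p_cl))
    z <- pmin(pmax(z, -3), 3)
    wm <- w * p_cl * (1 - p_cl)
    st <- fit_stump(mat, z, wm, layout)
    stumps[[m]] <- st
    F <- F + 0.5 * predict_stump(st, mat)
    p <- 1 / (1 + exp(-2 * F))
  }
  structure(list(algorithm_id = "logitboost", schema = schema,
                 stumps = stumps, M = M),
            class = "prospr_model")
}

predict_logitboost <- function(model, X) {
  mat <- build_design(X, model$schema)
  F <- numeric(nrow(mat))
  for (st in model$stumps) F <- F + 0.5 * predict_stump(st, mat)
  1 / (1 + exp(-2 * F))
}
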