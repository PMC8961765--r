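## Supervised instance filters applied before training: class balancing
## by instance reweighting, and Fayyad-Irani entropy/MDL discretisation
## of numeric features into nominal bins.

#' Class balancing by instance reweighting
#'
#' Gives the minority class more weight so both classes carry the same
#' total: every minority-class weight is multiplied by the ratio of the
#' majority to the minority total weight, majority weights are left
#' unchanged.  With unit input weights and 20 pathogenic vs 80 benign
#' variants, each pathogenic weight becomes 4 and both class totals 80.
#'
#' @param y binary labels (logical or 0/1; 1 = pathogenic).
#' @param w initial positive instance weights (default all 1).
#' @return numeric weight vector with equal per-class totals.
#' @export
class_balance <- function(y, w = rep(1, length(y))) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L)
    stop("class balancing requires both classes present")
  stopifnot(all(w > 0), length(w) == length(y))
  tot1 <- sum(w[y == 1L])
  tot0 <- sum(w[y == 0L])
  out <- w
  if (tot1 < tot0) out[y == 1L] <- w[y == 1L] * (tot0 / tot1)
  if (tot0 < tot1) out[y == 0L] <- w[y == 0L] * (tot1 / tot0)
  out
}

## Weighted class entropy (bits) of a label vector.
weighted_entropy <- function(y, w) {
  tot <- sum(w)
  if (tot <= 0) return(0)
  p <- vapply(unique(y), function(cl) sum(w[y == cl]), numeric(1L)) / tot
  p <- p[p > 0]
  -sum(p * log2(p))
}

## Fayyad-Irani MDL acceptance test for one candidate binary split.
## S is split into S1 (x <= cut) and S2; all quantities weighted.
mdl_accept <- function(y, w, left) {
  N <- sum(w)
  if (N <= 0) return(FALSE)
  ent_s <- weighted_entropy(y, w)
  ent_1 <- weighted_entropy(y[left], w[left])
  ent_2 <- weighted_entropy(y[!left], w[!left])
  w1 <- sum(w[left]); w2 <- sum(w[!left])
  gain <- ent_s - (w1 / N) * ent_1 - (w2 / N) * ent_2
  k <- length(unique(y))
  k1 <- length(unique(y[left]))
  k2 <- length(unique(y[!left]))
  delta <- log2(3^k - 2) - (k * ent_s - k1 * ent_1 - k2 * ent_2)
  gain > (log2(N - 1) + delta) / N
}

## Best binary cut of a numeric column by weighted information gain;
## candidates are midpoints between adjacent distinct values.  Binary
## labels allow a fully vectorised sweep over cumulative class weights.
best_cut <- function(x, y, w) {
  ord <- order(x)
  xs <- x[ord]; ys <- as.integer(y[ord]); ws <- w[ord]
  boundary <- which(diff(xs) > 0)          # last index of each value run
  if (length(boundary) == 0L) return(NULL)
  cw1 <- cumsum(ws * (ys == 1L))
  cw0 <- cumsum(ws * (ys == 0L))
  N1 <- cw1[length(cw1)]; N0 <- cw0[length(cw0)]
  N <- N1 + N0
  l1 <- cw1[boundary]; l0 <- cw0[boundary]
  r1 <- N1 - l1; r0 <- N0 - l0
  plogp <- function(a, tot) ifelse(a > 0, a * log2(a / tot), 0)
  ent_side <- function(a, b) {
    tot <- a + b
    ifelse(tot > 0, -(plogp(a, tot) + plogp(b, tot)) / tot, 0)
  }
  ent_s <- ent_side(N1, N0)
  gain <- ent_s - ((l1 + l0) * ent_side(l1, l0) +
                     (r1 + r0) * ent_side(r1, r0)) / N
  k <- which.max(gain)
  if (!is.finite(gain[k])) return(NULL)
  i <- boundary[k]
  (xs[i] + xs[i + 1L]) / 2
}

#' Supervised MDL discretisation of one numeric feature
#'
#' Fayyad-Irani recursive binary splitting on weighted class entropy
#' with the MDL stopping criterion: a cut is accepted only when its
#' information gain exceeds the MDL coding cost
#' (log2(N-1) + log2(3^k - 2) - k Ent(S) + k1 Ent(S1) + k2 Ent(S2)) / N.
#' A feature whose root split fails the test gets no cut (single bin).
#' Missing values are ignored during the cut search and map to their own
#' category at application time.
#'
#' @param x numeric feature column (NA allowed).
#' @param y binary labels aligned with `x`.
#' @param w positive instance weights (default 1).
#' @return numeric vector of strictly increasing cut points (possibly
#'   empty).
#' @export
mdl_discretize <- function(x, y, w = rep(1, length(x))) {
  ok <- !is.na(x)
  recurse <- function(idx) {
    if (length(idx) < 2L) return(numeric(0))
    cut <- best_cut(x[idx], y[idx], w[idx])
    if (is.null(cut)) return(numeric(0))
    left <- x[idx] <= cut
    if (!mdl_accept(y[idx], w[idx], left)) return(numeric(0))
    c(recurse(idx[left]), cut, recurse(idx[!left]))
  }
  sort(recurse(which(ok)))
}

#' Apply a discretisation map
#'
#' Maps numeric values to 1-based bin indices given ordered cut points;
#' the convention is right-closed lower bins (x <= cut goes to the lower
#' bin).  Values beyond the fitted range fall into the end bins; NA maps
#' to NA (its own category downstream).
#'
#' @param x numeric vector.
#' @param cuts ordered cut points from [mdl_discretize()].
#' @return integer bin indices in 1..(length(cuts) + 1).
#' @export
apply_discretization <- function(x, cuts) {
  if (length(cuts) == 0L) return(ifelse(is.na(x), NA_integer_, 1L))
  idx <- vapply(x, function(v) {
    if (is.na(v)) return(NA_integer_)
    as.integer(sum(v > cuts) + 1L)
  }, integer(1L))
  idx
}

## Fit discretisation maps for every numeric column of a feature frame;
## categorical columns have their training levels recorded so that
## train/test applications share one schema.
fit_discretizer <- function(X, y, w = rep(1, nrow(X))) {
  num <- names(X)[vapply(X, is.numeric, logical(1L))]
  maps <- lapply(num, function(nm) mdl_discretize(X[[nm]], y, w))
  names(maps) <- num
  lev <- lapply(setdiff(names(X), num),
                function(nm) sort(unique(as.character(X[[nm]][!is.na(X[[nm]])]))))
  names(lev) <- setdiff(names(X), num)
  structure(list(cuts = maps, levels = lev), class = "prospr_discretizer")
}

## Apply fitted maps: every column becomes a factor with an explicit
## "(missing)" level; unseen categories map to missing.
apply_discretizer <- function(disc, X) {
  out <- X
  for (nm in names(X)) {
    if (nm %in% names(disc$cuts)) {
      bins <- apply_discretization(X[[nm]], disc$cuts[[nm]])
      lev <- as.character(seq_len(length(disc$cuts[[nm]]) + 1L))
      v <- factor(as.character(bins), levels = lev)
    } else {
      v <- factor(as.character(X[[nm]]), levels = disc$levels[[nm]])
    }
    f <- addNA(v, ifany = FALSE)
    levels(f)[is.na(levels(f))] <- "(missing)"
    out[[nm]] <- f
  }
  out
}
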