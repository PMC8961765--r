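# Independent brute-force oracles used to cross-check the package's
# implementations.  These deliberately use naive loops and direct
# definitions, not the code paths under test.

# MCC as the Pearson correlation (phi) of the two binary vectors
# realising a confusion table.
oracle_phi <- function(tp, fp, tn, fn) {
  truth <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  if (stats::sd(truth) == 0 || stats::sd(pred) == 0) return(0)
  stats::cor(truth, pred)
}

# ROC AUC by counting all positive-negative pairs.
oracle_roc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Average precision by an explicit descending sweep with tie groups.
oracle_ap <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  ap <- 0; tp <- 0; n_seen <- 0
  for (v in unique(s)) {
    idx <- which(s == v)
    tp <- tp + sum(y[idx])
    n_seen <- n_seen + length(idx)
    ap <- ap + sum(y[idx]) * (tp / n_seen)
  }
  ap / sum(y)
}

# Exhaustive recursive Fayyad-Irani discretisation: every midpoint
# between adjacent distinct values is evaluated by directly computed
# weighted entropies; the MDL test is applied verbatim; recursion on
# both sides.
oracle_mdl_cuts <- function(x, y, w = rep(1, length(x))) {
  ent <- function(yy, ww) {
    tot <- sum(ww)
    if (tot <= 0) return(0)
    p <- c(sum(ww[yy == 0]), sum(ww[yy == 1])) / tot
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  rec <- function(x, y, w) {
    ux <- sort(unique(x))
    if (length(ux) < 2) return(numeric(0))
    cands <- (ux[-length(ux)] + ux[-1]) / 2
    N <- sum(w)
    e_s <- ent(y, w)
    best_gain <- -Inf; best_cut <- NA
    for (cut in cands) {
      l <- x <= cut
      g <- e_s - sum(w[l]) / N * ent(y[l], w[l]) -
        sum(w[!l]) / N * ent(y[!l], w[!l])
      if (g > best_gain + 1e-12) { best_gain <- g; best_cut <- cut }
    }
    l <- x <= best_cut
    k <- length(unique(y)); k1 <- length(unique(y[l]))
    k2 <- length(unique(y[!l]))
    delta <- log2(3^k - 2) -
      (k * e_s - k1 * ent(y[l], w[l]) - k2 * ent(y[!l], w[!l]))
    if (best_gain <= (log2(N - 1) + delta) / N) return(numeric(0))
    c(rec(x[l], y[l], w[l]), best_cut, rec(x[!l], y[!l], w[!l]))
  }
  ok <- !is.na(x)
  sort(rec(x[ok], y[ok], w[ok]))
}

# Best threshold by a plain loop over the grid.
oracle_best_threshold <- function(scores, labels, grid) {
  best_t <- NA; best_m <- -Inf
  for (t in grid) {
    pred <- as.integer(scores >= t)
    tp <- sum(labels == 1 & pred == 1); fp <- sum(labels == 0 & pred == 1)
    tn <- sum(labels == 0 & pred == 0); fn <- sum(labels == 1 & pred == 0)
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    m <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
    if (m > best_m + 1e-15) { best_m <- m; best_t <- t }
  }
  list(threshold = best_t, mcc = best_m)
}

# All-pairs 3D neighbour count.
oracle_cluster3d <- function(query_xyz, other_xyz, radius) {
  cnt <- 0
  for (i in seq_len(nrow(other_xyz))) {
    if (sqrt(sum((other_xyz[i, ] - query_xyz)^2)) <= radius) cnt <- cnt + 1
  }
  cnt
}

# A tiny fully-annotated context for feature tests: helix structure,
# complete tracks, deterministic.
toy_context <- function(n = 30, seed = 42, fold = "helix",
                        tracks = TRUE, structure = TRUE) {
  toy <- make_toy_structure(n, fold, seed = seed)
  trk <- NULL
  if (tracks) {
    trk <- list(
      conservation_grade = rep(c(9, 5, 1), length.out = n),
      disorder_prob = seq(0, 1, length.out = n),
      stability_effect = rep(0.5, n),
      ppi_effect = rep(0.5, n),
      domain_id = rep("D1", n),
      topology = rep("extracellular", n),
      functional_site = rep(FALSE, n))
  }
  protein_context("TOY", paste(toy$sequence, collapse = ""),
                  structure = if (structure)
                    list(atoms = toy$atoms,
                         modelled_positions = toy$modelled_positions)
                  else NULL,
                  tracks = if (tracks) trk else list())
}
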