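## Incremental Hoeffding tree (very fast decision tree) for categorical
## attributes, consuming the dataset as a single ordered stream.
## Numeric columns are pre-binned into at most `numeric_bins` weighted
## quantile bins at the start of the fit (batch-wrapper convention).
## Instance weights act as replication weights throughout.

ht_entropy <- function(counts) {
  tot <- sum(counts)
  if (tot <= 0) return(0)
  p <- counts / tot
  p <- p[p > 0]
  -sum(p * log2(p))
}

ht_new_leaf <- function(n_attr) {
  leaf <- new.env(parent = emptyenv())
  leaf$is_leaf <- TRUE
  leaf$class_counts <- c(0, 0)          # benign, pathogenic
  leaf$stats <- vector("list", n_attr)  # per attr: matrix 2 x levels
  leaf$seen_since_check <- 0
  leaf$children <- NULL
  leaf$split_attr <- NA_integer_
  leaf
}

ht_route <- function(node, row, create = FALSE) {
  while (!node$is_leaf) {
    v <- row[[node$split_attr]]
    child <- node$children[[v]]
    if (is.null(child)) {
      if (!create) return(node)   # unseen branch: stop here
      child <- ht_new_leaf(length(node$stats))
      node$children[[v]] <- child
    }
    node <- child
  }
  node
}

ht_info_gain <- function(leaf, attr) {
  m <- leaf$stats[[attr]]
  if (is.null(m) || ncol(m) < 2L) return(0)
  tot <- sum(m)
  base <- ht_entropy(rowSums(m))
  cond <- 0
  for (v in seq_len(ncol(m))) {
    wv <- sum(m[, v])
    if (wv > 0) cond <- cond + (wv / tot) * ht_entropy(m[, v])
  }
  base - cond
}

ht_try_split <- function(leaf, delta, tie_threshold, used, levels_per_attr) {
  n <- sum(leaf$class_counts)
  if (n <= 0) return(FALSE)
  avail <- setdiff(seq_along(leaf$stats), used)
  if (length(avail) == 0L) return(FALSE)
  gains <- vapply(avail, function(a) ht_info_gain(leaf, a), numeric(1L))
  ord <- order(gains, decreasing = TRUE)
  g_best <- gains[ord[1L]]
  g_second <- if (length(gains) > 1L) gains[ord[2L]] else 0
  eps <- sqrt(log(1 / delta) / (2 * n))   # R = log2(2 classes) = 1
  if (g_best <= 0) return(FALSE)
  if ((g_best - g_second) > eps || eps < tie_threshold) {
    attr <- avail[ord[1L]]
    leaf$is_leaf <- FALSE
    leaf$split_attr <- attr
    leaf$children <- list()
    m <- leaf$stats[[attr]]
    for (v in colnames(m)) {
      child <- ht_new_leaf(length(leaf$stats))
      child$class_counts <- m[, v]
      leaf$children[[v]] <- child
    }
    return(TRUE)
  }
  FALSE
}

#' Hoeffding tree classifier
#'
#' Incremental decision tree: instances are consumed as a single ordered
#' stream (row order = input order) and a leaf is split once the
#' information-gain advantage of the best attribute over the second best
#' exceeds the Hoeffding bound eps = sqrt(R^2 ln(1/delta) / (2n)) with
#' R = log2(number of classes) = 1 and n the weighted count at the leaf,
#' or when eps falls below the tie threshold.  Split checks happen every
#' `grace` weighted instances per leaf.  Leaves predict Laplace-smoothed
#' class probabilities.
#'
#' @param X data.frame of features; numeric columns are pre-binned into
#'   at most `numeric_bins` quantile bins.
#' @param y binary labels (1 = pathogenic).
#' @param w positive replication weights.
#' @param delta Hoeffding bound confidence parameter (default 1e-7).
#' @param grace weighted instances between split checks (default 200).
#' @param tie_threshold epsilon below which a tie is declared and the
#'   best attribute is taken (default 0.05).
#' @param numeric_bins quantile bins for numeric columns (default 10).
#' @return a `prospr_model`.
#' @export
fit_hoeffding_tree <- function(X, y, w = rep(1, nrow(X)), delta = 1e-7,
                               grace = 200, tie_threshold = 0.05,
                               numeric_bins = 10L) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("single-class training data")
  schema <- feature_schema(X)
  ## pre-bin numerics; factors pass through as character
  bin_cuts <- list()
  cols <- list()
  for (nm in names(X)) {
    if (schema$is_factor[[nm]]) {
      v <- as.character(X[[nm]])
      v[is.na(v)] <- "(missing)"
      cols[[nm]] <- v
    } else {
      x <- as.numeric(X[[nm]])
      qs <- unique(stats::quantile(x, probs = seq_len(numeric_bins - 1L) /
                                     numeric_bins, na.rm = TRUE,
                                   names = FALSE, type = 1L))
      bin_cuts[[nm]] <- qs
      b <- apply_discretization(x, qs)
      v <- ifelse(is.na(b), "(missing)", paste0("bin", b))
      cols[[nm]] <- v
    }
  }
  n_attr <- length(cols)
  root <- ht_new_leaf(n_attr)
  n <- length(y)
  for (i in seq_len(n)) {
    row <- vapply(cols, function(cc) cc[i], character(1L))
    leaf <- ht_route(root, row, create = TRUE)
    cls <- y[i] + 1L
    leaf$class_counts[cls] <- leaf$class_counts[cls] + w[i]
    for (a in seq_len(n_attr)) {
      m <- leaf$stats[[a]]
      v <- row[[a]]
      if (is.null(m)) {
        m <- matrix(0, nrow = 2L, ncol = 0L)
      }
      if (!(v %in% colnames(m))) {
        m <- cbind(m, c(0, 0))
        colnames(m)[ncol(m)] <- v
      }
      m[cls, v] <- m[cls, v] + w[i]
      leaf$stats[[a]] <- m
    }
    leaf$seen_since_check <- leaf$seen_since_check + w[i]
    if (leaf$seen_since_check >= grace) {
      leaf$seen_since_check <- 0
      if (all(leaf$class_counts > 0)) {
        used <- integer(0)  # attributes may repeat deeper (kept simple)
        ht_try_split(leaf, delta, tie_threshold, used, NULL)
      }
    }
  }
  structure(list(algorithm_id = "hoeffding_tree", schema = schema,
                 root = root, bin_cuts = bin_cuts, delta = delta,
                 grace = grace, tie_threshold = tie_threshold),
            class = "prospr_model")
}

predict_hoeffding <- function(model, X) {
  check_schema(model$schema, X)
  cols <- list()
  for (nm in model$schema$cols) {
    if (model$schema$is_factor[[nm]]) {
      v <- as.character(X[[nm]])
      v[is.na(v)] <- "(missing)"
      cols[[nm]] <- v
    } else {
      b <- apply_discretization(as.numeric(X[[nm]]), model$bin_cuts[[nm]])
      cols[[nm]] <- ifelse(is.na(b), "(missing)", paste0("bin", b))
    }
  }
  n <- nrow(X)
  out <- numeric(n)
  for (i in seq_len(n)) {
    row <- vapply(cols, function(cc) cc[i], character(1L))
    node <- ht_route(model$root, row)
    cc <- node$class_counts
    out[i] <- (cc[2L] + 1) / (sum(cc) + 2)   # Laplace
  }
  out
}
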