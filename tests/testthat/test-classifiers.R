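test_that("logitboost learns separable data and is internally consistent", {
  set.seed(1)
  X <- data.frame(x = c(rnorm(20, -2), rnorm(20, 2)))
  y <- rep(0:1, each = 20)
  m <- fit_logitboost(X, y)
  p <- predict_proba(m, X)
  expect_equal(mean((p >= 0.5) == y), 1)

  # probabilities equal 1/(1+exp(-2F)) recomputed from the stored stumps
  mat <- prospr:::build_design(X, m$schema)
  F <- numeric(nrow(mat))
  for (st in m$stumps) F <- F + 0.5 * prospr:::predict_stump(st, mat)
  expect_equal(p, 1 / (1 + exp(-2 * F)), tolerance = 1e-12)

  # complement rule
  expect_equal(1 - p, 1 - predict_proba(m, X), tolerance = 1e-15)

  expect_error(fit_logitboost(X, rep(1, 40)), "single-class")
})

test_that("logitboost CV MCC on label-permuted data centres on zero", {
  set.seed(2)
  mccs <- vapply(1:12, function(s) {
    set.seed(s)
    X <- data.frame(a = rnorm(120), b = runif(120))
    y <- sample(rep(0:1, 60))
    repeated_kfold_cv(X, y, "logitboost", k = 5, repeats = 2,
                      seed = s)$mcc_mean
  }, numeric(1))
  expect_lt(abs(mean(mccs)), 0.15)
})

test_that("simple logistic recovers effect signs and handles edge cases", {
  set.seed(3)
  n <- 1500
  X <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, 1 / (1 + exp(-(2 * X$a - 1 * X$b))))
  m <- fit_simple_logistic(X, y, seed = 5)
  expect_gt(m$beta[["a"]], 0)
  expect_lt(m$beta[["b"]], 0)
  # the stronger effect dominates
  expect_gt(abs(m$beta[["a"]]), abs(m$beta[["b"]]))

  # intercept-only data predicts the weighted class prevalence
  Xc <- data.frame(c1 = rep(1, 100))
  yc <- rep(c(1, 0), c(30, 70))
  mc <- fit_simple_logistic(Xc, yc, seed = 1)
  expect_lt(abs(unname(predict_proba(mc, Xc[1, , drop = FALSE])) - 0.3),
            0.02)

  # an irrelevant noise feature barely moves held-out log-loss
  set.seed(4)
  deltas <- vapply(1:5, function(s) {
    set.seed(s)
    n <- 2000
    tr <- data.frame(a = rnorm(n))
    ytr <- rbinom(n, 1, 1 / (1 + exp(-1.5 * tr$a)))
    te <- data.frame(a = rnorm(n))
    yte <- rbinom(n, 1, 1 / (1 + exp(-1.5 * te$a)))
    m1 <- fit_simple_logistic(tr, ytr, seed = s)
    tr$noise <- rnorm(n); te$noise <- rnorm(n)
    m2 <- fit_simple_logistic(tr, ytr, seed = s)
    ll <- function(p, y) -mean(y * log(pmax(p, 1e-12)) +
                                 (1 - y) * log(pmax(1 - p, 1e-12)))
    ll(predict_proba(m2, te), yte) -
      ll(predict_proba(m1, te[, "a", drop = FALSE]), yte)
  }, numeric(1))
  expect_lt(mean(abs(deltas)), 0.02)
})

test_that("hoeffding tree splits on a perfectly predictive attribute", {
  set.seed(6)
  X <- data.frame(f = factor(sample(c("u", "v"), 5000, replace = TRUE)),
                  junk = factor(sample(letters[1:3], 5000, replace = TRUE)))
  y <- as.integer(X$f == "u")
  m <- fit_hoeffding_tree(X, y)
  expect_gte(mean((predict_proba(m, X) >= 0.5) == y), 0.99)
  expect_false(m$root$is_leaf)
  expect_equal(m$schema$cols[m$root$split_attr], "f")

  # an unsplit tree predicts the class prior
  m2 <- fit_hoeffding_tree(X[1:50, ], y[1:50], grace = 200)
  expect_true(m2$root$is_leaf)
  prior <- (sum(y[1:50]) + 1) / (50 + 2)
  expect_equal(unique(predict_proba(m2, X[1:5, ])), prior)
})

test_that("the Hoeffding bound follows its closed form", {
  # eps = sqrt(ln(1/delta) / (2n)); R = log2(2) = 1
  n <- 1000; delta <- 1e-7
  eps <- sqrt(log(1 / delta) / (2 * n))
  expect_equal(eps, sqrt(log(1e7) / 2000), tolerance = 1e-15)
  # a split with gain advantage above eps happens; below does not:
  # exercised implicitly by the predictive-attribute test above
  expect_true(eps < 0.1)
})

test_that("instance weights equal instance duplication for all three", {
  X <- data.frame(x = c(1.5, 2, 3, 4, -1, -2, -3, -4),
                  g = factor(rep(c("p", "q"), 4)))
  y <- c(1, 1, 1, 1, 0, 0, 0, 0)
  Xdup <- rbind(X, X[c(2, 5), ])
  ydup <- c(y, y[c(2, 5)])
  wdup <- rep(1, 8); wdup[c(2, 5)] <- 2

  for (alg in c("logitboost", "hoeffding_tree")) {
    mA <- fit_classifier(Xdup, ydup, algorithm = alg, seed = 1)
    mB <- fit_classifier(X, y, w = wdup, algorithm = alg, seed = 1)
    expect_equal(predict_proba(mA, X), predict_proba(mB, X),
                 tolerance = 1e-12, label = alg)
  }
  # simple logistic: equality up to its internal CV fold geometry, so
  # compare with the fold split disabled by using a fixed iteration path
  pathA <- prospr:::simple_logistic_path(
    prospr:::standardize_apply(
      prospr:::build_design(Xdup, prospr:::feature_schema(Xdup)),
      prospr:::standardize_fit(
        prospr:::build_design(X, prospr:::feature_schema(X)))),
    ydup, rep(1, 10), 20)
  pathB <- prospr:::simple_logistic_path(
    prospr:::standardize_apply(
      prospr:::build_design(X, prospr:::feature_schema(X)),
      prospr:::standardize_fit(
        prospr:::build_design(X, prospr:::feature_schema(X)))),
    y, wdup, 20)
  expect_equal(pathA[, 20], pathB[, 20], tolerance = 1e-6)
})

test_that("fixed seed and row order give identical models", {
  set.seed(9)
  X <- data.frame(a = rnorm(60), b = factor(sample(c("x", "y"), 60, TRUE)))
  y <- rbinom(60, 1, 0.5)
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  for (alg in c("logitboost", "simple_logistic", "hoeffding_tree")) {
    m1 <- fit_classifier(X, y, algorithm = alg, seed = 7)
    m2 <- fit_classifier(X, y, algorithm = alg, seed = 7)
    expect_equal(predict_proba(m1, X), predict_proba(m2, X),
                 label = alg)
  }
})

test_that("schema mismatches are rejected at prediction time", {
  X <- data.frame(a = rnorm(30), b = rnorm(30))
  y <- rep(0:1, 15)
  m <- fit_logitboost(X, y)
  expect_error(predict_proba(m, X[, "a", drop = FALSE]), "schema")
})
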