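test_that("repeated CV is deterministic and pools confusion per repeat", {
  sim <- simulate_gene_dataset(gene_sim_spec(n_pathogenic = 40,
                                             n_benign = 30,
                                             seq_length = 80, seed = 13))
  ann <- annotate_gene(sim$variants, sim$context)
  X <- ann[, feature_catalogue()]
  y <- as.integer(ann$label == "pathogenic")
  e1 <- repeated_kfold_cv(X, y, "logitboost", k = 5, repeats = 2, seed = 3)
  e2 <- repeated_kfold_cv(X, y, "logitboost", k = 5, repeats = 2, seed = 3)
  expect_identical(e1$per_repeat, e2$per_repeat)
  expect_equal(e1$mcc_mean, mean(e1$per_repeat$mcc))
  expect_equal(e1$mcc_sd, sd(e1$per_repeat$mcc))
  expect_equal(nrow(e1$per_repeat), 2L)
})

test_that("pooled-confusion MCC differs from per-fold averaging where it must", {
  # construct folds where one fold is all-correct (MCC 1) and the other
  # degenerate (all predicted positive -> MCC 0 by convention); pooling
  # the confusion gives a value different from the fold average
  truth <- c(1, 1, 0, 0, 1, 1, 1, 1)
  pred <- c(1, 1, 0, 0, 1, 1, 1, 1)
  # fold 1 = indices 1:4 (perfect), fold 2 = indices 5:8 (single class)
  m_pool <- mcc(confusion_counts(truth, pred))
  m_f1 <- mcc(confusion_counts(truth[1:4], pred[1:4]))
  m_f2 <- mcc(confusion_counts(truth[5:8], pred[5:8]))
  expect_equal(m_pool, 1)
  expect_equal(mean(c(m_f1, m_f2)), 0.5)
  expect_false(isTRUE(all.equal(m_pool, mean(c(m_f1, m_f2)))))
})

test_that("a separable synthetic gene reaches high CV MCC", {
  spec <- gene_sim_spec(n_pathogenic = 80, n_benign = 50, seq_length = 120,
                        p_high_cons = c(pathogenic = 0.95, benign = 0.05),
                        p_buried = c(pathogenic = 0.8, benign = 0.05),
                        seed = 21)
  sim <- simulate_gene_dataset(spec)
  ann <- annotate_gene(sim$variants, sim$context)
  X <- ann[, feature_catalogue()]
  y <- as.integer(ann$label == "pathogenic")
  ev <- repeated_kfold_cv(X, y, "logitboost", k = 10, repeats = 3, seed = 2)
  expect_gte(ev$mcc_mean, 0.6)
})

test_that("k is reduced with a warning when a class is small", {
  set.seed(5)
  X <- data.frame(a = rnorm(24))
  y <- rep(c(1, 0), c(4, 20))
  X$a[y == 1] <- X$a[y == 1] + 3
  expect_warning(ev <- repeated_kfold_cv(X, y, "logitboost", k = 10,
                                         repeats = 2, seed = 1),
                 "reducing k")
  expect_equal(ev$k, 4L)
})

test_that("correlation ranking orders features by |r| with the class", {
  set.seed(7)
  n <- 80
  y <- rep(0:1, each = n / 2)
  X <- data.frame(perfect = y,
                  weak = y + rnorm(n, sd = 3),
                  constant = rep(1, n),
                  noise = rnorm(n))
  rk <- correlation_rank(X, y)
  expect_equal(rk$feature[1], "perfect")
  expect_equal(rk$score[1], 1)
  expect_equal(rk$score[rk$feature == "constant"], 0)
  # ordering matches direct computation
  direct <- abs(cor(X$weak, y))
  expect_equal(rk$score[rk$feature == "weak"], direct, tolerance = 1e-12)
})

test_that("feature selection eliminates noise and keeps duplicates minimal", {
  set.seed(15)
  n <- 100
  y <- rep(0:1, each = n / 2)
  informative <- y + rnorm(n, sd = 0.4)
  X <- data.frame(inf1 = informative,
                  inf2 = y + rnorm(n, sd = 0.5),
                  n1 = rnorm(n), n2 = rnorm(n), n3 = rnorm(n))
  sel <- select_features(X, y, algorithm = "logitboost", seed = 3,
                         repeats = 2, k = 5)
  expect_true("inf1" %in% sel$features || "inf2" %in% sel$features)
  expect_lte(sum(c("n1", "n2", "n3") %in% sel$features), 1L)

  # identical copies collapse to a single survivor
  Xdup <- data.frame(a = informative, b = informative, c = informative)
  sel2 <- select_features(Xdup, y, algorithm = "logitboost", seed = 3,
                          repeats = 2, k = 5)
  expect_length(sel2$features, 1L)

  # determinism
  sel3 <- select_features(X, y, algorithm = "logitboost", seed = 3,
                          repeats = 2, k = 5)
  expect_identical(sel$features, sel3$features)
})

test_that("algorithm selection returns the argmax with fixed tie precedence", {
  set.seed(19)
  n <- 90
  y <- rep(0:1, each = n / 2)
  X <- data.frame(x = y + rnorm(n, sd = 0.5))
  sel <- select_algorithm(X, y, seed = 2, k = 5, repeats = 2)
  expect_true(sel$algorithm_id %in% c("logitboost", "simple_logistic"))
  expect_equal(sel$report$mcc_mean, sel$all[[sel$algorithm_id]]$mcc_mean)
  best <- max(vapply(sel$all, function(r) r$mcc_mean, numeric(1)))
  expect_equal(sel$report$mcc_mean, best)

  # constant features force identical (zero) MCC -> precedence tie-break
  Xc <- data.frame(c1 = rep(1, n))
  selc <- select_algorithm(Xc, y, seed = 2, k = 5, repeats = 2)
  expect_equal(selc$algorithm_id, "logitboost")
})

test_that("fold-internal discretisation blocks label leakage", {
  # pure-noise features on a small cohort: fitting cuts on the full data
  # (labels included) inflates CV MCC, fold-internal fitting does not
  res <- t(vapply(1:8, function(s) {
    set.seed(s)
    X <- as.data.frame(matrix(runif(20 * 15), 20, 15))
    y <- rep(0:1, each = 10)
    c(fold = repeated_kfold_cv(X, y, "logitboost", k = 5, repeats = 2,
                               seed = s)$mcc_mean,
      global = repeated_kfold_cv(X, y, "logitboost", k = 5, repeats = 2,
                                 seed = s,
                                 global_discretize = TRUE)$mcc_mean)
  }, c(fold = 0, global = 0)))
  expect_lt(abs(mean(res[, "fold"])), 0.15)
  expect_gt(mean(res[, "global"]) - mean(res[, "fold"]), 0.1)
})
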