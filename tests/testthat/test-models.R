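# planted binary problem: positives carry `n_info` informative bits
planted_problem <- function(n_pos = 30, n_neg = 40, d = 60, n_info = 5,
                            flip = 0.05, seed = 1L) {
  set.seed(seed)
  x <- matrix(rbinom((n_pos + n_neg) * d, 1, 0.2), n_pos + n_neg, d)
  y <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
  for (j in seq_len(n_info)) {
    x[y, j] <- rbinom(n_pos, 1, 1 - flip)
    x[!y, j] <- rbinom(n_neg, 1, flip)
  }
  list(x = x, y = y)
}

test_that("every subspace tree draws exactly the configured dimensions, freshly", {
  pb <- planted_problem(seed = 2)
  fit <- train_rf(pb$x, pb$y, rf_config(n_trees = 120, features_per_tree = 8,
                                        seed = 3))
  sizes <- vapply(fit$trees, function(t) length(t$features), 1L)
  expect_true(all(sizes == 8L))
  # without replacement within a tree
  expect_true(all(vapply(fit$trees,
                         function(t) !anyDuplicated(t$features), TRUE)))
  # fresh draw per tree: not all feature sets identical
  expect_gt(length(unique(vapply(fit$trees,
                                 function(t) paste(t$features, collapse = ","),
                                 ""))), 1L)
})

test_that("forest scores are vote fractions on the 1/n_trees grid", {
  pb <- planted_problem(seed = 4)
  fit <- train_rf(pb$x, pb$y, rf_config(n_trees = 150, features_per_tree = 6,
                                        seed = 5))
  sc <- predict(fit, pb$x)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_equal(sc * 150, round(sc * 150), tolerance = 1e-9)
  # a strongly informative problem: positives clearly outscore negatives
  expect_gt(min(sc[pb$y]) , max(0, mean(sc[!pb$y]) - 0.5))
  expect_gt(auc(pb$y, sc), 0.9)
})

test_that("tree feature draws match the combinatorial containment expectation", {
  # with m of d dimensions per tree, P(tree contains a given bit) = m/d
  pb <- planted_problem(d = 40, n_info = 1, seed = 6)
  n_trees <- 400
  fit <- train_rf(pb$x, pb$y, rf_config(n_trees = n_trees,
                                        features_per_tree = 4, seed = 7))
  contains <- vapply(fit$trees, function(t) 1L %in% t$features, TRUE)
  p_expect <- 1 - choose(39, 4) / choose(40, 4) # = 4/40
  expect_equal(p_expect, 4 / 40, tolerance = 1e-12)
  ci <- qbinom(c(0.005, 0.995), n_trees, p_expect)
  expect_gte(sum(contains), ci[1])
  expect_lte(sum(contains), ci[2])
})

test_that("degenerate all-identical features give a majority-class stump", {
  x <- matrix(0L, 20, 5)
  y <- rep(c(TRUE, FALSE), c(6, 14))
  fit <- train_rf(x, y, rf_config(n_trees = 10, features_per_tree = 3,
                                  seed = 8))
  sc <- predict(fit, x)
  expect_true(all(sc == 0)) # majority class is FALSE
  expect_error(train_rf(x, rep(TRUE, 20), rf_config(n_trees = 5)),
               "both classes")
})

test_that("per-split classical mode is available behind the flag", {
  pb <- planted_problem(seed = 12)
  fit <- train_rf(pb$x, pb$y, rf_config(n_trees = 100, features_per_tree = 8,
                                        per_split = TRUE, seed = 13))
  sc <- predict(fit, pb$x)
  expect_gt(auc(pb$y, sc), 0.9)
})

test_that("SVM separates a separable planted problem and keeps margin units", {
  pb <- planted_problem(n_pos = 25, n_neg = 35, flip = 0, seed = 9)
  fit <- train_svm(pb$x, pb$y, gamma = 2^-5, cost = 4)
  sc <- predict(fit, pb$x)
  r <- confusion_rates(pb$y, sc > 0)
  expect_equal(r$tpr, 1)
  expect_equal(r$tnr, 1)
  # margin identity: support vectors on the right side sit near or beyond +-1
  expect_gte(max(sc[pb$y]), 1 - 1e-6)
  expect_lte(min(sc[!pb$y]), -1 + 1e-6)
})

test_that("decision values agree with a from-scratch dual QP solve", {
  set.seed(10)
  n <- 16
  x <- matrix(rbinom(n * 4, 1, 0.5), n, 4)
  y <- rep(c(TRUE, FALSE), each = 8)
  x[y, 1] <- 1
  x[!y, 1] <- 0
  gamma <- 0.5
  C <- 2
  fit <- e1071::svm(x, factor(y, levels = c(FALSE, TRUE)), kernel = "radial",
                    gamma = gamma, cost = C, scale = FALSE,
                    tolerance = 1e-6)
  dv <- attr(predict(fit, x, decision.values = TRUE), "decision.values")
  dec <- if (colnames(dv)[1] == "FALSE/TRUE") -dv[, 1] else dv[, 1]

  ys <- ifelse(y, 1, -1)
  K <- exp(-gamma * as.matrix(dist(x))^2)
  sol <- kernlab::ipop(c = rep(-1, n), H = K * (ys %*% t(ys)), A = t(ys),
                       b = 0, l = rep(0, n), u = rep(C, n), r = 0,
                       sigf = 12, maxiter = 200)
  alpha <- kernlab::primal(sol)
  f_raw <- function(z) sum(alpha * ys * exp(-gamma * colSums((t(x) - z)^2)))
  on_margin <- which(alpha > 1e-6 & alpha < C - 1e-6)
  b <- mean(vapply(on_margin, function(i) ys[i] - f_raw(x[i, ]), 0))
  dec_oracle <- apply(x, 1, f_raw) + b
  expect_equal(unname(dec), dec_oracle, tolerance = 1e-4)
})

test_that("grid search picks a working point and errors on an impossible grid", {
  pb <- planted_problem(n_pos = 20, n_neg = 30, d = 30, seed = 11)
  cfg <- svm_config(gamma_grid = 2^c(-7, -3), c_grid = c(1, 8),
                    inner_folds = 3, seed = 14)
  tuned <- tune_svm(pb$x, pb$y, cfg, balance_config(smote_target_positives = 40))
  expect_true(tuned$gamma %in% cfg$gamma_grid)
  expect_true(tuned$cost %in% cfg$c_grid)
  expect_identical(nrow(tuned$grid), 4L)
  expect_gt(max(tuned$grid$auc, na.rm = TRUE), 0.8)
})

test_that("cross-validation scores each vector exactly once out of fold", {
  pb <- planted_problem(n_pos = 24, n_neg = 56, d = 40, seed = 15)
  res <- crossvalidate(pb$x, pb$y, "tanimoto", k_folds = 10,
                       balance_cfg = balance_config(smote_target_positives = 40),
                       seed = 16)
  td <- tidy(res)
  # every vector appears in exactly one test fold
  expect_identical(sort(td$index), seq_along(pb$y))
  expect_true(all(!is.na(td$score)))
  expect_identical(length(unique(td$fold)), 10L)
  # fold sizes are balanced within one
  expect_lte(diff(range(table(td$fold))), 2L)
  # all 10 per-fold models retained
  expect_length(res$models, 10)
  # no synthetic vector ever receives an out-of-fold score (leakage guard)
  expect_identical(nrow(td), length(pb$y))
  expect_error(crossvalidate(pb$x[1:20, ], pb$y[1:20] & c(rep(TRUE, 5),
                                                          rep(FALSE, 15)),
                             "tanimoto"),
               "positive")
})

test_that("label permutation drives cross-validated AUC to chance", {
  pb <- planted_problem(n_pos = 30, n_neg = 50, d = 40, seed = 17)
  set.seed(18)
  y_perm <- sample(pb$y)
  res <- crossvalidate(pb$x, y_perm, "tanimoto", k_folds = 10,
                       balance_cfg = balance_config(smote_target_positives = 40),
                       seed = 19)
  expect_gt(res$metrics$auc, 0.3)
  expect_lt(res$metrics$auc, 0.7)
})

test_that("glance and tidy expose consistent model summaries", {
  pb <- planted_problem(seed = 20)
  res <- crossvalidate(pb$x, pb$y, "rf", k_folds = 10,
                       balance_cfg = balance_config(smote_target_positives = 40),
                       rf_cfg = rf_config(n_trees = 60), seed = 21)
  g <- glance(res)
  expect_identical(g$model_kind, "rf")
  expect_equal(g$tpr + g$fnr, 1)
  expect_equal(g$tnr + g$fpr, 1)
  expect_equal(g$auc, auc(tidy(res)$label, tidy(res)$score))
})

test_that("the models keep their characteristic asymmetry under stressed imbalance", {
  # hard-vote forests lean to the majority (negative) class; SMOTE-balanced
  # SVMs trade a little specificity for sensitivity
  mk <- function(seed) {
    set.seed(seed)
    n_pos <- 15; n_neg <- 150; d <- 300; flip <- 0.2
    x <- matrix(rbinom((n_pos + n_neg) * d, 1, 0.15), n_pos + n_neg, d)
    y <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
    for (j in 1:6) {
      x[y, j] <- rbinom(n_pos, 1, 1 - flip)
      x[!y, j] <- rbinom(n_neg, 1, flip)
    }
    list(x = x, y = y)
  }
  bal <- balance_config(smote_target_positives = 100)
  scfg <- svm_config(gamma_grid = 2^c(-9, -7, -5), c_grid = 2^c(0, 2, 4))
  rf_tpr <- c(); rf_tnr <- c(); svm_tpr <- c(); svm_tnr <- c()
  for (s in 1:3) {
    pb <- mk(s)
    rf <- crossvalidate(pb$x, pb$y, "rf", balance_cfg = bal,
                        rf_cfg = rf_config(n_trees = 150), seed = s)
    sv <- crossvalidate(pb$x, pb$y, "svm", balance_cfg = bal,
                        svm_cfg = scfg, seed = s)
    rf_tpr <- c(rf_tpr, rf$metrics$tpr); rf_tnr <- c(rf_tnr, rf$metrics$tnr)
    svm_tpr <- c(svm_tpr, sv$metrics$tpr); svm_tnr <- c(svm_tnr, sv$metrics$tnr)
  }
  expect_gte(mean(svm_tpr), mean(rf_tpr))
  expect_gte(mean(rf_tnr), mean(svm_tnr))
})
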