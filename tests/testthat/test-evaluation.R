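# Confusion matrices, the accuracy / recall / AUC metrics, stratified folds,
# hidden-size tuning and the strategy comparison harness.

test_that("confusion matrix counts true-by-predicted pairs", {
  expect_equal(confusion_matrix(1:3, 1:3), diag(3) * 1L, ignore_attr = TRUE)
  expect_equal(confusion_matrix(c(1, 1, 2), c(1, 2, 2)),
               matrix(c(1L, 0L, 1L, 1L), 2, 2))
  set.seed(51)
  t1 <- sample(1:3, 30, replace = TRUE)
  t2 <- sample(1:3, 30, replace = TRUE)
  expect_equal(sum(confusion_matrix(t1, t2)), 30)
  expect_error(confusion_matrix(1:3, 1:2), "equal length")
})

test_that("metrics match hand arithmetic on fixed confusions", {
  # perfect predictions
  probs <- diag(3)[rep(1:3, each = 5), ]
  rep_perfect <- evaluate_classifier(rep(1:3, each = 5), probs)
  expect_equal(rep_perfect$alpha, 1)
  expect_equal(unname(rep_perfect$tau), rep(1, 3))
  expect_equal(rep_perfect$beta, 1)

  # 9/15 correct, uniform per-class errors: alpha = 0.6, all tau = 0.6
  t_true <- rep(1:3, each = 5)
  t_pred <- c(1, 1, 1, 2, 3, 2, 2, 2, 1, 3, 3, 3, 3, 1, 2)
  conf <- confusion_matrix(t_true, t_pred)
  expect_equal(conf, matrix(c(3L, 1L, 1L, 1L, 3L, 1L, 1L, 1L, 3L), 3, 3))
  probs2 <- diag(3)[t_pred, ] * 0.8 + 0.1
  rep2 <- evaluate_classifier(t_true, probs2)
  expect_equal(rep2$alpha, 0.6, tolerance = 1e-12)
  expect_equal(unname(rep2$tau), rep(0.6, 3), tolerance = 1e-12)
})

test_that("alpha is the class-size weighted mean of tau", {
  set.seed(52)
  for (rep in 1:10) {
    t_true <- sample(1:3, 40, replace = TRUE)
    t_pred <- sample(1:3, 40, replace = TRUE)
    conf <- confusion_matrix(t_true, t_pred)
    n_c <- rowSums(conf)
    tau <- diag(conf) / n_c
    expect_equal(sum(diag(conf)) / sum(conf),
                 sum(tau * n_c) / sum(n_c), tolerance = 1e-12)
  }
})

test_that("trapezoidal AUC equals the Mann-Whitney statistic", {
  # fixed 6-sample score table, hand-checkable
  scores <- cbind(c(0.7, 0.6, 0.3, 0.2, 0.5, 0.1),
                  c(0.2, 0.3, 0.4, 0.5, 0.3, 0.2),
                  c(0.1, 0.1, 0.3, 0.3, 0.2, 0.7))
  scores <- scores / rowSums(scores)
  t_true <- c(1, 1, 2, 2, 3, 3)
  rep6 <- evaluate_classifier(t_true, scores)
  for (cc in 1:3) {
    expect_equal(rep6$beta_per_class[[cc]],
                 auc_mann_whitney(scores[, cc], t_true == cc),
                 tolerance = 1e-10)
  }

  # random tie-free scores, many classes
  set.seed(53)
  for (rep in 1:10) {
    s <- rnorm(25)
    pos <- sample(c(TRUE, FALSE), 25, replace = TRUE)
    if (!any(pos)) pos[1] <- TRUE
    if (all(pos)) pos[1] <- FALSE
    expect_equal(ckainit:::.auc_trapezoid(roc_curve(s, pos)),
                 auc_mann_whitney(s, pos), tolerance = 1e-10)
  }
})

test_that("tied scores earn half credit in both AUC routes", {
  s <- c(0.9, 0.5, 0.5, 0.5, 0.1, 0.1)
  pos <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(ckainit:::.auc_trapezoid(roc_curve(s, pos)),
               auc_mann_whitney(s, pos), tolerance = 1e-10)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(54)
  s <- c(rnorm(15, 1), rnorm(20))
  pos <- rep(c(TRUE, FALSE), c(15, 20))
  ref <- as.numeric(pROC::auc(pROC::roc(response = pos, predictor = s,
                                        quiet = TRUE, direction = "<")))
  expect_equal(ckainit:::.auc_trapezoid(roc_curve(s, pos)), ref,
               tolerance = 1e-10)
})

test_that("ROC curves are monotone and anchored at the corners", {
  set.seed(55)
  s <- rnorm(30)
  pos <- rep(c(TRUE, FALSE), 15)
  roc <- roc_curve(s, pos)
  expect_equal(unlist(roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(roc[nrow(roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(roc$fpr) >= 0))
  expect_true(all(diff(roc$tpr) >= 0))
})

test_that("a class missing from the truth yields NA metrics with a warning", {
  probs <- matrix(c(0.6, 0.3, 0.1,
                    0.2, 0.7, 0.1,
                    0.5, 0.4, 0.1,
                    0.3, 0.6, 0.1), 4, 3, byrow = TRUE)
  expect_warning(rep3 <- evaluate_classifier(c(1, 2, 1, 2), probs), "absent")
  expect_true(is.na(rep3$tau[[3]]))
  expect_true(is.na(rep3$beta_per_class[[3]]))
  expect_false(is.na(rep3$beta))
})

test_that("stratified folds are disjoint, exhaustive and balanced", {
  set.seed(56)
  t <- rep(1:3, c(20, 25, 15))
  folds <- kfold_split(t, k = 5, seed = 99)
  val_all <- sort(unlist(lapply(folds, `[[`, "val")))
  expect_equal(val_all, seq_along(t))
  for (f in folds) {
    expect_length(intersect(f$train, f$val), 0)
    # per-fold class proportions within one sample of the global split
    for (cl in 1:3) {
      expect_lte(abs(sum(t[f$val] == cl) - sum(t == cl) / 5), 1)
    }
  }
  # same seed, same folds
  expect_identical(folds, kfold_split(t, k = 5, seed = 99))
  # N = 10, k = 5: validation folds of size 2
  f10 <- kfold_split(rep(1:2, 5), k = 5, seed = 1)
  expect_true(all(vapply(f10, function(f) length(f$val), integer(1)) == 2L))
  expect_warning(kfold_split(c(1, 1, 1, 2), k = 3, seed = 1), "fewer than k")
})

test_that("mean-to-deviation selection prefers stability and smaller sizes", {
  crit <- function(a) mean(a) / (stats::sd(a) + 1e-8)
  expect_gt(crit(c(0.8, 0.8, 0.8)), crit(c(0.9, 0.5, 0.7)))

  toy <- separable_toy(N = 50, D = 4, gap = 4, seed = 57)
  tc <- train_config(epochs = 30, seed = 1)
  res1 <- tune_hidden_size(toy$X, toy$t, "random", grid = 3L, seed = 5,
                           train_cfg = tc)
  expect_equal(res1$selected_m1, 3L)

  # ties break toward the smaller candidate (which.max takes the first)
  res2 <- list(grid = c(10L, 20L), criterion = c(a = 2, b = 2))
  expect_equal(res2$grid[which.max(res2$criterion)], 10L)

  expect_error(tune_hidden_size(toy$X, toy$t, "random", integer(0)), "empty")
})

test_that("tuning returns one accuracy per fold and a grid member", {
  toy <- separable_toy(N = 50, D = 4, gap = 4, seed = 58)
  res <- tune_hidden_size(toy$X, toy$t, "pca", grid = c(2L, 3L), seed = 3,
                          train_cfg = train_config(epochs = 30, seed = 1))
  expect_equal(dim(res$fold_accuracy), c(5L, 2L))
  expect_true(all(res$fold_accuracy >= 0 & res$fold_accuracy <= 1))
  expect_true(res$selected_m1 %in% res$grid)
})

test_that("strategy comparison is deterministic and correctly shaped", {
  set.seed(59)
  spec <- synthetic_spec(group_sizes = c(CV = 10L, SV = 10L),
                         n_per_class = c(NC = 40L, MCI = 50L, AD = 30L),
                         informative_features = 11:16, seed = 59)
  ds <- generate_synthetic(spec)
  tr <- seq(1, nrow(ds$X), by = 2)
  te <- setdiff(seq_len(nrow(ds$X)), tr)
  tc <- train_config(epochs = 25)
  cmp1 <- compare_inits(ds$X[tr, ], ds$t[tr], ds$X[te, ], ds$t[te],
                        seeds = c(1, 2), strategies = c("random", "pca"),
                        m1 = 4, train_cfg = tc)
  cmp2 <- compare_inits(ds$X[tr, ], ds$t[tr], ds$X[te, ], ds$t[te],
                        seeds = c(1, 2), strategies = c("random", "pca"),
                        m1 = 4, train_cfg = tc)
  expect_identical(cmp1$summary, cmp2$summary)
  expect_equal(cmp1$summary$strategy, c("random", "pca"))
  mean_cols <- setdiff(names(cmp1$summary)[!grepl("_sd$", names(cmp1$summary))],
                       "strategy")
  expect_equal(mean_cols, c("alpha", "tau_NC", "tau_MCI", "tau_AD",
                            "beta", "beta_NC", "beta_MCI", "beta_AD"))
  expect_true(all(cmp1$summary[mean_cols] >= 0 & cmp1$summary[mean_cols] <= 1))
})
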