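# Multiclass evaluation: confusion matrix, accuracy, class-wise recall,
# one-vs-rest ROC/AUC, stratified cross-validation, hidden-size tuning and
# the initialization-strategy comparison experiment.

#' Confusion matrix
#'
#' @param t_true,t_pred integer labels in `1..C`, equal length.
#' @param n_classes number of classes; defaults to the largest label seen.
#' @return a `C x C` integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(t_true, t_pred, n_classes = NULL) {
  if (length(t_true) != length(t_pred)) {
    stop("`t_true` and `t_pred` must have equal length")
  }
  C <- if (is.null(n_classes)) max(t_true, t_pred) else as.integer(n_classes)
  lv <- seq_len(C)
  M <- table(factor(t_true, levels = lv), factor(t_pred, levels = lv))
  matrix(as.integer(M), C, C)
}

#' One-vs-rest ROC curve
#'
#' Sweeps the decision threshold over the distinct score values (tied scores
#' are grouped, so ties contribute diagonal segments) and returns the
#' operating points from `(0, 0)` to `(1, 1)`.
#'
#' @param scores numeric vector, larger = more confidently positive.
#' @param positive logical (or 0/1) vector marking the positive samples.
#' @return data frame with columns `fpr` and `tpr`, both non-decreasing.
#' @export
roc_curve <- function(scores, positive) {
  positive <- as.logical(positive)
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC needs at least one positive and one negative sample")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- positive[ord]
  grp_end <- which(c(s[-1] != s[-length(s)], TRUE))  # last index of each tie group
  tp <- cumsum(p)[grp_end]
  fp <- cumsum(!p)[grp_end]
  data.frame(fpr = c(0, fp / n_neg), tpr = c(0, tp / n_pos))
}

# Trapezoidal area under a roc_curve data frame.
.auc_trapezoid <- function(roc) {
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-nrow(roc)]) / 2)
}

#' Evaluate a multiclass probabilistic classifier
#'
#' From true labels and softmax probabilities, computes the confusion matrix
#' (predictions are the per-row argmax), the overall accuracy
#' \eqn{\alpha = \mathrm{tr}(\mathrm{confusion})/N}, the class-wise true
#' positive rate \eqn{\tau^c = t_p^c / N^c}, the one-vs-rest trapezoidal AUC
#' \eqn{\beta^c} scored by the class-`c` probability, and the class-size
#' weighted average \eqn{\beta = \sum_c \beta^c N^c / \sum_c N^c}.
#'
#' A class absent from `t_true` has undefined \eqn{\tau^c} and \eqn{\beta^c};
#' they are reported as `NA` and excluded from \eqn{\beta} with a warning.
#'
#' @param t_true integer labels in `1..C`.
#' @param probs `N x C` matrix of class probabilities.
#' @param class_names optional length-`C` names for reporting.
#' @return object of class `"eval_report"`: list with `confusion`, `alpha`,
#'   `tau`, `beta`, `beta_per_class`, `roc` (per-class data frames), `n_per_class`.
#' @export
evaluate_classifier <- function(t_true, probs, class_names = NULL) {
  probs <- as.matrix(probs)
  t_true <- as.integer(t_true)
  C <- ncol(probs)
  if (is.null(class_names)) {
    class_names <- if (C == 3L) c("NC", "MCI", "AD") else paste0("class", seq_len(C))
  }
  t_pred <- max.col(probs, ties.method = "first")
  conf <- confusion_matrix(t_true, t_pred, n_classes = C)
  dimnames(conf) <- list(true = class_names, pred = class_names)
  n_c <- rowSums(conf)
  N <- sum(n_c)

  alpha <- sum(diag(conf)) / N
  tau <- ifelse(n_c > 0, diag(conf) / n_c, NA_real_)

  beta_c <- rep(NA_real_, C)
  roc <- vector("list", C)
  for (cc in seq_len(C)) {
    pos <- t_true == cc
    if (any(pos) && any(!pos)) {
      roc[[cc]] <- roc_curve(probs[, cc], pos)
      beta_c[cc] <- .auc_trapezoid(roc[[cc]])
    }
  }
  if (anyNA(beta_c) || anyNA(tau)) {
    warning("some classes are absent from the truth (or fill it entirely); ",
            "their tau/beta are NA and excluded from the weighted AUC")
  }
  ok <- !is.na(beta_c)
  beta <- sum(beta_c[ok] * n_c[ok]) / sum(n_c[ok])

  names(tau) <- names(beta_c) <- names(roc) <- class_names
  structure(list(confusion = conf, alpha = alpha, tau = tau, beta = beta,
                 beta_per_class = beta_c, roc = roc, n_per_class = n_c,
                 class_names = class_names),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Multiclass evaluation (N =", sum(x$n_per_class), ")\n")
  cat("  accuracy alpha:", format(x$alpha, digits = 4), "\n")
  cat("  weighted AUC beta:", format(x$beta, digits = 4), "\n")
  cat("  tau: ", paste(sprintf("%s=%.3f", names(x$tau), x$tau), collapse = "  "), "\n")
  cat("  confusion (rows = true):\n")
  print(x$confusion)
  invisible(x)
}

#' Stratified k-fold split
#'
#' Shuffles each class independently with a seeded generator and deals its
#' members round-robin into `k` folds, so validation folds are disjoint,
#' exhaustive, and carry per-class proportions within one sample of the
#' global ones.
#'
#' @param t integer label vector (stratification variable).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return a list of `k` elements, each a list with `train` and `val` index
#'   vectors.
#' @export
kfold_split <- function(t, k = 5L, seed = 1L) {
  k <- as.integer(k)
  N <- length(t)
  if (k > N) stop("k = ", k, " exceeds the ", N, " samples")
  if (any(table(t) < k)) {
    warning("a class has fewer than k members; its stratification is degenerate")
  }
  set.seed(seed)
  fold_of <- integer(N)
  for (cl in unique(t)) {
    idx <- which(t == cl)
    idx <- idx[sample.int(length(idx))]
    fold_of[idx] <- rep_len(seq_len(k), length(idx))
  }
  lapply(seq_len(k), function(f) {
    list(train = which(fold_of != f), val = which(fold_of == f))
  })
}

# z-score helper: fit on the training rows, apply to both.
.standardize_pair <- function(X_train, X_other = NULL) {
  ctr <- colMeans(X_train)
  scl <- apply(X_train, 2, stats::sd)
  scl[scl < 1e-12] <- 1
  tr <- sweep(sweep(X_train, 2, ctr, "-"), 2, scl, "/")
  ot <- if (is.null(X_other)) NULL else sweep(sweep(X_other, 2, ctr, "-"), 2, scl, "/")
  list(train = tr, other = ot, center = ctr, scale = scl)
}

# One init -> train -> predict pass on a standardized train/test pair.
.run_strategy <- function(strategy, Ztr, ttr, Zte, m1, seed, train_cfg) {
  net <- init_network(strategy, Ztr, ttr, m1, seed = seed)
  fit <- train_network(net, Ztr, ttr,
                       config = train_config(epochs = train_cfg$epochs,
                                             batch_size = train_cfg$batch_size,
                                             learning_rate = train_cfg$learning_rate,
                                             seed = seed,
                                             early_stop_patience = train_cfg$early_stop_patience))
  predict(fit$params, Zte, type = "prob")
}

#' Tune the hidden-layer size by stratified cross-validation
#'
#' Exhaustive search over a grid of hidden sizes: for each candidate `m1`,
#' a `k`-fold cross-validation runs initialize-and-train with the chosen
#' strategy and records the fold validation accuracies. The selected size
#' maximizes the mean-to-deviation ratio
#' \eqn{\mathrm{mean}/(\mathrm{sd} + 10^{-8})} — the most accurate *and*
#' stable configuration — with ties broken toward the smaller size.
#'
#' @param X raw feature matrix (z-scoring is refit inside every fold).
#' @param t integer labels.
#' @param strategy initialization strategy passed to [init_network()].
#' @param grid integer vector of candidate hidden sizes.
#' @param seed integer seed (folds and all fits derive from it).
#' @param k number of folds.
#' @param train_cfg a [train_config()] used for every fit.
#' @return object of class `"tuning_result"`: list with `grid`,
#'   `fold_accuracy` (matrix, folds x grid), `criterion`, `selected_m1`.
#' @export
tune_hidden_size <- function(X, t, strategy, grid, seed = 1L, k = 5L,
                             train_cfg = train_config()) {
  grid <- as.integer(grid)
  if (length(grid) == 0L) stop("`grid` of hidden sizes is empty")
  if (any(grid > ncol(X))) stop("grid contains sizes larger than D = ", ncol(X))
  X <- as.matrix(X)
  folds <- kfold_split(t, k = k, seed = seed)
  acc <- matrix(NA_real_, k, length(grid),
                dimnames = list(NULL, paste0("m1_", grid)))
  for (gi in seq_along(grid)) {
    for (fi in seq_len(k)) {
      fold <- folds[[fi]]
      std <- .standardize_pair(X[fold$train, , drop = FALSE],
                               X[fold$val, , drop = FALSE])
      probs <- .run_strategy(strategy, std$train, t[fold$train], std$other,
                             grid[gi], seed = seed + fi, train_cfg = train_cfg)
      acc[fi, gi] <- mean(max.col(probs, ties.method = "first") == t[fold$val])
    }
  }
  crit <- apply(acc, 2, function(a) mean(a) / (stats::sd(a) + 1e-8))
  sel <- grid[which.max(crit)]   # which.max takes the first, i.e. smallest m1
  structure(list(grid = grid, fold_accuracy = acc, criterion = crit,
                 selected_m1 = sel, strategy = strategy, seed = seed),
            class = "tuning_result")
}

#' @export
print.tuning_result <- function(x, ...) {
  cat("Hidden-size tuning (", x$strategy, "): selected m1 =", x$selected_m1, "\n")
  print(data.frame(m1 = x$grid,
                   mean_acc = colMeans(x$fold_accuracy),
                   sd_acc = apply(x$fold_accuracy, 2, stats::sd),
                   criterion = x$criterion, row.names = NULL))
  invisible(x)
}

#' Compare first-layer initialization strategies
#'
#' For every strategy and every seed: z-scores the training set (statistics
#' applied to the test set), fits the strategy's projection, initializes and
#' trains the network, and evaluates on the held-out test set. Reports per
#' strategy the mean and standard deviation over seeds of accuracy, class-wise
#' recall, weighted AUC and per-class AUC.
#'
#' @param X_train,t_train training features and labels.
#' @param X_test,t_test disjoint test features and labels.
#' @param seeds integer vector of seeds; each seed drives one full run.
#' @param strategies character vector of strategies to compare.
#' @param m1 hidden size: a single integer for all strategies or a named
#'   vector per strategy.
#' @param train_cfg a [train_config()].
#' @param class_names optional class names for the report columns.
#' @return object of class `"init_comparison"`: list with `summary` (data
#'   frame: one row per strategy, mean and sd columns for alpha, per-class
#'   tau, beta, per-class beta), `reports` (per strategy, per seed
#'   [evaluate_classifier()] reports), `m1`, `seeds`.
#' @export
compare_inits <- function(X_train, t_train, X_test, t_test, seeds,
                          strategies = c("random", "aen", "pca", "cka"),
                          m1 = 14L, train_cfg = train_config(),
                          class_names = NULL) {
  X_train <- as.matrix(X_train); X_test <- as.matrix(X_test)
  C <- max(t_train, t_test)
  if (is.null(class_names)) {
    class_names <- if (C == 3L) c("NC", "MCI", "AD") else paste0("class", seq_len(C))
  }
  m1_of <- function(s) {
    if (length(m1) == 1L && is.null(names(m1))) as.integer(m1) else as.integer(m1[[s]])
  }
  std <- .standardize_pair(X_train, X_test)

  reports <- lapply(strategies, function(s) {
    lapply(seeds, function(sd_i) {
      probs <- .run_strategy(s, std$train, t_train, std$other, m1_of(s),
                             seed = sd_i, train_cfg = train_cfg)
      evaluate_classifier(t_test, probs, class_names = class_names)
    })
  })
  names(reports) <- strategies

  row_of <- function(rep) {
    c(alpha = rep$alpha,
      stats::setNames(rep$tau, paste0("tau_", class_names)),
      beta = rep$beta,
      stats::setNames(rep$beta_per_class, paste0("beta_", class_names)))
  }
  summ <- do.call(rbind, lapply(strategies, function(s) {
    rows <- do.call(rbind, lapply(reports[[s]], row_of))
    mu <- colMeans(rows); sdv <- apply(rows, 2, stats::sd)
    data.frame(strategy = s, t(mu),
               t(stats::setNames(sdv, paste0(names(sdv), "_sd"))),
               check.names = FALSE, row.names = NULL)
  }))

  structure(list(summary = summ, reports = reports, m1 = m1, seeds = seeds,
                 class_names = class_names),
            class = "init_comparison")
}

#' @export
print.init_comparison <- function(x, digits = 3, ...) {
  cat("Initialization comparison over", length(x$seeds), "seeds (mean over seeds)\n")
  mean_cols <- !grepl("_sd$", names(x$summary))
  print(format(x$summary[, mean_cols], digits = digits), row.names = FALSE)
  invisible(x)
}
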