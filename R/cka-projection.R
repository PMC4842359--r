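# Learning the linear projection W by gradient ascent on the CKA coefficient,
# and the per-feature relevance it induces.

#' Squared Mahalanobis distances under a linear projection
#'
#' Pairwise squared distances
#' \eqn{d^2_W(x_i, x_j) = (x_i - x_j)^\top W^\top W (x_i - x_j)
#'      = \|W x_i - W x_j\|^2}:
#' Euclidean distances after mapping every sample through `W`. Computed on
#' the projected coordinates, so the cost is \eqn{O(N D m_1 + N^2 m_1)}.
#'
#' @param X numeric matrix, `N` samples in rows, `D` features in columns.
#' @param W projection matrix, `m1 x D` with `m1 <= D`.
#' @return symmetric `N x N` matrix with zero diagonal; round-off negatives
#'   are clipped at 0.
#' @export
sq_mahalanobis <- function(X, W) {
  X <- as.matrix(X); W <- as.matrix(W)
  if (ncol(W) != ncol(X)) {
    stop("dimension mismatch: W has ", ncol(W), " columns but X has ",
         ncol(X), " features")
  }
  Y <- X %*% t(W)                       # N x m1 projected samples
  sq <- rowSums(Y^2)
  D2 <- outer(sq, sq, "+") - 2 * tcrossprod(Y)
  D2[D2 < 0] <- 0
  diag(D2) <- 0
  (D2 + t(D2)) / 2
}

#' CKA objective of a projection
#'
#' Evaluates \eqn{\rho(K_W, B)}: squared Mahalanobis distances under `W` are
#' passed through the Gaussian kernel (bandwidth `sigma`) and aligned against
#' the label kernel of `t`. This is the function the pretraining maximizes
#' over `W`.
#'
#' @inheritParams sq_mahalanobis
#' @param t integer class labels, at least two distinct values.
#' @param sigma Gaussian kernel bandwidth (default 1; see [gaussian_kernel()]).
#' @return the alignment \eqn{\rho \in [0, 1]}.
#' @export
cka_objective <- function(W, X, t, sigma = 1) {
  if (length(unique(t)) < 2L) {
    stop("degenerate input: need at least 2 distinct labels to align against")
  }
  K <- gaussian_kernel(sq_mahalanobis(X, W), sigma)
  cka(K, label_kernel(t))
}

#' Analytic gradient of the CKA objective
#'
#' Gradient \eqn{\partial \rho / \partial W} of [cka_objective()] (the raw
#' coefficient, not its logarithm), obtained by the chain rule through the
#' Gaussian kernel. With \eqn{K_c = HKH}, \eqn{B_c = HBH},
#' \eqn{G = (B_c - \rho \frac{\|B_c\|}{\|K_c\|} K_c) / (\|K_c\| \|B_c\|)}
#' the derivative with respect to the kernel entries, and
#' \eqn{M = G \circ K}, the gradient collapses to
#' \deqn{\frac{\partial \rho}{\partial W}
#'   = -\frac{2}{\sigma^2} \, W X^\top L X, \qquad
#'   L = \mathrm{diag}(M 1) - M,}
#' a graph-Laplacian form costing \eqn{O(N^2 D)}.
#'
#' @inheritParams cka_objective
#' @return an `m1 x D` matrix of partial derivatives.
#' @export
cka_gradient <- function(W, X, t, sigma = 1) {
  X <- as.matrix(X); W <- as.matrix(W)
  if (length(unique(t)) < 2L) {
    stop("degenerate input: need at least 2 distinct labels to align against")
  }
  K <- gaussian_kernel(sq_mahalanobis(X, W), sigma)
  B <- label_kernel(t)
  Kc <- center_kernel(K)
  Bc <- center_kernel(B)
  nk <- sqrt(sum(Kc^2))
  nb <- sqrt(sum(Bc^2))
  if (nk < 1e-300) stop("degenerate input: constant kernel, gradient undefined")
  rho <- sum(Kc * Bc) / (nk * nb)
  G <- (Bc - rho * (nb / nk) * Kc) / (nk * nb)   # d rho / d K
  M <- G * K                                     # chain through exp(-d/2s^2)
  L <- diag(rowSums(M)) - M
  -(2 / sigma^2) * (W %*% crossprod(X, L %*% X))
}

#' Optimizer settings for the CKA projection
#'
#' @param max_iter maximum number of accepted ascent steps.
#' @param step initial step size for the ascent.
#' @param tol convergence tolerance on the relative increase of the
#'   alignment between accepted steps.
#' @param init `"pca"` (principal-axis loadings, deterministic) or
#'   `"random"` (seeded Gaussian entries).
#' @param seed integer seed controlling the random initialization.
#' @param max_halvings backtracking budget: how many times a rejected step is
#'   halved before the run stops.
#' @return a list of class `"cka_optimizer_config"`.
#' @export
optimizer_config <- function(max_iter = 500L, step = 1, tol = 1e-6,
                             init = c("pca", "random"), seed = 1L,
                             max_halvings = 20L) {
  init <- match.arg(init)
  stopifnot(max_iter >= 1, step > 0, tol > 0, max_halvings >= 1)
  structure(list(max_iter = as.integer(max_iter), step = step, tol = tol,
                 init = init, seed = as.integer(seed),
                 max_halvings = as.integer(max_halvings)),
            class = "cka_optimizer_config")
}

#' Learn a projection by maximizing centered kernel alignment
#'
#' Full-batch gradient ascent on \eqn{\rho(K_W, B)} with backtracking step
#' halving: a proposed step is accepted only if it increases the alignment,
#' so the trace of accepted \eqn{\rho} values is non-decreasing by
#' construction. The run stops when the relative improvement drops below
#' `config$tol`, when the backtracking budget is exhausted, or at
#' `config$max_iter`.
#'
#' Features are z-scored internally by default (the statistics are stored in
#' the returned model, and `W` acts on the standardized scale). The ascent
#' starts from PCA loadings of the standardized data, rescaled so the median
#' projected squared distance is 1, which puts the unit-bandwidth Gaussian
#' kernel in its sensitive regime.
#'
#' @inheritParams cka_objective
#' @param m1 output dimension of the projection, `2 <= m1 <= D`. The learned
#'   `m1 x D` matrix is meant to initialize the first layer of a network with
#'   `m1` hidden units, so the projection is always to a lower dimension than
#'   the input; with fewer samples than `m1` the projection would overfit and
#'   an error is raised.
#' @param config an [optimizer_config()].
#' @param standardize z-score the columns of `X` before learning (default
#'   `TRUE`). Set to `FALSE` when `X` is already on a common scale or when
#'   supplying a custom `init` matrix.
#' @param init optional `m1 x D` numeric matrix used as the starting point
#'   instead of the configured initialization (used verbatim, no rescaling).
#' @return an object of class `"cka_projection"`: list with elements `W`
#'   (`m1 x D`), `trace` (data frame of accepted iterations and their
#'   \eqn{\rho}), `rho` (final alignment), `relevance` (max-normalized
#'   per-feature relevance), `relevance_raw`, `config`, `seed`, `center`,
#'   `scale` (z-scoring statistics or `NULL`), `feature_names`.
#' @export
fit_cka_projection <- function(X, t, m1, config = optimizer_config(),
                               standardize = TRUE, init = NULL) {
  X <- as.matrix(X)
  N <- nrow(X); D <- ncol(X)
  m1 <- as.integer(m1)
  if (m1 > D) {
    stop("projection must reduce dimension: m1 = ", m1, " exceeds D = ", D)
  }
  if (m1 < 2L) stop("`m1` must be at least 2")
  if (N <= m1) {
    stop("need more samples than projection dimensions (N = ", N,
         ", m1 = ", m1, "): the projection would overfit")
  }
  if (length(t) != N) stop("length of `t` must match rows of `X`")
  feature_names <- colnames(X)
  dimnames(X) <- NULL

  center <- NULL; scl <- NULL
  if (standardize) {
    center <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl < 1e-12] <- 1        # constant columns carry no signal; leave them
    X <- sweep(sweep(X, 2, center, "-"), 2, scl, "/")
  }

  if (!is.null(init)) {
    W <- as.matrix(init)
    if (nrow(W) != m1 || ncol(W) != D) {
      stop("`init` must be an m1 x D matrix (", m1, " x ", D, ")")
    }
  } else if (config$init == "pca") {
    W <- pca_projection(X, m1)
    W <- .rescale_projection(W, X)
  } else {
    set.seed(config$seed)
    W <- matrix(stats::rnorm(m1 * D, sd = 1 / sqrt(D)), m1, D)
    W <- .rescale_projection(W, X)
  }

  rho <- cka_objective(W, X, t)
  trace_it <- 0L
  trace_rho <- rho
  step <- config$step

  for (iter in seq_len(config$max_iter)) {
    G <- cka_gradient(W, X, t)
    accepted <- FALSE
    for (h in seq_len(config$max_halvings)) {
      W_new <- W + step * G
      rho_new <- tryCatch(cka_objective(W_new, X, t), error = function(e) -Inf)
      if (is.finite(rho_new) && rho_new > rho) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    rel <- (rho_new - rho) / max(abs(rho), 1e-12)
    W <- W_new
    rho <- rho_new
    trace_it <- c(trace_it, iter)
    trace_rho <- c(trace_rho, rho)
    step <- step * 2                    # cautious re-expansion after success
    if (rel < config$tol) break
  }

  rel_raw <- relevance(W, normalize = FALSE)
  rel_norm <- if (max(rel_raw) > 0) rel_raw / max(rel_raw) else rel_raw
  structure(list(
    W = W,
    trace = data.frame(iteration = trace_it, rho = trace_rho),
    rho = rho,
    relevance = rel_norm,
    relevance_raw = rel_raw,
    config = config,
    seed = config$seed,
    center = center,
    scale = scl,
    feature_names = feature_names
  ), class = "cka_projection")
}

# Rescale W so the median projected squared distance is 1.
.rescale_projection <- function(W, X) {
  D2 <- sq_mahalanobis(X, W)
  med <- stats::median(D2[upper.tri(D2)])
  if (is.finite(med) && med > 0) W / sqrt(med) else W
}

#' @export
print.cka_projection <- function(x, ...) {
  cat("CKA projection model\n")
  cat("  W:", nrow(x$W), "x", ncol(x$W), "\n")
  cat("  final alignment rho:", format(x$rho, digits = 6), "\n")
  cat("  accepted steps:", nrow(x$trace) - 1L, "\n")
  invisible(x)
}

#' Per-feature relevance of a projection
#'
#' The relevance of feature \eqn{d} is the mean squared weight tying it to
#' the projection outputs, \eqn{\varrho_d = \frac{1}{m_1}\sum_u w_{ud}^2}:
#' features the embedding depends on strongly get large values. For
#' reporting, the vector is normalized by its maximum so the most relevant
#' feature scores 1 (the raw expectation is available with
#' `normalize = FALSE`).
#'
#' @param W projection matrix, `m1 x D`.
#' @param normalize divide by the maximum (default `TRUE`).
#' @return a nonnegative length-`D` vector (named after `W`'s columns if
#'   present). An all-zero `W` yields an all-zero vector with a warning.
#' @export
relevance <- function(W, normalize = TRUE) {
  W <- as.matrix(W)
  if (length(W) == 0L) stop("`W` is empty")
  r <- colMeans(W^2)
  if (normalize) {
    m <- max(r)
    if (m > 0) r <- r / m else warning("all-zero projection: relevance is identically zero")
  }
  r
}

#' Aggregate relevance over named feature groups
#'
#' Averages a per-feature relevance vector within groups (e.g. the
#' morphometric feature families: cortical volume, subcortical volume,
#' surface area, thickness average, thickness standard deviation), for
#' grouped bar reporting.
#'
#' @param rel length-`D` relevance vector.
#' @param groups length-`D` character/factor vector assigning each feature to
#'   a group.
#' @return a named vector of group mean relevances, in first-appearance order.
#' @export
group_relevance <- function(rel, groups) {
  if (length(rel) != length(groups)) {
    stop("`rel` and `groups` must have the same length")
  }
  groups <- factor(groups, levels = unique(as.character(groups)))
  tapply(rel, groups, mean)
}
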