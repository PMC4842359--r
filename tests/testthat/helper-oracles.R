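# Independent brute-force oracles used across the suite. They deliberately
# materialize the dense centering matrix and loop over scalars, so they share
# no code path with the implementation they check.

# CKA via the explicit dense centering matrix H = I - n^-1 11'.
cka_dense_oracle <- function(K, B) {
  n <- nrow(K)
  H <- diag(n) - matrix(1 / n, n, n)
  Kc <- H %*% K %*% H
  Bc <- H %*% B %*% H
  sum(Kc * Bc) / (sqrt(sum(Kc^2)) * sqrt(sum(Bc^2)))
}

# Scalar-loop evaluation of the projected-Gaussian kernel alignment.
cka_objective_oracle <- function(W, X, t, sigma = 1) {
  n <- nrow(X)
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- W %*% (X[i, ] - X[j, ])
      K[i, j] <- exp(-sum(d^2) / (2 * sigma^2))
    }
  }
  B <- outer(t, t, function(a, b) as.numeric(a == b))
  cka_dense_oracle(K, B)
}

# Central finite differences of f at W, elementwise.
finite_diff <- function(f, W, h = 1e-6) {
  G <- W * 0
  for (i in seq_along(W)) {
    Wp <- W; Wp[i] <- Wp[i] + h
    Wm <- W; Wm[i] <- Wm[i] - h
    G[i] <- (f(Wp) - f(Wm)) / (2 * h)
  }
  G
}

# Max elementwise mismatch of `analytic` vs `reference`, relative to the
# reference gradient's scale.
grad_rel_error <- function(analytic, reference) {
  max(abs(analytic - reference)) / max(abs(reference))
}

# One-vs-rest AUC as the normalized Mann-Whitney U statistic (rank form,
# ties get half credit) -- independent of the trapezoidal ROC code.
auc_mann_whitney <- function(scores, positive) {
  positive <- as.logical(positive)
  r <- rank(scores)
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Random PSD matrix of size n.
random_psd <- function(n) {
  A <- matrix(stats::rnorm(n * n), n)
  crossprod(A)
}

# Small seeded 2-class dataset separated along feature 1 only.
separable_toy <- function(N = 60, D = 5, gap = 3, seed = 1) {
  set.seed(seed)
  t <- rep(1:2, each = N / 2)
  X <- matrix(stats::rnorm(N * D), N, D)
  X[, 1] <- X[, 1] + (t - 1.5) * gap
  list(X = X, t = t)
}
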