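# Unsupervised pretraining baselines: PCA loadings and a single-hidden-layer
# autoencoder.

#' PCA projection matrix
#'
#' Top-`m1` principal-axis loadings of `X` (expected z-scored), returned as
#' an `m1 x D` matrix whose rows are unit-norm eigenvectors of the sample
#' covariance in descending eigenvalue order. For reproducibility each row's
#' sign is fixed so its largest-magnitude entry is positive.
#'
#' @param X numeric matrix, samples in rows.
#' @param m1 number of components, at most `min(N - 1, D)`.
#' @return an `m1 x D` projection matrix with orthonormal rows.
#' @export
pca_projection <- function(X, m1) {
  X <- as.matrix(X)
  m1 <- as.integer(m1)
  kmax <- min(nrow(X) - 1L, ncol(X))
  if (m1 > kmax) {
    stop("m1 = ", m1, " exceeds the ", kmax,
         " principal components available for ", nrow(X), " samples and ",
         ncol(X), " features")
  }
  rot <- stats::prcomp(X, center = TRUE, scale. = FALSE)$rotation[, seq_len(m1), drop = FALSE]
  W <- t(rot)
  for (u in seq_len(nrow(W))) {
    j <- which.max(abs(W[u, ]))
    if (W[u, j] < 0) W[u, ] <- -W[u, ]
  }
  dimnames(W) <- NULL
  W
}

#' Autoencoder settings
#'
#' @param m1 size of the encoding (hidden) layer.
#' @param epochs training epochs.
#' @param learning_rate SGD step size.
#' @param batch_size minibatch size.
#' @param seed integer seed for initialization and shuffling.
#' @return a list of class `"aen_config"`.
#' @export
aen_config <- function(m1, epochs = 200L, learning_rate = 0.05,
                       batch_size = 32L, seed = 1L) {
  stopifnot(m1 >= 1, epochs >= 1, learning_rate > 0, batch_size >= 1)
  structure(list(m1 = as.integer(m1), epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "aen_config")
}

#' Autoencoder encoder weights
#'
#' Trains a single-hidden-layer autoencoder — sigmoid encoder
#' \eqn{h = \phi(b_1 + W_1 x)} and linear decoder
#' \eqn{\hat x = b_2 + W_2 h} — on the mean squared reconstruction error with
#' seeded minibatch SGD (untied weights). The returned encoder matrix serves
#' as an unsupervised first-layer initialization.
#'
#' @param X numeric matrix, samples in rows; expected z-scored.
#' @param config an [aen_config()].
#' @param full return the whole autoencoder (encoder + decoder + loss
#'   history) instead of just the encoder matrix.
#' @return the `m1 x D` encoder weight matrix (default), or a list with
#'   `encoder`, `b1`, `decoder`, `b2`, `loss` when `full = TRUE`.
#' @export
aen_fit <- function(X, config, full = FALSE) {
  X <- as.matrix(X)
  N <- nrow(X); D <- ncol(X)
  m1 <- config$m1
  if (m1 > D) stop("encoding size m1 = ", m1, " exceeds D = ", D)
  set.seed(config$seed)
  r <- 1 / sqrt(D)
  W1 <- matrix(stats::runif(m1 * D, -r, r), m1, D)
  b1 <- stats::runif(m1, -r, r)
  r2 <- 1 / sqrt(m1)
  W2 <- matrix(stats::runif(D * m1, -r2, r2), D, m1)
  b2 <- stats::runif(D, -r2, r2)
  lr <- config$learning_rate
  loss_hist <- numeric(config$epochs)

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(N)
    starts <- seq(1L, N, by = config$batch_size)
    batch_losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, N)]
      Xb <- X[idx, , drop = FALSE]
      n <- nrow(Xb)
      H <- nn_sigmoid(Xb %*% t(W1) + matrix(b1, n, m1, byrow = TRUE))
      Xhat <- H %*% t(W2) + matrix(b2, n, D, byrow = TRUE)
      R <- Xhat - Xb
      batch_losses[bi] <- mean(R^2)
      dXhat <- 2 * R / (n * D)                       # d mean(R^2) / d Xhat
      dW2 <- crossprod(dXhat, H)
      db2 <- colSums(dXhat)
      dH <- (dXhat %*% W2) * .sigmoid_deriv(H)
      dW1 <- crossprod(dH, Xb)
      db1 <- colSums(dH)
      W2 <- W2 - lr * dW2; b2 <- b2 - lr * db2
      W1 <- W1 - lr * dW1; b1 <- b1 - lr * db1
    }
    loss_hist[epoch] <- mean(batch_losses)
    if (!is.finite(loss_hist[epoch])) {
      stop("autoencoder training diverged at epoch ", epoch,
           " (learning rate ", lr, ")")
    }
  }

  if (full) {
    list(encoder = W1, b1 = b1, decoder = W2, b2 = b2, loss = loss_hist)
  } else {
    W1
  }
}
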