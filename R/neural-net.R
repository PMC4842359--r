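# Feedforward softmax classifier trained by backpropagation, with pluggable
# first-layer initialization (random / PCA / autoencoder / CKA projection).

#' Sigmoid activation
#'
#' The hidden-layer nonlinearity \eqn{\phi(z) = (\tanh z + 1)/2}, a sigmoid
#' mapping onto `(0, 1)`. Built on `tanh`, so it is numerically stable for
#' large `|z|`.
#'
#' @param z numeric scalar, vector or matrix.
#' @return same shape as `z`, values in `(0, 1)`.
#' @export
nn_sigmoid <- function(z) (tanh(z) + 1) / 2

# derivative of nn_sigmoid expressed through its value s: s' = 2 s (1 - s)
.sigmoid_deriv <- function(s) 2 * s * (1 - s)

# Row-wise numerically stable softmax (max subtraction).
.softmax <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

#' Forward pass of the classifier
#'
#' Propagates samples through the hidden sigmoid layers
#' \eqn{h^l = \phi(b^l + W^l h^{l-1})} (with \eqn{h^0 = x}) and the softmax
#' output layer. Each output row is a probability vector over the `C`
#' classes: positive entries summing to one, interpretable as
#' \eqn{P(t = c \mid x)}.
#'
#' @param params a network as returned by [init_network()]: list with
#'   `layers`, each layer a list of `W` (`m_out x m_in`) and `b`
#'   (length `m_out`).
#' @param X numeric matrix, samples in rows (`N x D`).
#' @return list with `hidden` (list of `N x m_l` activation matrices, one per
#'   hidden layer) and `probs` (`N x C` class probabilities).
#' @export
nn_forward <- function(params, X) {
  X <- as.matrix(X)
  L <- length(params$layers)
  hidden <- vector("list", L - 1L)
  H <- X
  for (l in seq_len(L)) {
    layer <- params$layers[[l]]
    if (ncol(layer$W) != ncol(H)) {
      stop("dimension mismatch at layer ", l, ": weights expect ",
           ncol(layer$W), " inputs, got ", ncol(H))
    }
    Z <- H %*% t(layer$W) + matrix(layer$b, nrow(H), length(layer$b), byrow = TRUE)
    if (l < L) {
      H <- nn_sigmoid(Z)
      hidden[[l]] <- H
    } else {
      P <- .softmax(Z)
    }
  }
  list(hidden = hidden, probs = P)
}

#' Mean negative log-likelihood of the true classes
#'
#' The training loss: \eqn{\frac{1}{N}\sum_i -\log P(t_i \mid x_i)} with the
#' probabilities floored at `1e-12` so a confidently wrong prediction yields
#' a large finite value rather than infinity.
#'
#' @param probs `N x C` matrix of class probabilities (rows sum to 1).
#' @param t integer labels in `1..C`.
#' @return a nonnegative scalar.
#' @export
nn_nll <- function(probs, t) {
  probs <- as.matrix(probs)
  t <- as.integer(t)
  if (any(t < 1L) || any(t > ncol(probs))) {
    stop("labels must lie in 1..C with C = ", ncol(probs))
  }
  p <- probs[cbind(seq_along(t), t)]
  mean(-log(pmax(p, 1e-12)))
}

#' Initialize a one-hidden-layer softmax network
#'
#' Builds the `D -> m1 -> C` network. The first-layer weights come from the
#' chosen projection strategy; everything else (both bias vectors and the
#' output weights) is always drawn at random from a seeded
#' uniform\eqn{(-r, r)} with \eqn{r = 1/\sqrt{\mathrm{fan~in}}}, whatever the
#' strategy — pretraining fixes only where the hidden layer starts.
#'
#' Strategies: `"random"` draws the first layer like the rest; `"pca"` uses
#' the top-`m1` principal-axis loadings of `X`; `"aen"` uses the encoder of a
#' single-hidden-layer autoencoder trained on `X`; `"cka"` uses the
#' supervised CKA projection fitted on `(X, t)`. `X` is expected to be
#' z-scored already (training-set statistics); the projections are computed
#' on it as given.
#'
#' @param strategy one of `"random"`, `"pca"`, `"aen"`, `"cka"`.
#' @param X standardized feature matrix (`N x D`), samples in rows.
#' @param t integer labels in `1..C` (used by the CKA strategy and to count
#'   classes).
#' @param m1 hidden-layer size, `m1 <= D`.
#' @param seed integer seed for all random draws (and for the AEN/CKA fits
#'   when `projection` is not supplied).
#' @param projection optional precomputed `m1 x D` matrix (or a
#'   `"cka_projection"` model) to use as the first layer, bypassing the
#'   strategy's own fit.
#' @param n_classes number of classes `C`; defaults to `max(t)`.
#' @return an object of class `"nn_params"`: list with `layers` (two layers
#'   of `W`, `b`), `sizes`, `strategy`, `seed`.
#' @export
init_network <- function(strategy = c("random", "pca", "aen", "cka"),
                         X, t, m1, seed = 1L, projection = NULL,
                         n_classes = NULL) {
  strategy <- match.arg(strategy)
  X <- as.matrix(X)
  D <- ncol(X)
  m1 <- as.integer(m1)
  if (m1 > D) stop("hidden size m1 = ", m1, " exceeds input dimension D = ", D)
  t <- as.integer(t)
  C <- if (is.null(n_classes)) max(t) else as.integer(n_classes)

  if (!is.null(projection)) {
    W1 <- if (inherits(projection, "cka_projection")) projection$W else as.matrix(projection)
    if (nrow(W1) != m1 || ncol(W1) != D) {
      stop("supplied projection is ", nrow(W1), " x ", ncol(W1),
           " but the first layer needs ", m1, " x ", D)
    }
  } else {
    W1 <- switch(strategy,
      random = NULL,                       # drawn below with the other params
      pca = pca_projection(X, m1),
      aen = aen_fit(X, aen_config(m1 = m1, seed = seed)),
      cka = fit_cka_projection(X, t, m1,
                               config = optimizer_config(seed = seed),
                               standardize = FALSE)$W
    )
  }

  set.seed(seed)
  r1 <- 1 / sqrt(D)
  if (is.null(W1)) W1 <- matrix(stats::runif(m1 * D, -r1, r1), m1, D)
  b1 <- stats::runif(m1, -r1, r1)
  r2 <- 1 / sqrt(m1)
  W2 <- matrix(stats::runif(C * m1, -r2, r2), C, m1)
  b2 <- stats::runif(C, -r2, r2)

  structure(list(
    layers = list(list(W = W1, b = b1), list(W = W2, b = b2)),
    sizes = c(D, m1, C),
    strategy = strategy,
    seed = as.integer(seed)
  ), class = "nn_params")
}

#' @export
print.nn_params <- function(x, ...) {
  cat("Feedforward softmax network ", paste(x$sizes, collapse = "-"),
      " (init: ", x$strategy, ")\n", sep = "")
  invisible(x)
}

#' Training settings
#'
#' @param epochs number of passes over the training data.
#' @param batch_size minibatch size for stochastic gradient descent.
#' @param learning_rate step size.
#' @param seed integer seed controlling the epoch shuffles (and the held-out
#'   split if early stopping is on).
#' @param early_stop_patience if a positive integer, 10% of the data is held
#'   out and training stops once its loss has not improved for this many
#'   epochs; `NULL` (default) disables early stopping.
#' @return a list of class `"nn_train_config"`.
#' @export
train_config <- function(epochs = 300L, batch_size = 32L, learning_rate = 0.05,
                         seed = 1L, early_stop_patience = NULL) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed),
                 early_stop_patience = early_stop_patience),
            class = "nn_train_config")
}

# Backpropagation gradients of the mean NLL on a batch.
# Returns a list parallel to params$layers with dW, db per layer.
.nn_gradients <- function(params, X, t) {
  n <- nrow(X)
  C <- params$sizes[length(params$sizes)]
  fwd <- nn_forward(params, X)
  Y <- matrix(0, n, C)
  Y[cbind(seq_len(n), as.integer(t))] <- 1
  grads <- vector("list", length(params$layers))

  delta <- (fwd$probs - Y) / n                       # N x C
  for (l in rev(seq_along(params$layers))) {
    H_in <- if (l == 1L) X else fwd$hidden[[l - 1L]]
    grads[[l]] <- list(dW = crossprod(delta, H_in), db = colSums(delta))
    if (l > 1L) {
      delta <- (delta %*% params$layers[[l]]$W) * .sigmoid_deriv(fwd$hidden[[l - 1L]])
    }
  }
  grads
}

#' Train a network by minibatch stochastic gradient descent
#'
#' Minimizes the mean negative log-likelihood by backpropagation with plain
#' SGD. Minibatches are reshuffled every epoch with a seeded generator, so
#' the whole run is reproducible. With `early_stop_patience` set, a seeded
#' 10% split is held out and training stops when its loss stalls.
#'
#' @param params an initialized [init_network()] object.
#' @param X standardized feature matrix (`N x D`).
#' @param t integer labels in `1..C`.
#' @param config a [train_config()].
#' @return list with `params` (trained network), `loss` (epoch-mean training
#'   loss) and, when early stopping is active, `val_loss`.
#' @export
train_network <- function(params, X, t, config = train_config()) {
  X <- as.matrix(X)
  t <- as.integer(t)
  if (length(unique(t)) < 2L) stop("need labels from at least 2 classes")
  set.seed(config$seed)

  val_idx <- integer(0)
  if (!is.null(config$early_stop_patience)) {
    val_idx <- sample(nrow(X), max(1L, round(0.1 * nrow(X))))
  }
  tr_idx <- setdiff(seq_len(nrow(X)), val_idx)
  Xtr <- X[tr_idx, , drop = FALSE]; ttr <- t[tr_idx]

  loss_hist <- numeric(0)
  val_hist <- numeric(0)
  best_val <- Inf; best_params <- params; stall <- 0L

  for (epoch in seq_len(config$epochs)) {
    ord <- sample(nrow(Xtr))
    starts <- seq(1L, length(ord), by = config$batch_size)
    batch_losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, length(ord))]
      Xb <- Xtr[idx, , drop = FALSE]; tb <- ttr[idx]
      batch_losses[bi] <- nn_nll(nn_forward(params, Xb)$probs, tb)
      if (config$learning_rate > 0) {
        g <- .nn_gradients(params, Xb, tb)
        for (l in seq_along(params$layers)) {
          params$layers[[l]]$W <- params$layers[[l]]$W - config$learning_rate * g[[l]]$dW
          params$layers[[l]]$b <- params$layers[[l]]$b - config$learning_rate * g[[l]]$db
        }
      }
    }
    epoch_loss <- mean(batch_losses)
    if (!is.finite(epoch_loss)) {
      stop("training diverged at epoch ", epoch, ": loss is not finite ",
           "(learning rate ", config$learning_rate, ")")
    }
    loss_hist <- c(loss_hist, epoch_loss)

    if (length(val_idx)) {
      vl <- nn_nll(nn_forward(params, X[val_idx, , drop = FALSE])$probs, t[val_idx])
      val_hist <- c(val_hist, vl)
      if (vl < best_val - 1e-9) {
        best_val <- vl; best_params <- params; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$early_stop_patience) {
          params <- best_params
          break
        }
      }
    }
  }

  out <- list(params = params, loss = loss_hist)
  if (length(val_idx)) out$val_loss <- val_hist
  out
}

#' Predict class labels
#'
#' @param object a trained `"nn_params"` network.
#' @param X feature matrix on the same (standardized) scale the network was
#'   trained on.
#' @param type `"class"` for hard labels in `1..C`, `"prob"` for the softmax
#'   probability matrix.
#' @param ... unused.
#' @return integer labels or an `N x C` probability matrix.
#' @export
predict.nn_params <- function(object, X, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  P <- nn_forward(object, X)$probs
  if (type == "prob") P else max.col(P, ties.method = "first")
}
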