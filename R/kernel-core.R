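# Kernel matrices, centering and the centered kernel alignment coefficient.

#' Double-center a kernel matrix
#'
#' Computes \eqn{HKH} with \eqn{H = I - n^{-1} 1 1^\top} the usual centering
#' matrix, without ever materializing \eqn{H}: row means, column means and the
#' grand mean are subtracted instead, which costs \eqn{O(n^2)} time and memory.
#' Rows and columns of the result each sum to zero (up to round-off).
#'
#' @param K a square numeric matrix (a Gram/kernel matrix).
#' @return the centered matrix \eqn{HKH}, same dimensions as `K`.
#' @examples
#' center_kernel(diag(2))        # [[.5,-.5],[-.5,.5]]
#' center_kernel(matrix(1, 4, 4))  # all zeros: H annihilates constants
#' @export
center_kernel <- function(K) {
  K <- as.matrix(K)
  if (nrow(K) != ncol(K)) {
    stop("`K` must be square, got ", nrow(K), "x", ncol(K))
  }
  rm <- rowMeans(K)
  cm <- colMeans(K)
  gm <- mean(K)
  sweep(sweep(K, 1, rm, "-"), 2, cm, "-") + gm
}

#' Label (target) kernel
#'
#' Builds the binary co-membership matrix \eqn{B} with \eqn{b_{ij} = 1} iff
#' samples \eqn{i} and \eqn{j} carry the same class label. Under a label sort
#' the matrix is block diagonal, one all-ones block per class. It is the
#' "ideal" kernel the feature kernel is aligned against.
#'
#' @param t integer (or factor) vector of class labels.
#' @return an `N x N` binary matrix with unit diagonal.
#' @examples
#' label_kernel(c(1, 1, 2))
#' @export
label_kernel <- function(t) {
  if (length(t) == 0L) stop("label vector is empty")
  t <- as.vector(t)
  B <- outer(t, t, "==") * 1
  dimnames(B) <- NULL
  B
}

#' Gaussian kernel from squared distances
#'
#' Maps a matrix of squared pairwise distances to kernel values
#' \eqn{k_{ij} = \exp(-d^2_{ij} / 2\sigma^2)}. The Gaussian is positive
#' definite and infinitely divisible; with squared Mahalanobis distances it
#' gives the feature-similarity kernel that the projection learning aligns
#' with the label kernel.
#'
#' @param sq_dists symmetric nonnegative matrix of squared distances with
#'   zero diagonal.
#' @param sigma kernel bandwidth, a positive scalar. Defaults to 1: when the
#'   distances come from a learned projection `W`, the scale of `W` absorbs
#'   the bandwidth, so a free `sigma` would be redundant.
#' @return a matrix of kernel values in `(0, 1]` with unit diagonal.
#' @export
gaussian_kernel <- function(sq_dists, sigma = 1) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0) {
    stop("`sigma` must be a positive finite scalar")
  }
  sq_dists <- as.matrix(sq_dists)
  if (any(sq_dists < 0)) stop("squared distances must be nonnegative")
  exp(-sq_dists / (2 * sigma^2))
}

#' Centered kernel alignment (CKA)
#'
#' The normalized Frobenius inner product of two double-centered Gram
#' matrices,
#' \deqn{\rho(K, B) = \frac{\langle HKH, HBH \rangle_F}
#'                         {\|HKH\|_F \, \|HBH\|_F},}
#' a number in \eqn{[0, 1]} for positive semidefinite inputs. It measures how
#' similar the sample geometries induced by the two kernels are; against a
#' label kernel it quantifies how well a feature representation separates the
#' classes. Centering makes the coefficient invariant to constant offsets and
#' positive rescaling of either kernel.
#'
#' @param K,B square numeric matrices of equal dimension.
#' @return the alignment coefficient, a scalar in `[0, 1]`.
#' @export
cka <- function(K, B) {
  K <- as.matrix(K); B <- as.matrix(B)
  if (nrow(K) != ncol(K) || nrow(B) != ncol(B) || nrow(K) != nrow(B)) {
    stop("`K` and `B` must be square matrices of equal dimension")
  }
  Kc <- center_kernel(K)
  Bc <- center_kernel(B)
  nk <- sqrt(sum(Kc^2))
  nb <- sqrt(sum(Bc^2))
  if (nk < 1e-300 || nb < 1e-300) {
    stop("degenerate input: a kernel is constant, its centered norm is zero, ",
         "so the alignment is undefined")
  }
  rho <- sum(Kc * Bc) / (nk * nb)
  # PSD inputs give rho >= 0; tolerate tiny negative round-off only
  if (rho < 0 && rho >= -1e-12) rho <- 0
  rho
}
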