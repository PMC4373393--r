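# Fixed-point (Fast) independent component analysis, symmetric variant with
# the tanh contrast. The data are centered and PCA-whitened internally; the
# rotation maximizing negentropy is found by the fixed-point iteration with
# symmetric (parallel) decorrelation. Encoding is a pure linear map -- this is
# the no-competition baseline of the model comparison.

sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  vals <- pmax(e$values, 1e-12)
  e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors) %*% W
}

#' Fit FastICA
#'
#' Learns an unmixing matrix `W` (components x inputs) such that `y = W (x -
#' mean)` has maximally non-Gaussian, decorrelated components, and the mixing
#' matrix `V = pinv(W)` such that `x ~ V y + mean`. Uses the symmetric
#' fixed-point iteration with nonlinearity `tanh`; convergence when the
#' maximum change of any row direction is below `tol`. If the centered data
#' are rank deficient, the number of components is reduced with a warning.
#'
#' @param X input matrix, inputs x samples (at least `n_components` samples).
#' @param n_components number of independent components.
#' @param seed integer seed for the random rotation initialization.
#' @param tol convergence tolerance on row directions (default 1e-4).
#' @param max_iter iteration cap (default 500).
#' @return Object of class `c("fastica", "coding_model")` with elements `W`,
#'   `V`, `mean`, `n_iter`, `converged`.
#' @export
fastica <- function(X, n_components, seed = 1, tol = 1e-4, max_iter = 500) {
  X <- as.matrix(X)
  m <- nrow(X); n <- ncol(X)
  if (n < n_components) stop("need at least n_components samples")
  mu <- rowMeans(X)
  Xc <- X - mu

  # internal PCA whitening
  e <- eigen(tcrossprod(Xc) / n, symmetric = TRUE)
  rank <- sum(e$values > max(e$values) * 1e-10)
  if (rank < n_components) {
    warning("data rank ", rank, " < n_components; reducing to ", rank)
    n_components <- rank
  }
  K <- diag(1 / sqrt(e$values[1:n_components]), n_components) %*%
    t(e$vectors[, 1:n_components, drop = FALSE])
  Z <- K %*% Xc                                     # whitened, comp x n

  W <- with_seed(seed,
    matrix(stats::rnorm(n_components^2), n_components, n_components))
  W <- sym_decorrelate(W)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    U <- W %*% Z
    G <- tanh(U)
    W1 <- G %*% t(Z) / n - diag(rowMeans(1 - G^2), n_components) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(1 - abs(rowSums(W1 * W))))     # row-direction change
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }

  Wfull <- W %*% K                                  # comp x inputs
  Vfull <- e$vectors[, 1:n_components, drop = FALSE] %*%
    diag(sqrt(e$values[1:n_components]), n_components) %*% t(W)
  structure(list(W = Wfull, V = Vfull, mean = mu,
                 n_units = n_components, n_iter = it, converged = converged,
                 seed = seed),
            class = c("fastica", "coding_model"))
}

#' Encode inputs with a fitted FastICA model
#'
#' Pure linear map `y = W (x - mean)`: no iteration, no rectification, no
#' competition. Components have unit variance and are pairwise decorrelated
#' on the training data.
#'
#' @param object fitted [fastica] model.
#' @param newdata input matrix, inputs x samples.
#' @param ... unused.
#' @return Signed activity matrix, components x samples.
#' @export
predict.fastica <- function(object, newdata, ...) {
  object$W %*% (as.matrix(newdata) - object$mean)
}

#' @export
print.fastica <- function(x, ...) {
  cat(sprintf("<fastica: %d components, %d inputs, %s in %d iterations>\n",
              x$n_units, ncol(x$W),
              if (x$converged) "converged" else "not converged", x$n_iter))
  invisible(x)
}

#' @export
coef.fastica <- function(object, ...) object$V
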