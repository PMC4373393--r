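# Non-negative matrix factorization with a hard sparseness constraint on the
# code (NMFSC). The input matrix X (inputs x samples) is factorized as
# X ~ V Y with V >= 0 (basis columns) and Y >= 0 (codes in columns). V is
# updated by the Euclidean multiplicative rule
#   V <- V * (X Y') / (V Y Y'),
# Y by a subtractive gradient step
#   Y <- Y - mu * V' (V Y - X)
# followed by a column-wise projection to the target Hoyer sparseness.
# Competition between units is therefore top-down subtractive inhibition of
# the input plus the sparseness projection.

project_columns <- function(Y, s_y) {
  for (j in seq_len(ncol(Y))) {
    col <- Y[, j]
    if (any(col != 0)) Y[, j] <- project_sparseness(col, s_y)
  }
  Y
}

recon_error <- function(X, V, Y) sum((X - V %*% Y)^2)

# One Y pass: subtractive step with halving line search (projected when a
# sparseness target is set, multiplicative otherwise, as "sparseness 0" means
# no constraint).
nmfsc_y_step <- function(X, V, Y, s_y, mu, eps = 1e-9) {
  if (is.null(s_y) || s_y <= 0) {
    Y <- Y * (crossprod(V, X)) / (crossprod(V, V %*% Y) + eps)
    return(list(Y = Y, mu = mu, err = recon_error(X, V, Y)))
  }
  err0 <- recon_error(X, V, Y)
  for (try in 1:20) {
    Ynew <- Y - mu * crossprod(V, V %*% Y - X)
    Ynew <- project_columns(Ynew, s_y)
    err <- recon_error(X, V, Ynew)
    if (err <= err0) return(list(Y = Ynew, mu = mu * 1.2, err = err))
    mu <- mu / 2
  }
  list(Y = Y, mu = mu, err = err0)
}

#' Fit NMF with a sparseness constraint
#'
#' Alternates the multiplicative basis update with the subtractive,
#' sparseness-projected code update until the relative change of the squared
#' reconstruction error drops below `tol`. Basis columns are rescaled to unit
#' L2 norm after every update (the code rows absorb the scale, leaving the
#' reconstruction unchanged). `s_y = 0` (or `NULL`) disables the constraint,
#' in which case the code update is the plain multiplicative rule.
#'
#' @param X non-negative input matrix, inputs x samples.
#' @param n_units number of basis vectors / code units.
#' @param s_y target Hoyer sparseness of every code column (default 0.85, the
#'   level at which occlusion robustness peaks).
#' @param mu0 initial step size of the code update; halved whenever a step
#'   would increase the reconstruction error.
#' @param max_epochs cap on alternating passes.
#' @param tol relative reconstruction-error change for convergence.
#' @param seed integer seed for the random initialization.
#' @return Object of class `c("nmfsc", "coding_model")` with elements `V`
#'   (basis), `s_y`, `mu`, `err_trace`, `converged`.
#' @export
nmfsc <- function(X, n_units, s_y = 0.85, mu0 = 1, max_epochs = 200,
                  tol = 1e-5, seed = 1) {
  if (any(X < 0)) stop("X must be non-negative")
  m <- nrow(X); n <- ncol(X)
  eps <- 1e-9
  init <- with_seed(seed, list(
    V = matrix(stats::runif(m * n_units), m, n_units),
    Y = matrix(stats::runif(n_units * n), n_units, n)))
  V <- init$V
  V <- sweep(V, 2, pmax(sqrt(colSums(V^2)), eps), "/")
  Y <- init$Y
  if (!is.null(s_y) && s_y > 0) Y <- project_columns(Y, s_y)

  mu <- mu0
  err_trace <- numeric(0)
  err_prev <- recon_error(X, V, Y)
  converged <- FALSE
  for (epoch in seq_len(max_epochs)) {
    st <- nmfsc_y_step(X, V, Y, s_y, mu, eps)
    Y <- st$Y; mu <- st$mu
    V <- V * (X %*% t(Y)) / (V %*% Y %*% t(Y) + eps)
    nrm <- pmax(sqrt(colSums(V^2)), eps)
    V <- sweep(V, 2, nrm, "/")
    Y <- Y * nrm                       # keep V Y unchanged by the rescaling
    if (!is.null(s_y) && s_y > 0) Y <- project_columns(Y, s_y)
    err <- recon_error(X, V, Y)
    err_trace <- c(err_trace, err)
    if (abs(err_prev - err) <= tol * max(err_prev, eps)) {
      converged <- TRUE
      break
    }
    err_prev <- err
  }
  structure(list(V = V, s_y = s_y, mu = mu, n_units = n_units,
                 err_trace = err_trace, converged = converged, seed = seed),
            class = c("nmfsc", "coding_model"))
}

#' Encode inputs with a fitted NMFSC model
#'
#' Keeps the basis fixed and re-runs the code optimization for the new
#' inputs: codes are initialized at the rectified projection `V' x` and
#' iterated (subtractive step plus sparseness projection) until the maximum
#' code change falls below `tol`. Deterministic.
#'
#' @param object fitted [nmfsc] model.
#' @param newdata non-negative input matrix, inputs x samples.
#' @param max_iter,tol iteration controls.
#' @param ... unused.
#' @return Non-negative activity matrix, units x samples.
#' @export
predict.nmfsc <- function(object, newdata, max_iter = 200, tol = 1e-5, ...) {
  X <- as.matrix(newdata)
  V <- object$V
  s_y <- object$s_y
  Y <- pmax(crossprod(V, X), 0)
  if (!is.null(s_y) && s_y > 0) Y <- project_columns(Y, s_y)
  mu <- object$mu
  for (it in seq_len(max_iter)) {
    st <- nmfsc_y_step(X, V, Y, s_y, mu)
    delta <- max(abs(st$Y - Y))
    Y <- st$Y; mu <- st$mu
    if (delta < tol) break
  }
  Y
}

#' @export
print.nmfsc <- function(x, ...) {
  cat(sprintf(
    "<nmfsc: %d units, %d inputs, code sparseness %s, %s after %d epochs>\n",
    x$n_units, nrow(x$V),
    if (is.null(x$s_y) || x$s_y <= 0) "unconstrained" else format(x$s_y),
    if (x$converged) "converged" else "stopped", length(x$err_trace)))
  invisible(x)
}

#' @export
coef.nmfsc <- function(object, ...) object$V
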