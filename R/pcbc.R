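# Predictive coding / biased competition via divisive input modulation (DIM).
# Error units divide the input by its top-down reconstruction,
#   e = x / (eps1 + V' y),
# output units update multiplicatively from the inhibited input,
#   y <- (eps2 + y) * (W e),
# and learning is the multiplicative rule
#   W <- W * (1 + beta * y (e' - 1)),
# whose fixed point is e = 1, i.e. perfect reconstruction. Feedforward W and
# feedback V hold the same pattern and differ only in normalization: W rows
# sum to 1, V rows have maximum 1.

feedback_from <- function(W) {
  mx <- apply(W, 1, max)
  W / pmax(mx, 1e-12)
}

#' Error-unit activity
#'
#' Elementwise division of the input by its reconstruction: `e = x / (eps1 +
#' V' y)`. Equal input and reconstruction give `e = 1`; an unreconstructed
#' input (`y = 0`) gives a large error that drives the initial activation.
#'
#' @param x non-negative input vector (or inputs x samples matrix).
#' @param V feedback weights, units x inputs.
#' @param y non-negative activity vector (or units x samples matrix).
#' @param eps1 small constant preventing division by zero.
#' @return Non-negative error values, same shape as `x`.
#' @export
pcbc_error <- function(x, V, y, eps1 = 1e-6) {
  x / (eps1 + crossprod(V, y))
}

#' Settle PC/BC activities on an input
#'
#' Starting from `y = 0`, alternates the error computation and the
#' multiplicative output update for `n_iter` iterations. Activities stay
#' non-negative throughout. Works on a single input vector or a whole batch
#' (inputs x samples).
#'
#' @param x input vector or matrix.
#' @param state fitted or initialized [pcbc] model.
#' @param n_iter number of error/output iterations (default: the model's
#'   test-time setting, 200).
#' @return List with `y` (activities) and `e` (final error-unit values).
#' @export
pcbc_settle <- function(x, state, n_iter = state$n_iter) {
  x <- as.matrix(x)
  y <- matrix(0, state$n_units, ncol(x))
  e <- x
  for (i in seq_len(n_iter)) {
    e <- pcbc_error(x, state$V, y, state$eps1)
    y <- (state$eps2 + y) * (state$W %*% e)
  }
  list(y = y, e = e)
}

#' One PC/BC learning step
#'
#' `W <- W * (1 + beta * y (e' - 1))`, clipped at zero, rows renormalized to
#' sum 1, and the feedback matrix recomputed as the row-max normalization of
#' `W`. If the error equals 1 everywhere (perfect reconstruction) or the unit
#' is silent, its weights do not change.
#'
#' @param state a [pcbc] model.
#' @param y settled activity vector for one input.
#' @param e its final error-unit values.
#' @return The state with updated `W` and `V`.
#' @export
pcbc_learn_step <- function(state, y, e) {
  W <- state$W * (1 + state$beta * outer(as.vector(y), as.vector(e) - 1))
  W[W < 0] <- 0
  rs <- rowSums(W)
  W <- W / pmax(rs, 1e-12)
  state$W <- W
  state$V <- feedback_from(W)
  state
}

#' Train a PC/BC network
#'
#' Presents `n_presentations` inputs sampled with replacement from the
#' training matrix; each presentation settles for `n_iter_train` iterations
#' and applies one learning step. Deterministic given `seed`.
#'
#' @param X non-negative training inputs, inputs x samples.
#' @param n_units number of output units.
#' @param n_presentations training presentations (the full-scale experiment
#'   uses 100,000; scale down for quick runs).
#' @param beta learning rate.
#' @param eps1,eps2 small constants of the error and output updates.
#' @param n_iter_train settling iterations per training presentation.
#' @param n_iter settling iterations at encoding time (default 200).
#' @param init_noise weight initialization noise amplitude, relative to the
#'   mean input value (see Details).
#' @param seed integer seed (weight init and presentation order).
#'
#' @details Each unit's weights are initialized to a randomly drawn training
#' input plus uniform noise, then row-normalized. Anchoring the units to data
#' points breaks the symmetry between them: with homogeneous random rows the
#' winner-take-most settling dynamics let a single unit win every input, and
#' the network collapses onto one global-average template instead of a
#' distributed dictionary.
#' @return Object of class `c("pcbc", "coding_model")`.
#' @export
pcbc <- function(X, n_units, n_presentations = 100000, beta = 0.01,
                 eps1 = 1e-6, eps2 = 1e-3, n_iter_train = 50, n_iter = 200,
                 init_noise = 0.5, seed = 1) {
  X <- as.matrix(X)
  if (any(X < 0)) stop("X must be non-negative")
  m <- nrow(X)
  init <- with_seed(seed, {
    anchors <- sample.int(ncol(X), n_units, replace = n_units > ncol(X))
    list(W = t(X[, anchors, drop = FALSE]) + init_noise * mean(X) *
           matrix(stats::runif(n_units * m), n_units, m),
         order = sample.int(ncol(X), n_presentations, replace = TRUE))
  })
  W <- init$W / rowSums(init$W)
  state <- structure(list(W = W, V = feedback_from(W), beta = beta,
                          eps1 = eps1, eps2 = eps2, n_iter = n_iter,
                          n_units = n_units, ablated = FALSE, seed = seed),
                     class = c("pcbc", "coding_model"))
  for (t in seq_len(n_presentations)) {
    x <- X[, init$order[t]]
    st <- pcbc_settle(x, state, n_iter_train)
    state <- pcbc_learn_step(state, st$y, st$e)
  }
  state
}

#' Encode inputs with a fitted PC/BC model
#'
#' Settles the network on each input for the model's test-time iteration
#' count (1 if the model was ablated) and returns the activities.
#'
#' @param object fitted [pcbc] model.
#' @param newdata non-negative input matrix, inputs x samples.
#' @param ... unused.
#' @return Non-negative activity matrix, units x samples.
#' @export
predict.pcbc <- function(object, newdata, ...) {
  pcbc_settle(as.matrix(newdata), object)$y
}

#' @export
print.pcbc <- function(x, ...) {
  cat(sprintf("<pcbc: %d units, %d inputs, %d settling iterations%s>\n",
              x$n_units, ncol(x$W), x$n_iter,
              if (x$ablated) " (competition ablated)" else ""))
  invisible(x)
}

#' @export
coef.pcbc <- function(object, ...) object$W
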