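# Rate-based Hebbian neural network (HNN): threshold-linear units driven by
# feedforward weights Wff and inhibited through learned non-negative lateral
# weights C (zero diagonal). Rates follow
#   tau_r * dr_j/dt = -r_j + [Wff_j . x - sum_k C[k, j] r_k]+
# integrated by explicit Euler (step 1) for a fixed number of steps per
# image, with a fast calcium trace Ca tracking r. Feedforward learning is
# covariance Hebb with an Oja-style decay regulated by a per-unit homeostatic
# term theta (driving each unit's long-run mean activity toward a common
# target p); lateral learning is the anti-Hebb rule
#   dC[k, j] = eta_lat * (Ca_k Ca_j - p^2), clipped at 0,
# so inhibition grows between coactive units and decays between units that
# never fire together. The numeric constants are this package's
# concretization of the mechanism, not values from any reference network.

#' Settle HNN rates on an input
#'
#' Euler integration of the threshold-linear dynamics for `steps` unit time
#' steps, starting at `r = 0`. Rates are non-negative at every step. Works on
#' a single input vector or a batch (inputs x samples).
#'
#' @param x input vector or matrix.
#' @param state an [hnn] model (fitted or initialized).
#' @param steps integration steps (default: the model's setting, 100).
#' @return List with `r` (settled rates, units x samples) and `ca` (calcium
#'   trace at the last step).
#' @export
hnn_settle <- function(x, state, steps = state$steps) {
  ff <- state$Wff %*% as.matrix(x)
  r <- matrix(0, nrow(ff), ncol(ff))
  ca <- r
  for (t in seq_len(steps)) {
    inh <- crossprod(state$C, r)
    r <- r + (pmax(ff - inh, 0) - r) / state$tau_r
    ca <- ca + (r - ca) / state$tau_ca
  }
  list(r = r, ca = ca)
}

#' One HNN learning step
#'
#' Covariance Hebb with Oja decay on the feedforward weights, homeostatic
#' adaptation of the per-unit regulation term, and the anti-Hebbian lateral
#' update. Running means of the input and of the calcium trace are updated
#' with rate `mean_rate`.
#'
#' @param state an [hnn] model.
#' @param x the presented input vector.
#' @param ca the unit calcium traces after settling.
#' @return The state with updated `Wff`, `C`, `theta` and running means.
#' @export
hnn_learn_step <- function(state, x, ca) {
  ca <- as.vector(ca)
  state$xbar <- (1 - state$mean_rate) * state$xbar + state$mean_rate * x
  state$cabar <- (1 - state$mean_rate) * state$cabar + state$mean_rate * ca

  hebb <- outer(ca - state$cabar, x - state$xbar)
  decay <- (state$theta * ca^2) * state$Wff
  state$Wff <- state$Wff + state$eta_ff * (hebb - decay)

  state$theta <- pmax(
    state$theta + state$eta_theta * (state$cabar - state$p) / state$p, 0.01)

  C <- state$C + state$eta_lat * (outer(ca, ca) - state$p^2)
  C[C < 0] <- 0
  diag(C) <- 0
  state$C <- C
  state
}

#' Train a Hebbian network with lateral inhibition
#'
#' Presents `n_presentations` inputs sampled with replacement; each
#' presentation settles the rate dynamics for `steps` time steps and applies
#' one learning step. Deterministic given `seed`.
#'
#' @param X non-negative training inputs, inputs x samples.
#' @param n_units number of units.
#' @param n_presentations training presentations (the full-scale experiment
#'   uses 200,000; scale down for quick runs).
#' @param tau_r,tau_ca rate and calcium-trace time constants (steps).
#' @param eta_ff,eta_lat,eta_theta feedforward, lateral, and homeostatic
#'   learning rates.
#' @param p target long-run mean activity per unit; the anti-Hebb rule decays
#'   lateral weights toward coactivations at chance level `p^2`.
#' @param steps integration steps per presented image.
#' @param mean_rate update rate of the running input/trace means.
#' @param seed integer seed (weight init and presentation order).
#' @return Object of class `c("hnn", "coding_model")` with `Wff`, `C`,
#'   `theta` and the configuration.
#' @export
hnn <- function(X, n_units, n_presentations = 200000, tau_r = 10,
                tau_ca = 2, eta_ff = 2e-3, eta_lat = 3e-3, eta_theta = 0.01,
                p = 0.1, steps = 100, mean_rate = 0.01, seed = 1) {
  X <- as.matrix(X)
  m <- nrow(X)
  init <- with_seed(seed, list(
    W = matrix(stats::runif(n_units * m), n_units, m),
    order = sample.int(ncol(X), n_presentations, replace = TRUE)))
  W <- init$W / sqrt(rowSums(init$W^2))
  state <- structure(list(
    Wff = W, C = matrix(0, n_units, n_units),
    theta = rep(1, n_units), xbar = rowMeans(X), cabar = rep(0, n_units),
    tau_r = tau_r, tau_ca = tau_ca, eta_ff = eta_ff, eta_lat = eta_lat,
    eta_theta = eta_theta, p = p, steps = steps, mean_rate = mean_rate,
    n_units = n_units, ablated = FALSE, seed = seed),
    class = c("hnn", "coding_model"))
  for (t in seq_len(n_presentations)) {
    x <- X[, init$order[t]]
    st <- hnn_settle(x, state)
    state <- hnn_learn_step(state, x, st$ca)
  }
  state
}

#' Encode inputs with a fitted HNN
#'
#' Settles the rate dynamics on each input with frozen weights and returns
#' the settled rates.
#'
#' @param object fitted [hnn] model.
#' @param newdata non-negative input matrix, inputs x samples.
#' @param ... unused.
#' @return Non-negative rate matrix, units x samples.
#' @export
predict.hnn <- function(object, newdata, ...) {
  hnn_settle(as.matrix(newdata), object)$r
}

#' @export
print.hnn <- function(x, ...) {
  cat(sprintf(
    "<hnn: %d units, %d inputs, %d Euler steps%s, mean lateral weight %.3g>\n",
    x$n_units, ncol(x$Wff), x$steps,
    if (x$ablated) " (lateral inhibition ablated)" else "",
    mean(x$C)))
  invisible(x)
}

#' @export
coef.hnn <- function(object, ...) object$Wff

#' Switch off a model's competition mechanism
#'
#' Returns a copy of the model with its competitive mechanism disabled: for
#' [pcbc], encoding uses exactly one error/output iteration instead of the
#' full settling; for [hnn], all lateral inhibitory weights are set to zero
#' (feedforward weights untouched). Used to measure how much of the occlusion
#' robustness the competition itself contributes.
#'
#' @param object a fitted model.
#' @param ... unused.
#' @return The ablated model.
#' @export
ablate <- function(object, ...) UseMethod("ablate")

#' @rdname ablate
#' @export
ablate.pcbc <- function(object, ...) {
  object$n_iter <- 1L
  object$ablated <- TRUE
  object
}

#' @rdname ablate
#' @export
ablate.hnn <- function(object, ...) {
  object$C[] <- 0
  object$ablated <- TRUE
  object
}
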