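# Hoyer sparseness and its projection operator. The sparseness measure
# relates the L1 to the L2 norm: 0 for a uniform vector, 1 for a one-hot
# vector. The projection finds the closest non-negative vector (in Euclidean
# distance) with a prescribed sparseness, preserving the L2 norm, by
# alternating between the L1 hyperplane and the L2 sphere and zeroing
# negative coordinates.

#' Hoyer sparseness of a vector
#'
#' `s(v) = (sqrt(n) - ||v||_1 / ||v||_2) / (sqrt(n) - 1)`: 0 when all entries
#' are equal (densest), 1 when exactly one entry is non-zero (sparsest).
#'
#' @param v non-negative numeric vector (use `abs()` for signed codes).
#' @return Sparseness value in `[0, 1]`.
#' @export
hoyer_sparseness <- function(v) {
  if (all(v == 0)) stop("sparseness is undefined for the zero vector")
  n <- length(v)
  (sqrt(n) - sum(abs(v)) / l2norm(v)) / (sqrt(n) - 1)
}

#' Project a vector to a target Hoyer sparseness
#'
#' Returns the closest (Euclidean) non-negative vector with Hoyer sparseness
#' `s`. By default the L2 norm of `v` is preserved and the L1 norm is set to
#' the value implied by `s`; with `preserve_l2 = FALSE` the L1 norm is
#' preserved instead.
#'
#' @param v numeric vector (treated via its non-negative target; `v` itself
#'   may contain the result of a gradient step and so have negative entries).
#' @param s target sparseness in `[0, 1]`.
#' @param preserve_l2 keep `||v||_2` fixed (default) or `||v||_1`.
#' @return Non-negative vector with sparseness `s` (within 1e-6).
#' @export
project_sparseness <- function(v, s, preserve_l2 = TRUE) {
  if (s < 0 || s > 1) stop("target sparseness must be in [0, 1]")
  n <- length(v)
  l2 <- l2norm(v)
  if (l2 == 0) stop("cannot project the zero vector")
  if (preserve_l2) {
    l1 <- l2 * (sqrt(n) - s * (sqrt(n) - 1))
  } else {
    l1 <- sum(abs(v))
    l2 <- l1 / (sqrt(n) - s * (sqrt(n) - 1))
  }
  if (s == 1) {  # limit case: one-hot on the largest coordinate
    out <- numeric(n)
    out[which.max(v)] <- l2
    return(out)
  }
  hoyer_project(v, l1, l2)
}

# Alternating hyperplane/sphere projection with negative-coordinate zeroing.
hoyer_project <- function(x, l1, l2) {
  n <- length(x)
  zero <- rep(FALSE, n)
  s <- x + (l1 - sum(x)) / n
  for (iter in seq_len(n + 1)) {
    m <- ifelse(zero, 0, l1 / sum(!zero))
    w <- s - m
    a <- sum(w^2)
    b <- 2 * sum(w * m)
    cc <- sum(m^2) - l2^2
    disc <- max(b^2 - 4 * a * cc, 0)
    alpha <- if (a > 0) (-b + sqrt(disc)) / (2 * a) else 0
    s <- m + alpha * w
    if (all(s >= 0)) return(s)
    zero <- zero | (s < 0)
    s[zero] <- 0
    nfree <- sum(!zero)
    if (nfree == 0) break
    s[!zero] <- s[!zero] - (sum(s) - l1) / nfree
  }
  # guard: the zeroing loop removes at least one coordinate per pass, so this
  # is unreachable for valid (l1, l2); fall back to the one-hot limit
  out <- numeric(n)
  out[which.max(x)] <- l2
  out
}
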