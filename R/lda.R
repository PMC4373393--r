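# Linear discriminant analysis on activity codes: class means, pooled
# within-class covariance, empirical priors, prediction by the linear
# discriminant score. The pooled covariance is shrunk toward a scaled
# identity when singular, which sparse codes routinely make it (silent units
# give zero-variance coordinates that stock LDA implementations reject).

#' Fit a linear discriminant classifier
#'
#' @param x feature matrix, samples x features (transpose activity matrices,
#'   which are units x samples).
#' @param grouping class labels, one per row of `x`; every class needs at
#'   least 2 samples.
#' @param shrink shrinkage added to the pooled covariance when it is
#'   singular, as a multiple of `trace(S)/d` on the diagonal.
#' @return Object of class `lda_model` with class means, the (possibly
#'   shrunk) pooled covariance factorization, and empirical priors.
#' @export
lda_fit <- function(x, grouping, shrink = 1e-6) {
  x <- as.matrix(x)
  g <- factor(grouping)
  counts <- table(g)
  if (length(counts) < 2) stop("need at least 2 classes")
  if (any(counts < 2)) stop("every class needs at least 2 samples")
  n <- nrow(x); d <- ncol(x); k <- length(counts)

  M <- rowsum(x, g) / as.vector(counts)        # class means, k x d
  Xc <- x - M[as.integer(g), , drop = FALSE]
  S <- crossprod(Xc) / (n - k)

  lambda <- shrink * sum(diag(S)) / d
  A <- tryCatch({
    R <- chol(S)
    backsolve(R, forwardsolve(t(R), t(M)))     # S^{-1} M'
  }, error = function(e) NULL)
  if (is.null(A)) {
    S <- S + diag(max(lambda, 1e-12), d)
    R <- chol(S)
    A <- backsolve(R, forwardsolve(t(R), t(M)))
  }
  structure(list(means = M, coef = A,           # coef: d x k, S^{-1} m_c
                 const = -0.5 * colSums(t(M) * A) +
                   log(as.vector(counts) / n),
                 classes = levels(g)),
            class = "lda_model")
}

#' Predict classes with a fitted linear discriminant
#'
#' @param object an `lda_model`.
#' @param newdata samples x features matrix.
#' @param ... unused.
#' @return Character vector of predicted class labels.
#' @export
predict.lda_model <- function(object, newdata, ...) {
  scores <- as.matrix(newdata) %*% object$coef +
    rep(object$const, each = nrow(as.matrix(newdata)))
  object$classes[max.col(scores, ties.method = "first")]
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model: %d classes, %d features>\n",
              length(x$classes), ncol(x$means)))
  invisible(x)
}
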