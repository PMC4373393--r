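# Robustness evaluation: LDA accuracy under increasing occlusion, cosine
# stability of the population code, mean Hoyer sparseness, reverse-correlation
# receptive fields, and the lateral-inhibition selectivity analysis.

# activities of a model on preprocessed inputs; model = NULL is the raw-input
# baseline (the classifier sees the 288-dim on/off vectors directly)
encode_inputs <- function(model, X) {
  if (is.null(model)) X else stats::predict(model, X)
}

cosine <- function(a, b) {
  na <- l2norm(a); nb <- l2norm(b)
  if (na == 0 || nb == 0) return(0)   # zero codes contribute 0 by convention
  sum(a * b) / (na * nb)
}

#' Preprocessed inputs over an occlusion grid
#'
#' Occludes the batch at every level (with the same occlusion RNG, so all
#' models can be shown identical occluded images) and preprocesses each
#' version once.
#'
#' @param pp a fitted `preprocessor`.
#' @param batch an [image_batch] of raw test images.
#' @param levels occlusion levels (the standard grid is 0 to 0.60 in steps
#'   of 0.05).
#' @param seed occlusion RNG seed.
#' @return Named list (one entry per level) of `preprocess()` results.
#' @export
occlusion_grid_inputs <- function(pp, batch, levels = seq(0, 0.6, by = 0.05),
                                  seed = 99) {
  out <- lapply(levels, function(lv) {
    preprocess(pp, if (lv == 0) batch else occlude(batch, lv, seed))
  })
  names(out) <- format(levels)
  out
}

#' Classification accuracy under occlusion
#'
#' Trains an LDA classifier on the model's codes for the (non-occluded)
#' training inputs, then measures classification accuracy of the codes of
#' occluded test inputs at every occlusion level. With `model = NULL` the
#' classifier runs directly on the preprocessed input vectors, giving the
#' raw-data baseline curve.
#'
#' @param model a fitted coding model, or `NULL` for the raw-input baseline.
#' @param train_inputs result of `preprocess()` on the training batch (or a
#'   list with `X` and `labels`).
#' @param test_grid result of [occlusion_grid_inputs] on the test batch.
#' @return Named numeric vector of accuracies, one per occlusion level.
#' @export
accuracy_curve <- function(model, train_inputs, test_grid) {
  codes_tr <- encode_inputs(model, train_inputs$X)
  clf <- lda_fit(t(codes_tr), train_inputs$labels)
  vapply(test_grid, function(te) {
    codes <- encode_inputs(model, te$X)
    mean(predict(clf, t(codes)) == as.character(te$labels))
  }, numeric(1))
}

#' Cosine stability of a population code under occlusion
#'
#' Mean, over the test images, of the cosine of the angle between the
#' activity vector for the intact image and the activity vector for the same
#' image occluded at `level`. A perfectly occlusion-invariant code scores 1.
#' Pairs where either code is the zero vector contribute 0.
#'
#' @param model a fitted coding model.
#' @param clean_inputs `preprocess()` result for the intact test batch.
#' @param occluded_inputs `preprocess()` result for the same batch occluded.
#' @return Mean cosine in `[-1, 1]`.
#' @export
cosine_stability <- function(model, clean_inputs, occluded_inputs) {
  Y0 <- encode_inputs(model, clean_inputs$X)
  Y1 <- encode_inputs(model, occluded_inputs$X)
  mean(vapply(seq_len(ncol(Y0)), function(j) cosine(Y0[, j], Y1[, j]),
              numeric(1)))
}

#' Mean Hoyer sparseness of a model's code
#'
#' Mean Hoyer sparseness of the per-image activity vectors over a set of
#' (non-occluded) inputs. Signed codes (FastICA) are measured on their
#' absolute values; all-zero codes are skipped.
#'
#' @param model a fitted coding model.
#' @param inputs `preprocess()` result (or any list with `X`).
#' @return Mean sparseness in `[0, 1]`.
#' @export
mean_code_sparseness <- function(model, inputs) {
  Y <- abs(encode_inputs(model, inputs$X))
  s <- apply(Y, 2, function(v) if (all(v == 0)) NA_real_
             else hoyer_sparseness(v))
  mean(s, na.rm = TRUE)
}

#' Receptive field by reverse correlation
#'
#' Probes the model with images containing `n_dots` randomly placed
#' unit-intensity dots on a zero background, preprocessed like any other
#' input, and returns for each requested unit the response-weighted average
#' of the probe input vectors, recombined (on minus off) into a square map.
#'
#' @param model a fitted coding model.
#' @param pp the fitted `preprocessor`.
#' @param units unit indices to map.
#' @param n_probes number of random-dot probe images.
#' @param seed probe RNG seed.
#' @param n_dots dots per probe image (default 90).
#' @param probe_size probe image side in raw pixels (default 28).
#' @return List of `side x side` signed matrices, one per unit.
#' @export
reverse_correlation_rf <- function(model, pp, units, n_probes = 5000,
                                   seed = 7, n_dots = 90, probe_size = 28) {
  px <- array(0, dim = c(n_probes, probe_size, probe_size))
  for (i in seq_len(n_probes)) {
    dots <- with_seed(substream_seed(seed, i),
                      sample.int(probe_size^2, n_dots))
    img <- numeric(probe_size^2)
    img[dots] <- 1
    px[i, , ] <- matrix(img, probe_size, probe_size)
  }
  probes <- preprocess(pp, image_batch(px, integer(n_probes)))
  Y <- encode_inputs(model, probes$X)
  lapply(units, function(u) {
    unsplit_on_off(as.vector(probes$X %*% Y[u, ]) / n_probes, pp$side)
  })
}

#' Recombine a unit's on/off weights into a display image
#'
#' On-channel weights minus off-channel weights, reshaped to the image grid,
#' with a symmetric display range about zero recorded in the `"zmax"`
#' attribute (so the maximum weight maps to white, zero to mid gray, and the
#' minimum to black).
#'
#' @param on,off the on- and off-half of a unit's weight vector (each of
#'   length `side^2`), or a single full weight vector if `off` is missing.
#' @return A `side x side` signed matrix with attribute `zmax`.
#' @export
weight_image <- function(on, off) {
  if (missing(off)) {
    w <- unsplit_on_off(on)
  } else {
    side <- as.integer(sqrt(length(on)))
    w <- matrix(on - off, side, side)
  }
  attr(w, "zmax") <- max(abs(w), 1e-12)
  w
}

#' Correlation of unit weights with class templates
#'
#' For every unit, the Pearson correlation between its weight vector and its
#' best-matching class-mean input template, a summary of how digit-like the
#' learned weight patterns are. Models whose learning rule is mean-centering
#' (the covariance-learning [hnn]) are compared against centered templates
#' (class mean minus global mean), since a perfectly class-selective
#' covariance unit converges to the centered template, not the raw one;
#' non-negative models ([pcbc], [nmfsc]) are compared against the raw class
#' means.
#'
#' @param model a fitted coding model.
#' @param inputs `preprocess()` result with `X` and `labels` (training set).
#' @return Numeric vector: each unit's maximum class-template correlation.
#' @export
class_template_correlation <- function(model, inputs) {
  templates <- vapply(sort(unique(inputs$labels)), function(cl) {
    rowMeans(inputs$X[, inputs$labels == cl, drop = FALSE])
  }, numeric(nrow(inputs$X)))
  if (inherits(model, "hnn")) templates <- templates - rowMeans(inputs$X)
  W <- coef(model)
  if (inherits(model, "fastica") || inherits(model, "nmfsc")) W <- t(W)
  cc <- suppressWarnings(stats::cor(t(W), templates))
  apply(cc, 1, max)
}

#' Selectivity of lateral inhibition
#'
#' For randomly sampled units of a trained [hnn], ranks each unit's outgoing
#' inhibition targets by lateral weight (ties broken by unit index) and
#' compares the feedforward-weight cosine similarity of the `top_k` most
#' inhibited targets against the `top_k` least inhibited ones. A positive
#' statistic means units inhibit most strongly the units whose feedforward
#' weights resemble their own.
#'
#' @param state a trained [hnn] model.
#' @param n_neurons number of units to sample.
#' @param top_k targets per end of the ranking.
#' @param seed sampling seed.
#' @return List with `statistic` (mean top-minus-bottom similarity
#'   difference), `per_neuron` (the per-unit differences), and `targets`
#'   (each sampled unit's full ranked target list).
#' @export
lateral_selectivity <- function(state, n_neurons = 10, top_k = 10, seed = 5) {
  n <- state$n_units
  stopifnot(n >= 2 * top_k + 1)
  sel <- with_seed(seed, sample.int(n, n_neurons))
  targets <- list()
  per <- numeric(n_neurons)
  for (i in seq_along(sel)) {
    u <- sel[i]
    others <- setdiff(seq_len(n), u)
    ord <- others[order(-state$C[u, others], others)]  # outgoing inhibition
    sims <- vapply(ord, function(k) cosine(state$Wff[u, ], state$Wff[k, ]),
                   numeric(1))
    # all outgoing weights tied (e.g. ablated network): no selectivity
    per[i] <- if (diff(range(state$C[u, others])) == 0) 0 else
      mean(sims[seq_len(top_k)]) -
      mean(sims[seq(length(ord) - top_k + 1, length(ord))])
    targets[[i]] <- ord
  }
  list(statistic = mean(per), per_neuron = per, neurons = sel,
       targets = targets)
}

#' Plot a model's unit weight patterns
#'
#' Draws a grid of on-minus-off weight images (white = maximum, gray = zero,
#' black = minimum), one per unit.
#'
#' @param x a fitted coding model.
#' @param units unit indices to draw (default: up to the first 25).
#' @param ... passed to [graphics::image].
#' @export
plot.coding_model <- function(x, units = NULL, ...) {
  W <- coef(x)
  if (inherits(x, "fastica") || inherits(x, "nmfsc")) W <- t(W)
  if (is.null(units)) units <- seq_len(min(25, nrow(W)))
  nc <- ceiling(sqrt(length(units)))
  nr <- ceiling(length(units) / nc)
  op <- graphics::par(mfrow = c(nr, nc), mar = c(0.2, 0.2, 0.2, 0.2))
  on.exit(graphics::par(op), add = TRUE)
  for (u in units) {
    w <- weight_image(W[u, ])
    z <- attr(w, "zmax")
    graphics::image(t(w)[, rev(seq_len(nrow(w)))], zlim = c(-z, z),
                    col = grDevices::gray.colors(64, 0, 1), axes = FALSE, ...)
  }
  invisible(x)
}

#' @export
summary.coding_model <- function(object, ...) {
  print(object)
  invisible(object)
}
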