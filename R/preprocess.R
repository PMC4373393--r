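# Retina/LGN-style preprocessing: antialiased bicubic downscaling to 12x12,
# spectral whitening with the f * exp(-(f/f0)^4) filter, and splitting the
# signed whitened image into concatenated non-negative on/off channels
# (on-center and off-center LGN pathways). Occlusion deletes a fixed fraction
# of a digit's non-zero pixels before any of this.

# Keys bicubic kernel (a = -0.5), the kernel behind MATLAB imresize's default.
keys_cubic <- function(x) {
  ax <- abs(x)
  ifelse(ax <= 1, 1.5 * ax^3 - 2.5 * ax^2 + 1,
         ifelse(ax < 2, -0.5 * ax^3 + 2.5 * ax^2 - 4 * ax + 2, 0))
}

# 1-D resize matrix (m_out x n_in) for scale factor s, antialiased when s < 1
# by stretching the kernel support to 4/s; edge handling by index clamping and
# row normalization.
resize_matrix <- function(n_in, scale) {
  n_out <- ceiling(n_in * scale)
  kw <- if (scale < 1) scale else 1           # kernel rescale for antialias
  M <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    u <- i / scale + 0.5 * (1 - 1 / scale)    # center in input coordinates
    j <- floor(u - 2 / kw):ceiling(u + 2 / kw)
    w <- kw * keys_cubic(kw * (u - j))
    j <- pmin(pmax(j, 1), n_in)               # replicate edges
    keep <- w != 0
    for (k in which(keep)) M[i, j[k]] <- M[i, j[k]] + w[k]
    M[i, ] <- M[i, ] / sum(M[i, ])
  }
  M
}

#' Downscale a batch of square images
#'
#' Separable antialiased bicubic (Keys kernel) resize, matching the behaviour
#' of a default bicubic image resize with antialiasing. Output values are
#' clipped to `[0, 1]`, and pixels whose magnitude falls below `1e-3` are
#' snapped to exactly 0 so the digit/background distinction that occlusion
#' relies on survives interpolation ringing.
#'
#' @param batch an [image_batch] of square images.
#' @param factor linear scale factor (default 0.40, mapping 28x28 to 12x12).
#' @return An [image_batch] of downscaled images.
#' @export
downscale <- function(batch, factor = 0.40) {
  d <- dim(batch$pixels)
  if (d[2] != d[3]) stop("images must be square")
  M <- resize_matrix(d[2], factor)
  m <- nrow(M)
  out <- array(0, dim = c(d[1], m, m))
  for (i in seq_len(d[1])) {
    y <- M %*% batch$pixels[i, , ] %*% t(M)
    y <- pmin(pmax(y, 0), 1)
    y[abs(y) < 1e-3] <- 0
    out[i, , ] <- y
  }
  image_batch(out, batch$labels)
}

# radial-frequency whitening filter on the FFT grid of an n x n image
whitening_filter <- function(n, f0_ratio = 200 / 256) {
  fr <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[1:n]  # cycles/image
  f <- sqrt(outer(fr^2, fr^2, "+"))
  f0 <- f0_ratio * (n / 2)                                # fraction of Nyquist
  f * exp(-(f / f0)^4)
}

#' Whiten a square image
#'
#' Applies the radial frequency-domain filter `R(f) = f * exp(-(f/f0)^4)` via
#' the 2-D FFT, flattening the image spectrum the way retinal/LGN processing
#' approximately does. The filter has zero gain at DC, so the output has
#' (numerically) zero mean and contains both positive and negative values.
#'
#' @param img square numeric matrix.
#' @param f0_ratio cutoff frequency as a fraction of Nyquist
#'   (default `200/256`, the classic natural-image whitening choice rescaled
#'   to the image size).
#' @param scale global multiplicative rescaling applied to the output
#'   (normally fitted once on training data by [fit_preprocessor]).
#' @return A real matrix of the same size, mean approximately 0.
#' @export
whiten <- function(img, f0_ratio = 200 / 256, scale = 1) {
  n <- nrow(img)
  if (ncol(img) != n) stop("image must be square")
  filt <- whitening_filter(n, f0_ratio)
  scale * Re(stats::fft(stats::fft(img) * filt, inverse = TRUE)) / n^2
}

#' Split a whitened image into on/off channels
#'
#' The positive part and the absolute value of the negative part of the
#' whitened image are flattened and concatenated, mimicking the on-center and
#' off-center LGN pathways. For a 12x12 image this yields the 288-dimensional
#' non-negative input vector all models consume. The split is lossless:
#' `x[1:144] - x[145:288]` reshaped recovers the whitened image exactly.
#'
#' @param w whitened square matrix.
#' @return Non-negative numeric vector of length `2 * length(w)`.
#' @export
split_on_off <- function(w) {
  v <- as.vector(w)
  c(pmax(v, 0), pmax(-v, 0))
}

#' Recombine on/off channels into a signed map
#'
#' Inverse of [split_on_off] up to reshaping: on-channel minus off-channel.
#'
#' @param x vector of length `2 * side^2` (on half then off half).
#' @param side image side length (default `sqrt(length(x) / 2)`).
#' @return A `side x side` signed matrix.
#' @export
unsplit_on_off <- function(x, side = sqrt(length(x) / 2)) {
  side <- as.integer(side)
  n <- side^2
  matrix(x[1:n] - x[(n + 1):(2 * n)], side, side)
}

#' Occlude digit pixels
#'
#' For each image independently, exactly `round(level * n_nonzero)` of its
#' non-zero (digit) pixels -- rounding half away from zero -- are chosen
#' uniformly without replacement and set to 0. Background (zero) pixels are
#' never touched. Occlusion is applied to raw images, before whitening. Each
#' image uses an RNG substream derived from `(seed, image index)`, so results
#' are reproducible and independent of processing order, and all models can
#' be shown identical occluded images.
#'
#' @param batch an [image_batch].
#' @param level fraction of non-zero pixels to delete, in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return An [image_batch] with occluded pixels.
#' @export
occlude <- function(batch, level, seed = 1) {
  if (level < 0 || level > 1) stop("occlusion level must be in [0, 1]")
  px <- batch$pixels
  n <- dim(px)[1]
  for (i in seq_len(n)) {
    img <- px[i, , ]
    nz <- which(img != 0)
    k <- round_half_away(level * length(nz))
    if (k > 0) {
      drop <- with_seed(substream_seed(seed, i), sample(nz, k))
      img[drop] <- 0
      px[i, , ] <- img
    }
  }
  image_batch(px, batch$labels)
}

#' Fit the preprocessing pipeline on training images
#'
#' Downscales and whitens the training images and fits the one free parameter
#' of the pipeline: a global output scale chosen so the whitened training
#' images have unit mean-square pixel activity. The scale is frozen and
#' reused for all later (test-time, occluded) images.
#'
#' @param train_batch an [image_batch] of raw training images.
#' @param resize_factor linear downscale factor (default 0.40).
#' @param f0_ratio whitening cutoff as a fraction of Nyquist.
#' @return An object of class `preprocessor`.
#' @export
fit_preprocessor <- function(train_batch, resize_factor = 0.40,
                             f0_ratio = 200 / 256) {
  small <- downscale(train_batch, resize_factor)
  n <- dim(small$pixels)[1]
  ssq <- 0
  npix <- dim(small$pixels)[2]^2
  for (i in seq_len(n)) {
    w <- whiten(small$pixels[i, , ], f0_ratio)
    ssq <- ssq + sum(w^2)
  }
  scale <- 1 / sqrt(ssq / (n * npix))
  structure(list(resize_factor = resize_factor, f0_ratio = f0_ratio,
                 scale = scale, side = dim(small$pixels)[2]),
            class = "preprocessor")
}

#' @export
print.preprocessor <- function(x, ...) {
  cat(sprintf(
    "<preprocessor: resize %.2f -> %dx%d, f0 = %.3f x Nyquist, scale %.4g>\n",
    x$resize_factor, x$side, x$side, x$f0_ratio, x$scale))
  invisible(x)
}

#' Apply a fitted preprocessor to an image batch
#'
#' Downscale, whiten (with the frozen training-set scale), and split into
#' on/off channels.
#'
#' @param pp a fitted `preprocessor`.
#' @param batch an [image_batch] of raw images.
#' @return A list with `X` (input-dim x n matrix of non-negative on/off
#'   vectors, 288 x n for 12x12 images) and `labels`.
#' @export
preprocess <- function(pp, batch) {
  small <- downscale(batch, pp$resize_factor)
  n <- dim(small$pixels)[1]
  X <- matrix(0, 2 * pp$side^2, n)
  for (i in seq_len(n)) {
    X[, i] <- split_on_off(whiten(small$pixels[i, , ], pp$f0_ratio, pp$scale))
  }
  list(X = X, labels = batch$labels)
}
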