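# Synthetic MNIST-like digit glyphs: each class is rendered from a fixed
# polyline skeleton with per-sample rotation/translation jitter and a Gaussian
# stroke profile, on an exactly-zero background. The generator exists so the
# whole pipeline (preprocessing, training, occlusion, classification) is
# exercisable without downloading MNIST; it emulates MNIST's statistical
# structure (centered, size-normalized 28x28 digits, zero background,
# foreground intensities in (0,1]) rather than its visual detail.

ellipse_points <- function(cx, cy, rx, ry, n = 14) {
  th <- seq(0, 2 * pi, length.out = n + 1)
  cbind(cx + rx * sin(th), cy - ry * cos(th))
}

# Polyline skeletons per digit class, coordinates in the unit square
# (x rightward, y downward). Each skeleton is a list of k x 2 matrices.
digit_skeletons <- function() {
  list(
    `0` = list(ellipse_points(0.5, 0.5, 0.34, 0.45)),
    `1` = list(rbind(c(0.35, 0.22), c(0.52, 0.06), c(0.52, 0.94))),
    `2` = list(rbind(c(0.15, 0.28), c(0.28, 0.08), c(0.55, 0.04),
                     c(0.8, 0.16), c(0.82, 0.36), c(0.12, 0.92),
                     c(0.88, 0.92))),
    `3` = list(rbind(c(0.15, 0.16), c(0.45, 0.04), c(0.8, 0.16),
                     c(0.78, 0.38), c(0.45, 0.48)),
               rbind(c(0.45, 0.48), c(0.85, 0.6), c(0.82, 0.85),
                     c(0.45, 0.96), c(0.12, 0.84))),
    `4` = list(rbind(c(0.55, 0.05), c(0.1, 0.62), c(0.9, 0.62)),
               rbind(c(0.68, 0.3), c(0.68, 0.95))),
    `5` = list(rbind(c(0.85, 0.06), c(0.2, 0.06), c(0.16, 0.45),
                     c(0.55, 0.38), c(0.85, 0.56), c(0.8, 0.82),
                     c(0.45, 0.95), c(0.13, 0.84))),
    `6` = list(rbind(c(0.75, 0.05), c(0.38, 0.3), c(0.2, 0.62)),
               ellipse_points(0.5, 0.7, 0.3, 0.24)),
    `7` = list(rbind(c(0.12, 0.1), c(0.88, 0.08), c(0.38, 0.93))),
    `8` = list(ellipse_points(0.5, 0.27, 0.26, 0.21),
               ellipse_points(0.5, 0.72, 0.32, 0.24)),
    `9` = list(ellipse_points(0.47, 0.3, 0.28, 0.24),
               rbind(c(0.75, 0.32), c(0.73, 0.6), c(0.58, 0.93)))
  )
}

# min distance from each point of `pts` (m x 2) to a polyline (k x 2)
dist_to_polyline <- function(pts, poly) {
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(poly) - 1)) {
    a <- poly[i, ]; b <- poly[i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 < 1e-12) {
      di <- sqrt((pts[, 1] - a[1])^2 + (pts[, 2] - a[2])^2)
    } else {
      t <- ((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2
      t <- pmin(pmax(t, 0), 1)
      px <- a[1] + t * ab[1]; py <- a[2] + t * ab[2]
      di <- sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2)
    }
    d <- pmin(d, di)
  }
  d
}

render_glyph <- function(skel, angle_deg, dx, dy, sigma, peak, size = 28) {
  # unit square -> pixel box, then rigid jitter about the image center
  cx <- (size + 1) / 2
  th <- angle_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  grid <- as.matrix(expand.grid(x = seq_len(size), y = seq_len(size)))
  d <- rep(Inf, size * size)
  for (poly in skel) {
    p <- cbind(8 + 12 * poly[, 1], 5 + 18 * poly[, 2])
    p <- sweep(sweep(p, 2, c(cx, cx)) %*% t(rot), 2, c(cx + dx, cx + dy), "+")
    # keep the stroke (cutoff radius 2*sigma <= 2.7 px) inside a 1-px margin
    p[, 1] <- pmin(pmax(p[, 1], 4), 25)
    p[, 2] <- pmin(pmax(p[, 2], 4), 25)
    d <- pmin(d, dist_to_polyline(grid, p))
  }
  v <- peak * exp(-d^2 / (2 * sigma^2))
  v[d >= 2 * sigma] <- 0
  matrix(v, size, size, byrow = TRUE)  # rows = y, cols = x
}

#' Generate synthetic labeled digit images
#'
#' Draws `n` digit images uniformly over the 10 classes. Each image is
#' rendered from a fixed per-class polyline skeleton with small random
#' rotation (plus/minus 15 degrees), translation (plus/minus 2 px), stroke
#' width variation, and a smooth Gaussian intensity profile with values in
#' `(0, 1]`. Background pixels are exactly 0 and every glyph keeps at least a
#' one-pixel zero margin, matching the conventions of MNIST that the
#' occlusion logic relies on. Deterministic given `seed`, with per-image
#' substreams so results do not depend on generation order.
#'
#' @param n number of images (>= 1).
#' @param seed integer RNG seed.
#' @param size image side length in pixels (default 28).
#' @return An [image_batch] of `n` images of `size x size` with labels.
#' @examples
#' b <- generate_digits(20, seed = 1)
#' range(b$pixels)
#' @export
generate_digits <- function(n, seed, size = 28) {
  stopifnot(n >= 1)
  skels <- digit_skeletons()
  labels <- with_seed(substream_seed(seed, 0), sample(0:9, n, replace = TRUE))
  px <- array(0, dim = c(n, size, size))
  for (i in seq_len(n)) {
    px[i, , ] <- with_seed(substream_seed(seed, i), {
      render_glyph(skels[[labels[i] + 1]],
                   angle_deg = stats::runif(1, -15, 15),
                   dx = stats::runif(1, -2, 2),
                   dy = stats::runif(1, -2, 2),
                   sigma = stats::runif(1, 0.9, 1.35),
                   peak = stats::runif(1, 0.7, 1),
                   size = size)
    })
  }
  image_batch(px, labels)
}
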