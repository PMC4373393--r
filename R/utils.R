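#' @keywords internal
"_PACKAGE"

# Deterministic substream seed for (seed, index) pairs so per-image randomness
# is reproducible and independent of processing order.
substream_seed <- function(seed, index) {
  s <- (as.double(seed) * 1000003 + as.double(index) * 7919) %% 2147483629
  as.integer(s)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# round-half-away-from-zero (base round() is banker's rounding)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

l2norm <- function(v) sqrt(sum(v^2))

#' Construct a labeled image batch
#'
#' Container for a stack of square grayscale images with class labels, the
#' common currency of the data-preparation functions.
#'
#' @param pixels numeric array of dimension `n x h x w` with intensities in
#'   `[0, 1]`; background pixels must be exactly 0 for the occlusion logic to
#'   be well defined.
#' @param labels integer vector of length `n` with class ids in `0..9`.
#' @return An object of class `image_batch`.
#' @export
image_batch <- function(pixels, labels) {
  stopifnot(length(dim(pixels)) == 3)
  if (dim(pixels)[2] != dim(pixels)[3])
    stop("images must be square (h == w)")
  labels <- as.integer(labels)
  if (length(labels) != dim(pixels)[1])
    stop("number of labels does not match number of images")
  structure(list(pixels = pixels, labels = labels), class = "image_batch")
}

#' @export
print.image_batch <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_batch: %d images of %dx%d, %d classes>\n",
              d[1], d[2], d[3], length(unique(x$labels))))
  invisible(x)
}

#' @export
length.image_batch <- function(x) dim(x$pixels)[1]

#' @export
`[.image_batch` <- function(x, i) {
  image_batch(x$pixels[i, , , drop = FALSE], x$labels[i])
}
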