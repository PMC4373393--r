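# IDX (MNIST-style) binary i/o. Big-endian; magic 2051 = unsigned-byte rank-3
# image tensor, 2049 = unsigned-byte rank-1 label vector.

#' Read an IDX image/label file pair
#'
#' Reads digit images and labels stored in the IDX binary format used by the
#' MNIST distribution and returns them as an [image_batch] with pixel values
#' rescaled from `0..255` to `[0, 1]`.
#'
#' @param images_path path to the image file (magic number 2051).
#' @param labels_path path to the label file (magic number 2049).
#' @return An [image_batch].
#' @export
read_idx <- function(images_path, labels_path) {
  if (!file.exists(images_path)) stop("image file not found: ", images_path)
  if (!file.exists(labels_path)) stop("label file not found: ", labels_path)

  icon <- file(images_path, "rb"); on.exit(close(icon), add = TRUE)
  magic <- readBin(icon, "integer", n = 1, size = 4, endian = "big")
  if (!identical(magic, 2051L))
    stop("bad magic number in image file (expected 2051, got ", magic, ")")
  hdr <- readBin(icon, "integer", n = 3, size = 4, endian = "big")
  n <- hdr[1]; h <- hdr[2]; w <- hdr[3]
  raw_px <- readBin(icon, "integer", n = n * h * w, size = 1, signed = FALSE)
  if (length(raw_px) != n * h * w)
    stop("truncated image file: expected ", n * h * w, " pixels")

  lcon <- file(labels_path, "rb"); on.exit(close(lcon), add = TRUE)
  lmagic <- readBin(lcon, "integer", n = 1, size = 4, endian = "big")
  if (!identical(lmagic, 2049L))
    stop("bad magic number in label file (expected 2049, got ", lmagic, ")")
  nl <- readBin(lcon, "integer", n = 1, size = 4, endian = "big")
  if (nl != n)
    stop("image/label count mismatch: ", n, " images vs ", nl, " labels")
  labels <- readBin(lcon, "integer", n = nl, size = 1, signed = FALSE)

  # file stores images row-major; fill an n x h x w array accordingly
  px <- aperm(array(raw_px / 255, dim = c(w, h, n)), c(3, 2, 1))
  image_batch(px, labels)
}

#' Write an image batch as an IDX file pair
#'
#' Emits the batch in MNIST's IDX binary format so synthetic digits are a
#' drop-in replacement for MNIST file paths.
#'
#' @param batch an [image_batch]; intensities are quantized to `0..255`.
#' @param images_path,labels_path output paths.
#' @return `invisible(NULL)`.
#' @export
write_idx <- function(batch, images_path, labels_path) {
  d <- dim(batch$pixels)
  icon <- file(images_path, "wb"); on.exit(close(icon), add = TRUE)
  writeBin(c(2051L, d[1], d[2], d[3]), icon, size = 4, endian = "big")
  px <- as.integer(round(aperm(batch$pixels, c(3, 2, 1)) * 255))
  writeBin(as.raw(pmin(pmax(px, 0L), 255L)), icon)

  lcon <- file(labels_path, "wb"); on.exit(close(lcon), add = TRUE)
  writeBin(c(2049L, d[1]), lcon, size = 4, endian = "big")
  writeBin(as.raw(batch$labels), lcon)
  invisible(NULL)
}
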