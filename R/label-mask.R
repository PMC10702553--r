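#' Three-class label masks
#'
#' A label mask is an integer matrix with the class codes used throughout the
#' pipeline: `0` background, `1` myelin, `2` axon, plus a `pixel_size_um`
#' attribute (physical pixel edge length in micrometres; optical sections are
#' typically digitised at 0.05 um/px). Row/column indices are 0-based in the
#' on-disk contract and 1-based inside R, origin top-left.
#'
#' @param labels integer matrix with values in `{0, 1, 2}`.
#' @param pixel_size_um pixel edge length in micrometres, `> 0`.
#' @return An object of class `label_mask` (an integer matrix).
#' @examples
#' m <- label_mask(matrix(0L, 8, 8))
#' table(m)
#' @export
label_mask <- function(labels, pixel_size_um = 0.05) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "integer"
  if (!all(labels %in% 0:2)) {
    stop("label mask may only contain codes 0 (background), 1 (myelin), 2 (axon)")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L || pixel_size_um <= 0) {
    stop("pixel_size_um must be a single positive number")
  }
  structure(labels, pixel_size_um = pixel_size_um, class = c("label_mask", "matrix", "array"))
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- tabulate(as.integer(x) + 1L, nbins = 3L)
  cat(sprintf(
    "<label_mask> %d x %d px @ %.4g um/px | background %d, myelin %d, axon %d\n",
    nrow(x), ncol(x), pixel_size_um(x), tab[1], tab[2], tab[3]
  ))
  invisible(x)
}

#' Pixel size of a mask or scene
#' @param x a `label_mask` or `phantom_scene`.
#' @return Pixel edge length in micrometres.
#' @export
pixel_size_um <- function(x) {
  ps <- attr(x, "pixel_size_um")
  if (is.null(ps) && inherits(x, "phantom_scene")) ps <- x$pixel_size_um
  if (is.null(ps)) ps <- 0.05
  ps
}

## class codes, used everywhere downstream
CLASS_BACKGROUND <- 0L
CLASS_MYELIN <- 1L
CLASS_AXON <- 2L

#' Read and write label masks as PNG
#'
#' Masks are stored as single-channel 8-bit PNG holding the raw codes
#' `{0, 1, 2}`; the round trip is lossless.
#'
#' @param mask a `label_mask`.
#' @param path file path ending in `.png`.
#' @param pixel_size_um pixel size to attach on read (PNG carries no units).
#' @return `write_mask_png()` returns `path` invisibly; `read_mask_png()`
#'   returns a `label_mask`.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.integer(mask) / 255, nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path, pixel_size_um = 0.05) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  label_mask(matrix(as.integer(round(arr * 255)), nrow(arr), ncol(arr)),
             pixel_size_um = pixel_size_um)
}

#' Write a grayscale intensity image
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param path file path ending in `.png` or `.tif`/`.tiff`.
#' @param bits 8 or 16 bits per sample.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 16L) {
  image <- pmin(pmax(image, 0), 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(image, path)
  } else {
    tiff::writeTIFF(image, path, bits.per.sample = as.integer(bits))
  }
  invisible(path)
}

#' Read a grayscale intensity image
#'
#' RGB inputs are converted to luminance; values are scaled to `[0, 1]`.
#' @param path PNG or TIFF file.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_image <- function(path) {
  arr <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(arr)) == 3L) {
    w <- c(0.2126, 0.7152, 0.0722)[seq_len(min(3L, dim(arr)[3]))]
    arr <- apply(arr[, , seq_along(w), drop = FALSE], c(1, 2),
                 function(v) sum(v * w) / sum(w))
  }
  arr
}
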