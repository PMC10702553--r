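#' Per-class probability maps
#'
#' The common currency between the segmentation backends and post-processing:
#' an `H x W x 3` array of class probabilities in the fixed class order
#' (background, myelin, axon). Probabilities are in `[0, 1]` and sum to 1 per
#' pixel (tolerance 1e-5). Both the network backend and the deterministic
#' oracle backend produce this structure, so downstream stages accept either
#' interchangeably.
#'
#' @param maps numeric `H x W x 3` array.
#' @param source `"network"` or `"oracle"`.
#' @return A `probability_maps` object.
#' @export
probability_maps <- function(maps, source = c("network", "oracle")) {
  source <- match.arg(source)
  if (length(dim(maps)) != 3L || dim(maps)[3] != 3L) {
    stop("probability maps must be an H x W x 3 array (background, myelin, axon)")
  }
  if (anyNA(maps) || min(maps) < -1e-8 || max(maps) > 1 + 1e-8) {
    stop("probabilities must lie in [0, 1]")
  }
  sums <- maps[, , 1] + maps[, , 2] + maps[, , 3]
  if (max(abs(sums - 1)) > 1e-5) {
    stop("per-pixel probabilities must sum to 1 (tolerance 1e-5)")
  }
  structure(maps, source = source,
            class_order = c("background", "myelin", "axon"),
            class = c("probability_maps", "array"))
}

#' @export
print.probability_maps <- function(x, ...) {
  cat(sprintf("<probability_maps> %d x %d px, classes (background, myelin, axon), source %s\n",
              dim(x)[1], dim(x)[2], attr(x, "source")))
  invisible(x)
}

#' Oracle segmentation backend
#'
#' A deterministic test double for the network: converts a ground-truth label
#' mask to near-one-hot probability maps, optionally corrupting a seeded
#' random subset of pixels (`floor(flip_rate * H * W)` of them, each flipped
#' to a random wrong class). With `flip_rate = 0` the argmax reproduces the
#' mask exactly, which makes end-to-end pipeline identities testable.
#'
#' @param mask a [label_mask()].
#' @param flip_rate fraction of pixels to corrupt, in `[0, 0.5)`.
#' @param seed integer seed for the corruption draw.
#' @param confidence probability assigned to the chosen class (rest split
#'   evenly between the other two).
#' @return A [probability_maps()] with `source = "oracle"`.
#' @examples
#' sc <- generate_scene(64, 64, n_fibers = 2, radius_range = c(6, 9), seed = 1)
#' pm <- oracle_predict(sc$mask)
#' all(apply(pm, c(1, 2), which.max) - 1L == unclass(sc$mask))
#' @export
oracle_predict <- function(mask, flip_rate = 0, seed = 1, confidence = 0.98) {
  stopifnot(flip_rate >= 0, flip_rate < 0.5, confidence > 0.5, confidence < 1)
  labels <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  n <- length(labels)
  if (flip_rate > 0) {
    local_seed(seed)
    k <- floor(flip_rate * n)
    idx <- sample.int(n, k)
    # flip each chosen pixel to one of the two wrong classes
    shift <- sample(1:2, k, replace = TRUE)
    labels[idx] <- (labels[idx] + shift) %% 3L
  }
  off <- (1 - confidence) / 2
  maps <- array(off, dim = c(nrow(labels), ncol(labels), 3L))
  for (cls in 0:2) {
    sel <- labels == cls
    plane <- maps[, , cls + 1L]
    plane[sel] <- confidence
    maps[, , cls + 1L] <- plane
  }
  probability_maps(maps, source = "oracle")
}
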