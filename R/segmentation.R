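#' Network configuration for the segmentation U-Net
#'
#' The reference architecture has 6 resolution levels with 16, 32, 64, 128,
#' 256 and 512 filters; each level applies two 3x3 convolutions, each followed
#' by per-channel normalization and parametric ReLU, with stride-2
#' downsampling between levels. Training uses the soft Dice loss with the
#' Adam optimizer at learning rate 1e-3 on 512 x 512 patches. That full
#' configuration is constructible here, but a reduced 3-level variant
#' (8/16/32 filters) is the practical default for CPU-scale experiments and
#' is what the package's own tests use.
#'
#' @param depths integer vector of filter counts per level, strictly
#'   increasing.
#' @param patch_size training patch edge in pixels; must be a multiple of
#'   `2^(length(depths) - 1)`.
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs.
#' @param augmentations subset of `c("rotate", "flip", "zoom",
#'   "gaussian_noise", "gaussian_smooth")`: right-angle rotations, axis flips,
#'   mild zooms (0.9–1.1, nearest-neighbour for masks), additive Gaussian
#'   noise and Gaussian smoothing.
#' @param n_val held-out validation patches (default: one third, at least 1
#'   when more than one pair is available).
#' @param seed seed controlling weight init, the train/validation split,
#'   shuffling and augmentation draws. Identical seed, data and config give
#'   bit-identical training runs.
#' @return A `unet_config` list.
#' @export
unet_config <- function(depths = c(8, 16, 32), patch_size = 256,
                        learning_rate = 1e-3, epochs = 20,
                        augmentations = c("flip", "rotate"),
                        n_val = NULL, seed = 0) {
  depths <- as.integer(depths)
  if (length(depths) < 2L || any(diff(depths) <= 0)) {
    stop("depths must be a strictly increasing vector of at least 2 filter counts")
  }
  div <- 2^(length(depths) - 1)
  if (patch_size %% div != 0) {
    stop("patch_size must be a multiple of ", div, " for ", length(depths), " levels")
  }
  augmentations <- if (length(augmentations) == 0) character(0) else
    match.arg(augmentations,
              c("rotate", "flip", "zoom", "gaussian_noise", "gaussian_smooth"),
              several.ok = TRUE)
  structure(list(depths = depths, patch_size = as.integer(patch_size),
                 stride = 2L, learning_rate = learning_rate,
                 loss = "dice", optimizer = "adam",
                 epochs = as.integer(epochs), augmentations = augmentations,
                 n_val = n_val, seed = as.integer(seed)),
            class = "unet_config")
}

#' Reference full-scale configuration
#'
#' The 6-level, 16..512-filter configuration on 512 px patches. Heavy on CPU;
#' provided so the full architecture is constructible.
#' @return A [unet_config()].
#' @export
unet_config_full <- function() {
  unet_config(depths = c(16L, 32L, 64L, 128L, 256L, 512L), patch_size = 512,
              augmentations = c("rotate", "flip", "zoom",
                                "gaussian_noise", "gaussian_smooth"))
}

#' Train the segmentation network
#'
#' Trains the encoder-decoder on image/mask pairs with the soft Dice loss and
#' Adam, logging per-epoch training loss and validation Dice per class on a
#' held-out split. All randomness (weight init, split, shuffling,
#' augmentation) derives from `config$seed`.
#'
#' @param images list of numeric matrices in `[0, 1]`, equal shapes.
#' @param masks list of [label_mask()]s aligned with `images`.
#' @param config a [unet_config()].
#' @param quiet suppress the per-epoch progress line.
#' @return A `seg_model`: list with the network handle (`ptr`), `config`,
#'   `depths`, and `log` (tibble: epoch, train_loss, val_dice_axon,
#'   val_dice_myelin, val_dice_background).
#' @export
train_segmenter <- function(images, masks, config = unet_config(), quiet = FALSE) {
  if (length(images) == 0L) stop("empty training set")
  if (length(images) != length(masks)) stop("images and masks must align")
  for (i in seq_along(images)) {
    if (!identical(dim(images[[i]]), dim(masks[[i]])[1:2])) {
      stop("image/mask shape mismatch at pair ", i)
    }
  }
  local_seed(config$seed)
  ptr <- .unet_create(config$depths, config$seed)

  n <- length(images)
  n_val <- config$n_val
  if (is.null(n_val)) n_val <- if (n > 1L) max(1L, round(n / 3)) else 0L
  n_val <- min(n_val, n - 1L)
  val_idx <- if (n_val > 0L) sort(sample.int(n, n_val)) else integer(0)
  train_idx <- setdiff(seq_len(n), val_idx)

  div <- 2^(length(config$depths) - 1)
  log_rows <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    losses <- numeric(0)
    for (i in sample(train_idx)) {
      pair <- augment_pair(images[[i]], matrix(as.integer(masks[[i]]), nrow(masks[[i]])),
                           config$augmentations)
      img <- pad_to_multiple(pair$image, div)
      lab <- pad_to_multiple(pair$mask, div)
      losses <- c(losses, .unet_train_step(ptr, img, lab, config$learning_rate))
    }
    val <- if (length(val_idx) > 0L) {
      scores <- purrr::map(val_idx, function(i) {
        pm <- predict_probabilities(images[[i]], model = list(ptr = ptr, depths = config$depths))
        pred <- threshold_probabilities(pm, pixel_size_um = pixel_size_um(masks[[i]]))
        c(bg = dice_score(pred, masks[[i]], CLASS_BACKGROUND),
          my = dice_score(pred, masks[[i]], CLASS_MYELIN),
          ax = dice_score(pred, masks[[i]], CLASS_AXON))
      })
      Reduce(`+`, scores) / length(scores)
    } else c(bg = NA_real_, my = NA_real_, ax = NA_real_)
    log_rows[[epoch]] <- tibble::tibble(
      epoch = epoch, train_loss = mean(losses),
      val_dice_background = val[["bg"]], val_dice_myelin = val[["my"]],
      val_dice_axon = val[["ax"]]
    )
    if (!quiet) {
      message(sprintf("epoch %3d  loss %.4f  val dice axon %.3f myelin %.3f",
                      epoch, mean(losses), val[["ax"]], val[["my"]]))
    }
  }
  structure(list(ptr = ptr, config = config, depths = config$depths,
                 log = dplyr::bind_rows(log_rows),
                 val_idx = val_idx, train_idx = train_idx),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("<seg_model> U-Net, %d levels (%s filters), %.0f parameters\n",
              length(x$depths), paste(x$depths, collapse = "/"),
              .unet_n_params(x$ptr)))
  if (nrow(x$log) > 0) {
    last <- x$log[nrow(x$log), ]
    cat(sprintf("after %d epochs: loss %.4f, val Dice axon %.3f / myelin %.3f\n",
                last$epoch, last$train_loss, last$val_dice_axon, last$val_dice_myelin))
  }
  invisible(x)
}

#' Predict class probability maps with a trained network
#'
#' Large images are processed in overlapping tiles blended by linear-ramp
#' weighted averaging; inputs are reflect-padded to the stride granularity of
#' the network and cropped back, so the output always matches the input shape.
#'
#' @param image numeric matrix in `[0, 1]`.
#' @param model a `seg_model` from [train_segmenter()] (or a loaded one).
#' @param tile tile edge in pixels, `NULL` for single-shot prediction.
#' @param overlap tile overlap in pixels.
#' @return A [probability_maps()] with `source = "network"`.
#' @export
predict_probabilities <- function(image, model, tile = NULL, overlap = 32) {
  if (is.null(model$ptr)) stop("model has no network handle; train or load one first")
  if (min(dim(image)) < 16) stop("image must be at least 16 px on each side")
  div <- 2^(length(model$depths) - 1)
  H <- nrow(image)
  W <- ncol(image)
  run_one <- function(img) {
    padded <- pad_to_multiple(img, div)
    pr <- .unet_predict(model$ptr, padded)
    pr[seq_len(nrow(img)), seq_len(ncol(img)), , drop = FALSE]
  }
  if (is.null(tile) || (H <= tile && W <= tile)) {
    return(probability_maps(run_one(image), source = "network"))
  }
  stopifnot(tile >= 16, overlap >= 0, overlap < tile)
  step <- tile - overlap
  starts <- function(total) {
    s <- seq(1L, max(total - tile + 1L, 1L), by = step)
    if (s[length(s)] + tile - 1L < total) s <- c(s, total - tile + 1L)
    unique(pmax(s, 1L))
  }
  acc <- array(0, dim = c(H, W, 3L))
  wacc <- matrix(0, H, W)
  ramp <- function(n) {
    r <- pmin(seq_len(n), rev(seq_len(n)))
    r / max(r)
  }
  for (r0 in starts(H)) {
    for (c0 in starts(W)) {
      r1 <- min(r0 + tile - 1L, H)
      c1 <- min(c0 + tile - 1L, W)
      sub <- image[r0:r1, c0:c1, drop = FALSE]
      pr <- run_one(sub)
      wt <- outer(ramp(nrow(sub)), ramp(ncol(sub)))
      for (k in 1:3) acc[r0:r1, c0:c1, k] <- acc[r0:r1, c0:c1, k] + pr[, , k] * wt
      wacc[r0:r1, c0:c1] <- wacc[r0:r1, c0:c1] + wt
    }
  }
  for (k in 1:3) acc[, , k] <- acc[, , k] / wacc
  tot <- acc[, , 1] + acc[, , 2] + acc[, , 3]
  for (k in 1:3) acc[, , k] <- acc[, , k] / tot
  probability_maps(acc, source = "network")
}

#' Save / load a trained segmentation model
#'
#' Checkpoints are written with `saveRDS()`: a plain list of the architecture,
#' config and weight matrices behind a stable path contract. Weights are never
#' shipped with the package; reproducibility comes from seeds plus the
#' phantom generator.
#'
#' @param model a `seg_model`.
#' @param path checkpoint path (`.rds`).
#' @return `save_segmenter()` returns `path` invisibly; `load_segmenter()`
#'   returns a `seg_model`.
#' @export
save_segmenter <- function(model, path) {
  saveRDS(list(depths = model$depths, config = model$config,
               weights = .unet_get_params(model$ptr), log = model$log), path)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  obj <- readRDS(path)
  ptr <- .unet_create(obj$depths, obj$config$seed)
  .unet_set_params(ptr, obj$weights)
  structure(list(ptr = ptr, config = obj$config, depths = obj$depths,
                 log = obj$log), class = "seg_model")
}

## ---- internals -------------------------------------------------------------

# Reflect-pad a matrix on the bottom/right to a multiple of `div`.
pad_to_multiple <- function(m, div) {
  H <- nrow(m)
  W <- ncol(m)
  Hp <- ceiling(H / div) * div
  Wp <- ceiling(W / div) * div
  if (Hp == H && Wp == W) return(m)
  ri <- c(seq_len(H), rev(seq_len(H)))[seq_len(Hp)]
  ci <- c(seq_len(W), rev(seq_len(W)))[seq_len(Wp)]
  m[ri, ci, drop = FALSE]
}

# Random augmentation of an image/mask pair; geometric ops use identical
# index transforms for both, mask resampling is nearest-neighbour.
augment_pair <- function(image, mask, augmentations) {
  if ("flip" %in% augmentations) {
    if (runif(1) < 0.5) {
      image <- image[nrow(image):1, , drop = FALSE]
      mask <- mask[nrow(mask):1, , drop = FALSE]
    }
    if (runif(1) < 0.5) {
      image <- image[, ncol(image):1, drop = FALSE]
      mask <- mask[, ncol(mask):1, drop = FALSE]
    }
  }
  if ("rotate" %in% augmentations) {
    k <- sample(0:3, 1)
    if (k > 0 && nrow(image) == ncol(image)) {
      for (i in seq_len(k)) {
        image <- t(image[nrow(image):1, , drop = FALSE])
        mask <- t(mask[nrow(mask):1, , drop = FALSE])
      }
    }
  }
  if ("zoom" %in% augmentations && runif(1) < 0.5) {
    fz <- runif(1, 0.9, 1.1)
    image <- zoom_keep_shape(image, fz, nearest = FALSE)
    mask <- zoom_keep_shape(mask, fz, nearest = TRUE)
  }
  if ("gaussian_noise" %in% augmentations && runif(1) < 0.5) {
    image <- pmin(pmax(image + matrix(rnorm(length(image), 0, 0.02), nrow(image)), 0), 1)
  }
  if ("gaussian_smooth" %in% augmentations && runif(1) < 0.5) {
    image <- as.matrix(EBImage::gblur(EBImage::Image(image), sigma = runif(1, 0.5, 1)))
  }
  storage.mode(mask) <- "integer"
  list(image = image, mask = mask)
}

# Zoom about the center, cropping or reflect-padding back to original shape.
zoom_keep_shape <- function(m, factor, nearest) {
  H <- nrow(m)
  W <- ncol(m)
  filt <- if (nearest) "none" else "bilinear"
  z <- as.matrix(EBImage::resize(EBImage::Image(m), w = max(round(H * factor), 8),
                                 h = max(round(W * factor), 8), filter = filt))
  zh <- nrow(z)
  zw <- ncol(z)
  if (zh >= H) {
    r0 <- floor((zh - H) / 2)
    c0 <- floor((zw - W) / 2)
    out <- z[r0 + seq_len(H), c0 + seq_len(W), drop = FALSE]
  } else {
    ri <- c(seq_len(zh), rev(seq_len(zh)))[seq_len(H)]
    ci <- c(seq_len(zw), rev(seq_len(zw)))[seq_len(W)]
    out <- z[ri, ci, drop = FALSE]
  }
  if (nearest) storage.mode(out) <- "integer"
  out
}
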