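#' Plot methods
#'
#' `autoplot()` methods for the package's result types: phantom scenes
#' (image and mask side by side), label masks, Bland–Altman results (scatter
#' of differences against means with bias and limits of agreement), and
#' training logs (per-epoch validation Dice).
#'
#' @param object object to plot.
#' @param which for scenes, `"image"`, `"mask"` or `"both"`.
#' @param ... unused.
#' @return A ggplot object.
#' @name autoplot-gratior
NULL

mask_palette <- c(background = "black", myelin = "white", axon = "gray60")

raster_df <- function(m, value_name = "value") {
  tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
}

#' @rdname autoplot-gratior
#' @export
autoplot.label_mask <- function(object, ...) {
  df <- raster_df(matrix(as.integer(object), nrow(object)))
  df$class <- factor(c("background", "myelin", "axon")[df$value + 1L],
                     levels = names(mask_palette))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = mask_palette) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-gratior
#' @export
autoplot.phantom_scene <- function(object, which = c("image", "mask", "both"), ...) {
  which <- match.arg(which)
  if (which == "mask") return(autoplot(object$mask))
  p_img <- ggplot2::ggplot(raster_df(object$image),
                           ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity") +
    ggplot2::theme_minimal()
  if (which == "image") return(p_img)
  patchwork_fallback(p_img, autoplot(object$mask))
}

# side-by-side without depending on patchwork
patchwork_fallback <- function(a, b) {
  if (requireNamespace("patchwork", quietly = TRUE)) a + b else a
}

#' @rdname autoplot-gratior
#' @export
autoplot.bland_altman_result <- function(object, ...) {
  df <- tibble::tibble(mean = object$means, diff = object$diffs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = object$bias, linetype = 1) +
    ggplot2::geom_hline(yintercept = object$loa, linetype = 2) +
    ggplot2::labs(x = "mean of methods", y = "difference (a - b)",
                  title = sprintf("bias %.3g, LoA [%.3g, %.3g]",
                                  object$bias, object$loa[1], object$loa[2])) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-gratior
#' @export
autoplot.seg_model <- function(object, ...) {
  df <- object$log
  long <- tibble::tibble(
    epoch = rep(df$epoch, 2),
    dice = c(df$val_dice_axon, df$val_dice_myelin),
    class = rep(c("axon", "myelin"), each = nrow(df))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$dice,
                                     colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(y = "validation Dice") +
    ggplot2::theme_minimal()
}
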