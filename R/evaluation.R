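#' Segmentation quality metrics
#'
#' `dice_score()` computes the overlap coefficient
#' `2 |A intersect B| / (|A| + |B|)` between the predicted and ground-truth
#' binary masks of one class; when both masks are empty for the class the
#' score is defined as 1.0 (the 0/0 case, documented convention).
#' `pixel_accuracy()` is the one-vs-rest binary accuracy
#' `(TP + TN) / (H * W)` for the class.
#'
#' @param pred_mask,truth_mask [label_mask()] objects (or integer matrices)
#'   of equal shape.
#' @param class_code class to score: 0 background, 1 myelin, 2 axon.
#' @return A single number in `[0, 1]`.
#' @examples
#' a <- matrix(c(2, 2, 0, 0), 2, 2)
#' b <- matrix(c(2, 0, 2, 0), 2, 2)
#' dice_score(a, b, 2)      # 0.5
#' pixel_accuracy(a, b, 2)  # 0.5
#' @export
dice_score <- function(pred_mask, truth_mask, class_code) {
  check_same_shape(pred_mask, truth_mask)
  a <- as.integer(pred_mask) == class_code
  b <- as.integer(truth_mask) == class_code
  denom <- sum(a) + sum(b)
  if (denom == 0L) return(1.0)
  2 * sum(a & b) / denom
}

#' @rdname dice_score
#' @export
pixel_accuracy <- function(pred_mask, truth_mask, class_code) {
  check_same_shape(pred_mask, truth_mask)
  a <- as.integer(pred_mask) == class_code
  b <- as.integer(truth_mask) == class_code
  mean(a == b)
}

#' Evaluate segmentation before and after fiber selection
#'
#' Computes per-class Dice and pixel accuracy on the full image
#' (`unrestricted`) and restricted to the support of the selected fibers
#' (`restricted`): the union of the selected predicted fibers' axon+myelin
#' pixels and the pixels of the ground-truth fibers matched to them by
#' maximal axon overlap. Restricting evaluation to quality-selected fibers is
#' how the pipeline's selection step is scored.
#'
#' @param pred_mask,truth_mask [label_mask()] objects of equal shape.
#' @param fiber_set result of [extract_fibers()] + [select_fibers()] computed
#'   on `pred_mask` (must carry the `selected` flag).
#' @return A tibble with columns `class`, `scope` (`unrestricted` /
#'   `restricted`), `dice`, `pixel_accuracy`, `n_pixels`.
#' @export
evaluate_selected <- function(pred_mask, truth_mask, fiber_set) {
  check_same_shape(pred_mask, truth_mask)
  fibers <- fiber_table(fiber_set)
  if (!"selected" %in% names(fibers)) {
    stop("fiber_set has no selection flags; run select_fibers() first")
  }
  sel_ids <- fibers$fiber_id[fibers$selected]
  if (length(sel_ids) == 0L) {
    stop("no fibers were selected; relax the selection criteria or inspect the mask")
  }
  pred <- matrix(as.integer(pred_mask), nrow(pred_mask), ncol(pred_mask))
  truth <- matrix(as.integer(truth_mask), nrow(truth_mask), ncol(truth_mask))

  support <- matrix(FALSE, nrow(pred), ncol(pred))
  support[fiber_set$axon_labels %in% sel_ids] <- TRUE
  support[fiber_set$myelin_labels %in% sel_ids] <- TRUE

  # ground-truth fibers matched to selected predictions by maximal axon overlap
  truth_set <- extract_fibers(truth_mask)
  if (nrow(truth_set$fibers) > 0L) {
    matches <- match_fibers(fiber_set, truth_set)
    keep <- matches$truth_id[matches$pred_id %in% sel_ids]
    support[truth_set$axon_labels %in% keep] <- TRUE
    support[truth_set$myelin_labels %in% keep] <- TRUE
  }

  score <- function(p, t, scope) {
    purrr::map_dfr(c(background = 0L, myelin = 1L, axon = 2L), function(code) {
      tibble::tibble(dice = dice_score(p, t, code),
                     pixel_accuracy = pixel_accuracy(p, t, code),
                     n_pixels = length(p))
    }, .id = "class") |>
      dplyr::mutate(scope = scope, .after = "class")
  }
  dplyr::bind_rows(
    score(pred, truth, "unrestricted"),
    score(matrix(pred[support], ncol = 1), matrix(truth[support], ncol = 1), "restricted")
  )
}

#' Match predicted fibers to ground-truth fibers
#'
#' Pairs each predicted fiber with the ground-truth fiber sharing the largest
#' axon-pixel overlap (unmatched fibers are dropped; call-sites flag them).
#'
#' @param pred_set,truth_set [extract_fibers()] results.
#' @return A tibble `pred_id`, `truth_id`, `overlap_px`.
#' @export
match_fibers <- function(pred_set, truth_set) {
  pa <- as.vector(pred_set$axon_labels)
  ta <- as.vector(truth_set$axon_labels)
  sel <- pa > 0L & ta > 0L
  if (!any(sel)) {
    return(tibble::tibble(pred_id = integer(), truth_id = integer(),
                          overlap_px = integer()))
  }
  tab <- as.data.frame(table(pred = pa[sel], truth = ta[sel]),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  tab$pred <- as.integer(tab$pred)
  tab$truth <- as.integer(tab$truth)
  tab <- tab[order(tab$pred, -tab$Freq, tab$truth), ]
  best <- tab[!duplicated(tab$pred), ]
  tibble::tibble(pred_id = best$pred, truth_id = best$truth,
                 overlap_px = as.integer(best$Freq))
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a)[1:2], dim(b)[1:2])) {
    stop("masks must have identical shape: ", paste(dim(a)[1:2], collapse = "x"),
         " vs ", paste(dim(b)[1:2], collapse = "x"))
  }
  invisible(TRUE)
}
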