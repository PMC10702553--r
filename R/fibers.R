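#' Fiber selection criteria
#'
#' Quality thresholds used to auto-select axons suitable for morphometry.
#' A fiber is excluded when its axon is highly elongated (eccentricity
#' strictly greater than `max_eccentricity`), not compact (solidity strictly
#' less than `min_solidity`), or too small (area strictly smaller than
#' `min_area_px`). The strict inequalities are deliberate: boundary values
#' (eccentricity 0.95, solidity 0.9, area 50 px) are retained.
#'
#' @param max_eccentricity upper eccentricity bound (default 0.95).
#' @param min_solidity lower solidity bound (default 0.9).
#' @param min_area_px minimum axon area in pixels (default 50).
#' @return A `selection_criteria` list.
#' @export
selection_criteria <- function(max_eccentricity = 0.95, min_solidity = 0.9,
                               min_area_px = 50) {
  stopifnot(max_eccentricity > 0, max_eccentricity < 1,
            min_solidity > 0, min_solidity <= 1, min_area_px > 0)
  structure(list(max_eccentricity = max_eccentricity,
                 min_solidity = min_solidity,
                 min_area_px = min_area_px),
            class = "selection_criteria")
}

#' Extract individual fibers from a label mask
#'
#' Finds 8-connected axon components and assigns every myelin pixel to
#' exactly one fiber: the fiber whose axon is nearest by geodesic distance
#' through the myelin class (multi-source breadth-first propagation with
#' axon components as seeds; equal-distance ties go to the lower fiber id,
#' deterministically). Myelin not reachable from any axon stays unassigned
#' and is reported separately. Fiber ids follow row-major discovery order of
#' the axon components.
#'
#' Shape descriptors come from the axon region alone: eccentricity is
#' `sqrt(1 - lambda2/lambda1)` for the eigenvalues `lambda1 >= lambda2` of
#' the normalized second central moments (the inertia-ellipse definition used
#' by standard regionprops tools), and solidity is axon area divided by the
#' pixel count of its filled convex hull.
#'
#' @param mask a [label_mask()].
#' @return A `fiber_set`: list with `fibers` (tibble: `fiber_id`,
#'   `centroid_row`, `centroid_col` (0-based), `axon_area_px`,
#'   `myelin_area_px`, `eccentricity`, `solidity`, `touches_border`),
#'   `axon_labels` / `myelin_labels` (integer matrices, 0 = none),
#'   `n_unassigned_myelin_px`, and `pixel_size_um`.
#' @examples
#' sc <- generate_scene(128, 128, n_fibers = 4, radius_range = c(6, 10), seed = 2)
#' fs <- extract_fibers(sc$mask)
#' fs$fibers
#' @export
extract_fibers <- function(mask) {
  labels <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  nr <- nrow(labels)
  nc <- ncol(labels)
  axon_labels <- .cc_label(labels == CLASS_AXON, 8L)
  n_fibers <- max(axon_labels)
  myelin_dom <- labels == CLASS_MYELIN
  grown <- .geodesic_label(axon_labels, myelin_dom)
  myelin_labels <- grown
  myelin_labels[!myelin_dom] <- 0L
  n_unassigned <- sum(myelin_dom & myelin_labels == 0L)

  if (n_fibers == 0L) {
    return(structure(
      list(fibers = empty_fiber_table(), axon_labels = axon_labels,
           myelin_labels = myelin_labels, n_unassigned_myelin_px = n_unassigned,
           pixel_size_um = pixel_size_um(mask)),
      class = "fiber_set"
    ))
  }

  idx <- which(axon_labels > 0L)
  ids <- axon_labels[idx]
  r <- (idx - 1L) %% nr      # 0-based coordinates
  c <- (idx - 1L) %/% nr
  area <- tabulate(ids, nbins = n_fibers)
  sr <- rowsum_by(r, ids, n_fibers)
  sc <- rowsum_by(c, ids, n_fibers)
  srr <- rowsum_by(r^2, ids, n_fibers)
  scc <- rowsum_by(c^2, ids, n_fibers)
  src <- rowsum_by(r * c, ids, n_fibers)
  mr <- sr / area
  mc <- sc / area
  mu20 <- srr / area - mr^2
  mu02 <- scc / area - mc^2
  mu11 <- src / area - mr * mc
  disc <- sqrt(pmax((mu20 - mu02)^2 + 4 * mu11^2, 0))
  l1 <- (mu20 + mu02 + disc) / 2
  l2 <- (mu20 + mu02 - disc) / 2
  ecc <- ifelse(l1 <= 0, 0, sqrt(pmax(1 - l2 / pmax(l1, .Machine$double.eps), 0)))

  myelin_area <- tabulate(myelin_labels[myelin_labels > 0L], nbins = n_fibers)
  solidity <- vapply(seq_len(n_fibers), function(id) {
    sel <- ids == id
    convex_solidity(r[sel], c[sel])
  }, numeric(1))

  border <- logical(n_fibers)
  edge <- unique(c(axon_labels[1, ], axon_labels[nr, ], axon_labels[, 1], axon_labels[, nc],
                   myelin_labels[1, ], myelin_labels[nr, ], myelin_labels[, 1], myelin_labels[, nc]))
  border[edge[edge > 0L]] <- TRUE

  fibers <- tibble::tibble(
    fiber_id = seq_len(n_fibers),
    centroid_row = mr, centroid_col = mc,
    axon_area_px = as.integer(area),
    myelin_area_px = as.integer(myelin_area),
    eccentricity = ecc,
    solidity = solidity,
    touches_border = border
  )
  structure(
    list(fibers = fibers, axon_labels = axon_labels,
         myelin_labels = myelin_labels, n_unassigned_myelin_px = n_unassigned,
         pixel_size_um = pixel_size_um(mask)),
    class = "fiber_set"
  )
}

#' @export
print.fiber_set <- function(x, ...) {
  cat(sprintf("<fiber_set> %d fibers, %d unassigned myelin px\n",
              nrow(x$fibers), x$n_unassigned_myelin_px))
  print(x$fibers)
  invisible(x)
}

#' Apply quality selection to extracted fibers
#'
#' Pure filter over the fiber table: flags each fiber as selected or not and
#' records every violated criterion (`eccentricity`, `solidity`, `area`, and
#' optionally `border`). Input order is preserved and the operation is
#' idempotent.
#'
#' @param fibers a `fiber_set` from [extract_fibers()] or its `fibers` tibble.
#' @param criteria a [selection_criteria()].
#' @param exclude_border also exclude fibers touching the image border
#'   (off by default; the standard criteria do not mention borders, but
#'   truncated border fibers can inflate errors).
#' @return Same type as the input, with `selected` (logical),
#'   `exclusion_reasons` (list of character vectors) and `exclusion`
#'   (collapsed `;`-separated string) columns added to the fiber table.
#' @export
select_fibers <- function(fibers, criteria = selection_criteria(),
                          exclude_border = FALSE) {
  if (inherits(fibers, "fiber_set")) {
    fibers$fibers <- select_fibers(fibers$fibers, criteria, exclude_border)
    return(fibers)
  }
  stopifnot(is.data.frame(fibers))
  reasons <- purrr::pmap(
    list(fibers$eccentricity, fibers$solidity, fibers$axon_area_px,
         if ("touches_border" %in% names(fibers)) fibers$touches_border else FALSE),
    function(e, s, a, b) {
      out <- character(0)
      if (e > criteria$max_eccentricity) out <- c(out, "eccentricity")
      if (s < criteria$min_solidity) out <- c(out, "solidity")
      if (a < criteria$min_area_px) out <- c(out, "area")
      if (exclude_border && isTRUE(b)) out <- c(out, "border")
      out
    }
  )
  fibers$selected <- lengths(reasons) == 0L
  fibers$exclusion_reasons <- reasons
  fibers$exclusion <- vapply(reasons, paste, character(1), collapse = ";")
  fibers
}

## ---- internals -------------------------------------------------------------

fiber_table <- function(x) {
  if (inherits(x, "fiber_set")) x$fibers else x
}

empty_fiber_table <- function() {
  tibble::tibble(
    fiber_id = integer(), centroid_row = numeric(), centroid_col = numeric(),
    axon_area_px = integer(), myelin_area_px = integer(),
    eccentricity = numeric(), solidity = numeric(), touches_border = logical()
  )
}

rowsum_by <- function(x, ids, nbins) {
  as.vector(rowsum(x, ids, reorder = TRUE))[seq_len(nbins)]
}

# Solidity = pixel count of the region / lattice-point count of the filled
# convex hull of its pixel centers (scanline over integer rows, tolerance for
# boundary points so hull vertices always count).
convex_solidity <- function(r, c, eps = 1e-7) {
  n <- length(r)
  if (n <= 2L) return(1)
  hull <- grDevices::chull(c, r)            # vertex order around the hull
  hx <- c[hull]
  hy <- r[hull]
  if (length(hull) <= 2L) return(1)         # collinear set
  m <- length(hx)
  nxt <- c(2:m, 1)
  hull_count <- 0L
  for (y in seq(min(hy), max(hy))) {
    xs <- numeric(0)
    for (k in seq_len(m)) {
      y1 <- hy[k]; y2 <- hy[nxt[k]]
      x1 <- hx[k]; x2 <- hx[nxt[k]]
      if (abs(y1 - y2) < eps) {
        if (abs(y - y1) < eps) xs <- c(xs, x1, x2)
      } else if ((y >= min(y1, y2) - eps) && (y <= max(y1, y2) + eps)) {
        xs <- c(xs, x1 + (y - y1) * (x2 - x1) / (y2 - y1))
      }
    }
    if (length(xs) == 0L) next
    hull_count <- hull_count +
      max(0L, floor(max(xs) + eps) - ceiling(min(xs) - eps) + 1L)
  }
  n / max(hull_count, n)
}
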