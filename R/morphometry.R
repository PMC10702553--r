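#' Per-fiber morphometrics
#'
#' For each fiber the reference region is the union of its axon and myelin
#' pixels, so the axon and myelin volume (area) fractions satisfy
#' `AVF + MVF = 1` exactly and the g-ratio
#' `g = sqrt(1 / (1 + MVF / AVF)) = sqrt(|axon| / |region|)` reduces to the
#' classical inner/outer radius ratio `r/R` for an annulus. Diameters are
#' area-equivalent circle diameters (`2 * sqrt(area / pi)`), robust to
#' boundary noise, and myelin thickness is half the difference between the
#' fiber and axon equivalent diameters. A fiber with no assigned myelin gets
#' `mvf = 0`, `g_ratio = 1`, zero thickness and an `unmyelinated` warning
#' flag — the selection module, not this one, governs exclusion.
#'
#' @param fibers a `fiber_set` from [extract_fibers()] (optionally after
#'   [select_fibers()]) or its fiber tibble (needs `axon_area_px` and
#'   `myelin_area_px`).
#' @param pixel_size_um pixel size in micrometres; defaults to the value
#'   recorded on the fiber set.
#' @return A tibble with one row per fiber: `fiber_id`, `selected` (if
#'   present), `axon_area_px`, `myelin_area_px`, `avf`, `mvf`, `g_ratio`,
#'   `axon_diameter_um`, `fiber_diameter_um`, `myelin_thickness_um`,
#'   `unmyelinated`.
#' @examples
#' # |axon| = 100, |myelin| = 300: AVF 0.25, MVF 0.75, g = 0.5
#' compute_morphometrics(tibble::tibble(
#'   fiber_id = 1L, axon_area_px = 100L, myelin_area_px = 300L
#' ), pixel_size_um = 0.05)
#' @export
compute_morphometrics <- function(fibers, pixel_size_um = NULL) {
  if (inherits(fibers, "fiber_set")) {
    if (is.null(pixel_size_um)) pixel_size_um <- fibers$pixel_size_um
    fibers <- fibers$fibers
  }
  if (is.null(pixel_size_um)) pixel_size_um <- 0.05
  stopifnot(is.data.frame(fibers), pixel_size_um > 0)
  if (nrow(fibers) == 0L) {
    return(tibble::tibble(
      fiber_id = integer(), axon_area_px = integer(), myelin_area_px = integer(),
      avf = numeric(), mvf = numeric(), g_ratio = numeric(),
      axon_diameter_um = numeric(), fiber_diameter_um = numeric(),
      myelin_thickness_um = numeric(), unmyelinated = logical()
    ))
  }
  if (any(fibers$axon_area_px <= 0)) stop("every fiber needs a nonempty axon")
  out <- dplyr::mutate(
    fibers,
    region_px = .data$axon_area_px + .data$myelin_area_px,
    avf = .data$axon_area_px / .data$region_px,
    mvf = .data$myelin_area_px / .data$region_px,
    g_ratio = sqrt(1 / (1 + .data$mvf / .data$avf)),
    axon_diameter_um = 2 * sqrt(.data$axon_area_px / pi) * pixel_size_um,
    fiber_diameter_um = 2 * sqrt(.data$region_px / pi) * pixel_size_um,
    myelin_thickness_um = (.data$fiber_diameter_um - .data$axon_diameter_um) / 2,
    unmyelinated = .data$myelin_area_px == 0L
  )
  if (any(out$unmyelinated)) {
    warning(sum(out$unmyelinated), " fiber(s) have no assigned myelin; ",
            "g_ratio = 1 and thickness = 0 reported for them")
  }
  keep <- intersect(
    c("fiber_id", "selected", "axon_area_px", "myelin_area_px", "avf", "mvf",
      "g_ratio", "axon_diameter_um", "fiber_diameter_um",
      "myelin_thickness_um", "unmyelinated"),
    names(out)
  )
  tibble::as_tibble(out[keep])
}

#' Summary statistics of per-fiber morphometrics
#'
#' Mean, sample standard deviation (`n - 1` denominator) and count for each
#' metric column present. With a single fiber the SD is reported as 0 and the
#' `single_observation` flag is set.
#'
#' @param rows tibble from [compute_morphometrics()] (any subset of rows).
#' @param metrics metric columns to summarise.
#' @return A tibble `metric`, `mean`, `sd`, `n`, `single_observation`.
#' @export
aggregate_morphometrics <- function(rows,
                                    metrics = c("g_ratio", "axon_diameter_um",
                                                "myelin_thickness_um", "avf", "mvf")) {
  stopifnot(is.data.frame(rows))
  if (nrow(rows) == 0L) stop("no fibers to aggregate")
  metrics <- intersect(metrics, names(rows))
  purrr::map_dfr(metrics, function(m) {
    v <- rows[[m]]
    tibble::tibble(
      metric = m,
      mean = mean(v),
      sd = if (length(v) > 1L) stats::sd(v) else 0,
      n = length(v),
      single_observation = length(v) == 1L
    )
  })
}
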