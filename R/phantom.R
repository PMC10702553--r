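#' Synthetic nerve-phantom scenes
#'
#' `generate_scene()` builds a stylized stained-nerve cross-section with exact
#' per-fiber ground truth: an intensity image, a 3-class [label_mask()], and a
#' design table holding every fiber's true geometry and morphometrics. Fibers
#' are elliptical annuli (axon core + myelin ring) placed without overlap by
#' rejection sampling. A controllable share of fibers carries the nuisance
#' morphologies that the downstream quality filters must reject:
#'
#' * `oblique` — strongly elongated axon (inertia-ellipse eccentricity above
#'   0.95), as produced by a cut that is not perpendicular to the fiber axis;
#' * `incomplete` — a wedge (>= 90 degrees) cut through axon and myelin, so the
#'   notched axon has solidity below 0.9;
#' * `undersized` — axon smaller than 50 px, too small for reliable metrics.
#'
#' Rasterization uses a pixel-center-inside test (the pixel at row `i`, column
#' `j` belongs to a region iff its center, at continuous 0-based coordinates
#' `(i-1, j-1)`, lies inside the closed region boundary), so pixel-count
#' oracles agree with the mask exactly. The same seed always yields a
#' bit-identical scene.
#'
#' @param width,height image size in pixels.
#' @param n_fibers number of fibers to place (`>= 0`).
#' @param radius_range `(min, max)` axon semi-minor radius in pixels; radii are
#'   drawn uniformly from this range.
#' @param g_ratio designed g-ratio: the myelin outer ellipse is the axon
#'   ellipse scaled by `1 / g_ratio`, so the true g-ratio is exact by
#'   construction. Either one value or a `(min, max)` range.
#' @param aspect_range `(min, max)` axis ratio `a/b` for defect-free axons
#'   (must stay within `[1, 1.2]`, near-circular); `c(1, 1)` gives exact
#'   circles.
#' @param defect_fractions named numeric vector mapping a defect
#'   (`"oblique"`, `"incomplete"`, `"undersized"`) to the fraction of fibers
#'   carrying it; converted to counts with `round()` and must sum to <= 1.
#' @param defect_counts named integer vector of exact defect counts; overrides
#'   `defect_fractions` when given.
#' @param noise_sd additive Gaussian intensity noise (image clipped to
#'   `[0, 1]` afterwards).
#' @param blur_sigma Gaussian blur sigma in pixels (0 = none).
#' @param stain_style `"PPD_like"` (dark myelin ring, mid-gray axon, light
#'   background — osmicated p-phenylenediamine appearance) or `"TB_like"`
#'   (softer ring contrast with a textured background, toluidine-blue
#'   appearance). Both are stylized contrast models, not photorealistic stains.
#' @param pixel_size_um physical pixel size (default 0.05 um/px, the standard
#'   digitisation scale for these sections).
#' @param seed integer seed; identical seeds give identical scenes.
#' @param max_attempts placement attempts per fiber before failing with a
#'   density error.
#' @return A `phantom_scene`: list with `image` (matrix in `[0, 1]`), `mask`
#'   (a [label_mask()]), `fibers` (design tibble, one row per fiber),
#'   `pixel_size_um`, `stain_style`, `seed`.
#' @examples
#' sc <- generate_scene(256, 256, n_fibers = 8, seed = 1)
#' sc$fibers
#' @export
generate_scene <- function(width = 512, height = 512, n_fibers = 30,
                           radius_range = c(8, 20), g_ratio = 0.6,
                           aspect_range = c(1, 1.1),
                           defect_fractions = NULL, defect_counts = NULL,
                           noise_sd = 0.02, blur_sigma = 0,
                           stain_style = c("PPD_like", "TB_like"),
                           pixel_size_um = 0.05, seed = 1,
                           max_attempts = 200L) {
  stopifnot(length(aspect_range) == 2L, aspect_range[1] >= 1,
            aspect_range[2] <= 1.2, aspect_range[1] <= aspect_range[2])
  stain_style <- match.arg(stain_style)
  stopifnot(width >= 16, height >= 16, n_fibers >= 0, noise_sd >= 0,
            blur_sigma >= 0, pixel_size_um > 0)
  if (length(g_ratio) == 1L) g_ratio <- c(g_ratio, g_ratio)
  if (any(g_ratio <= 0) || any(g_ratio >= 1)) stop("g_ratio must lie in (0, 1)")
  if (length(radius_range) != 2L || any(radius_range <= 0) ||
      radius_range[1] > radius_range[2]) {
    stop("radius_range must be (min, max) with 0 < min <= max")
  }
  if (2 * radius_range[2] / min(g_ratio) > min(width, height)) {
    stop("radius_range too large for the image: outer fiber cannot fit")
  }

  counts <- defect_count_plan(n_fibers, defect_fractions, defect_counts)
  defects <- rep(names(counts), counts)
  defects <- c(defects, rep("none", n_fibers - length(defects)))

  local_seed(seed)

  mask <- matrix(CLASS_BACKGROUND, height, width)
  occupied <- matrix(FALSE, height, width)
  rows <- vector("list", n_fibers)

  for (i in seq_len(n_fibers)) {
    geom <- NULL
    for (attempt in seq_len(max_attempts)) {
      cand <- sample_fiber_geometry(defects[i], radius_range, g_ratio, aspect_range)
      ras <- try_place_fiber(cand, occupied, height, width)
      if (!is.null(ras)) {
        geom <- cand
        geom$cr <- ras$cr
        geom$cc <- ras$cc
        break
      }
    }
    if (is.null(geom)) {
      stop(sprintf(
        "could not place fiber %d after %d attempts: fiber density too high for a %dx%d image",
        i, max_attempts, width, height
      ))
    }
    occupied[ras$support] <- TRUE
    mask[ras$axon] <- CLASS_AXON
    mask[ras$myelin] <- CLASS_MYELIN
    f_kept <- geom$kept_fraction
    eq_axon <- 2 * sqrt(geom$a * geom$b * f_kept)        # area-equivalent diameters, px
    eq_fiber <- 2 * sqrt(geom$A * geom$B * f_kept)
    rows[[i]] <- tibble::tibble(
      fiber_id = i,
      center_row = geom$cr, center_col = geom$cc,       # continuous, 0-based
      axon_r_a = geom$a, axon_r_b = geom$b,
      outer_r_a = geom$A, outer_r_b = geom$B,
      rotation = geom$rot, defect = defects[i],
      axon_area_px = length(ras$axon),
      myelin_area_px = length(ras$myelin),
      true_g_ratio = sqrt((geom$a * geom$b) / (geom$A * geom$B)),
      true_axon_diameter_um = eq_axon * pixel_size_um,
      true_myelin_thickness_um = (eq_fiber - eq_axon) / 2 * pixel_size_um
    )
  }

  fibers <- if (n_fibers > 0) dplyr::bind_rows(rows) else empty_design_table()
  image <- render_scene_image(mask, stain_style, noise_sd, blur_sigma)

  structure(
    list(
      image = image,
      mask = label_mask(mask, pixel_size_um = pixel_size_um),
      fibers = fibers,
      pixel_size_um = pixel_size_um,
      stain_style = stain_style,
      seed = seed
    ),
    class = "phantom_scene"
  )
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf(
    "<phantom_scene> %d x %d px, %d fibers (%s), stain %s, seed %d\n",
    nrow(x$image), ncol(x$image), nrow(x$fibers),
    paste(names(table(x$fibers$defect)), table(x$fibers$defect),
          sep = ":", collapse = ", "),
    x$stain_style, x$seed
  ))
  invisible(x)
}

#' Per-fiber ground-truth morphometrics of a phantom scene
#'
#' One row per designed fiber with the true g-ratio and the true
#' area-equivalent axon diameter and myelin thickness in micrometres. For a
#' circular fiber with axon radius `r` px and outer radius `R` px these are
#' exactly `r/R`, `2 * r * pixel_size_um` and `(R - r) * pixel_size_um`.
#'
#' @param scene a `phantom_scene`.
#' @return A tibble with columns `fiber_id`, `defect`, `true_g_ratio`,
#'   `true_axon_diameter_um`, `true_myelin_thickness_um`.
#' @export
scene_truth_table <- function(scene) {
  stopifnot(inherits(scene, "phantom_scene"))
  dplyr::select(
    scene$fibers,
    dplyr::all_of(c("fiber_id", "defect", "true_g_ratio",
                    "true_axon_diameter_um", "true_myelin_thickness_um"))
  )
}

#' Write a phantom scene to disk
#'
#' Writes `image.png` (16-bit grayscale via TIFF when `.tif`), `mask.png`
#' (codes 0/1/2) and `truth.csv` (design table with 0-based centers).
#'
#' @param scene a `phantom_scene`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_image(scene$image, file.path(dir, "image.png"))
  write_mask_png(scene$mask, file.path(dir, "mask.png"))
  write.csv(scene$fibers, file.path(dir, "truth.csv"), row.names = FALSE)
  invisible(dir)
}

## ---- internals -------------------------------------------------------------

# Seed deterministically for the calling frame, restoring the caller's RNG
# state on exit.
local_seed <- function(seed, env = parent.frame()) {
  withr::local_seed(as.integer(seed), .local_envir = env)
}

defect_count_plan <- function(n_fibers, fractions, counts) {
  valid <- c("oblique", "incomplete", "undersized")
  if (!is.null(counts)) {
    if (is.null(names(counts)) || !all(names(counts) %in% valid)) {
      stop("defect_counts must be named with defects in: ", paste(valid, collapse = ", "))
    }
    counts <- vapply(counts, as.integer, integer(1))
  } else if (!is.null(fractions)) {
    if (is.null(names(fractions)) || !all(names(fractions) %in% valid)) {
      stop("defect_fractions must be named with defects in: ", paste(valid, collapse = ", "))
    }
    if (any(fractions < 0) || sum(fractions) > 1 + 1e-12) {
      stop("defect_fractions must be nonnegative and sum to at most 1")
    }
    counts <- vapply(fractions, function(f) as.integer(round(f * n_fibers)), integer(1))
  } else {
    counts <- integer(0)
  }
  if (sum(counts) > n_fibers) stop("designed defect counts exceed n_fibers")
  counts[counts > 0]
}

# Draw the continuous geometry for one fiber of the given defect type.
# Defect geometries sit strictly beyond the selection thresholds so designed
# rejections are exact: oblique uses axis ratio 0.18 (eccentricity ~0.984),
# incomplete cuts a 110-degree wedge (solidity ~0.8), undersized uses r = 3 px
# (~29 px axon).
sample_fiber_geometry <- function(defect, radius_range, g_range,
                                  aspect_range = c(1, 1.1)) {
  g <- runif(1, g_range[1], g_range[2])
  r <- runif(1, radius_range[1], radius_range[2])
  rot <- runif(1, 0, pi)
  notch <- NULL
  if (defect == "none") {
    b <- r
    a <- r * runif(1, aspect_range[1], aspect_range[2])
  } else if (defect == "oblique") {
    a <- max(1.6 * r, 10)
    b <- 0.18 * a
  } else if (defect == "incomplete") {
    b <- max(r, 8)
    a <- b * runif(1, aspect_range[1], aspect_range[2])
    notch <- c(start = runif(1, 0, 2 * pi), width = 110 / 180 * pi)
  } else if (defect == "undersized") {
    b <- 3
    a <- 3
  } else stop("unknown defect: ", defect)
  list(
    a = a, b = b, A = a / g, B = b / g, rot = rot, g = g,
    notch = notch,
    kept_fraction = if (is.null(notch)) 1 else 1 - notch[["width"]] / (2 * pi)
  )
}

# Propose a center, rasterize, and return pixel indices, or NULL on overlap.
try_place_fiber <- function(geom, occupied, height, width) {
  margin <- max(geom$A, geom$B) + 2
  if (2 * margin >= height || 2 * margin >= width) return(NULL)
  cr <- runif(1, margin, (height - 1) - margin)   # continuous 0-based coords
  cc <- runif(1, margin, (width - 1) - margin)
  ras <- rasterize_annulus(cr, cc, geom$a, geom$b, geom$A, geom$B, geom$rot,
                           geom$notch, height, width)
  if (length(ras$axon) == 0L) return(NULL)
  # grow support by 1 px so neighbouring fibers never touch
  if (any(occupied[dilate_indices(ras$support, height, width)])) return(NULL)
  ras$cr <- cr
  ras$cc <- cc
  ras
}

# Pixel-center-inside rasterization of an elliptical annulus, optional wedge
# notch cut through both axon and ring. Returns linear indices.
rasterize_annulus <- function(cr, cc, a, b, A, B, rot, notch, height, width) {
  r0 <- max(1L, floor(cr - max(A, B)) + 1L)
  r1 <- min(height, ceiling(cr + max(A, B)) + 1L)
  c0 <- max(1L, floor(cc - max(A, B)) + 1L)
  c1 <- min(width, ceiling(cc + max(A, B)) + 1L)
  rr <- r0:r1
  cols <- c0:c1
  dy <- (rr - 1) - cr                      # rows in 0-based continuous coords
  dx <- (cols - 1) - cc
  DY <- matrix(dy, length(rr), length(cols))
  DX <- matrix(dx, length(rr), length(cols), byrow = TRUE)
  u <- cos(rot) * DX + sin(rot) * DY       # fiber frame
  v <- -sin(rot) * DX + cos(rot) * DY
  in_axon <- (u / a)^2 + (v / b)^2 <= 1
  in_outer <- (u / A)^2 + (v / B)^2 <= 1
  if (!is.null(notch)) {
    ang <- (atan2(v, u) - notch[["start"]]) %% (2 * pi)
    cut <- ang < notch[["width"]]
    in_axon <- in_axon & !cut
    in_outer <- in_outer & !cut
  }
  lin <- function(sel) {
    idx <- which(sel, arr.ind = TRUE)
    (cols[idx[, 2]] - 1L) * height + rr[idx[, 1]]
  }
  axon <- lin(in_axon)
  myelin <- lin(in_outer & !in_axon)
  list(axon = axon, myelin = myelin, support = c(axon, myelin))
}

dilate_indices <- function(idx, height, width) {
  if (length(idx) == 0L) return(idx)
  r <- ((idx - 1L) %% height) + 1L
  c <- ((idx - 1L) %/% height) + 1L
  out <- integer(0)
  for (dr in -1:1) for (dc in -1:1) {
    rr <- r + dr
    cc <- c + dc
    keep <- rr >= 1L & rr <= height & cc >= 1L & cc <= width
    out <- c(out, (cc[keep] - 1L) * height + rr[keep])
  }
  unique(out)
}

empty_design_table <- function() {
  tibble::tibble(
    fiber_id = integer(), center_row = numeric(), center_col = numeric(),
    axon_r_a = numeric(), axon_r_b = numeric(),
    outer_r_a = numeric(), outer_r_b = numeric(),
    rotation = numeric(), defect = character(),
    axon_area_px = integer(), myelin_area_px = integer(),
    true_g_ratio = numeric(), true_axon_diameter_um = numeric(),
    true_myelin_thickness_um = numeric()
  )
}

# Stylized appearance: intensities chosen for contrast structure, then noise,
# then blur, then clipping.
render_scene_image <- function(mask, stain_style, noise_sd, blur_sigma) {
  levels <- if (stain_style == "PPD_like") {
    c(background = 0.90, myelin = 0.15, axon = 0.55)
  } else {
    c(background = 0.85, myelin = 0.45, axon = 0.70)
  }
  img <- matrix(levels[["background"]], nrow(mask), ncol(mask))
  img[mask == CLASS_MYELIN] <- levels[["myelin"]]
  img[mask == CLASS_AXON] <- levels[["axon"]]
  if (stain_style == "TB_like") {
    # low-frequency background texture
    field <- matrix(rnorm(length(img)), nrow(img))
    field <- as.matrix(EBImage::gblur(EBImage::Image(field), sigma = 6))
    img <- img + 0.05 * field / max(stats::sd(field), 1e-8)
  }
  if (noise_sd > 0) img <- img + matrix(rnorm(length(img), 0, noise_sd), nrow(img))
  if (blur_sigma > 0) img <- as.matrix(EBImage::gblur(EBImage::Image(img), sigma = blur_sigma))
  pmin(pmax(img, 0), 1)
}
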