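test_that("extraction recovers each designed fiber's pixel counts", {
  sc <- generate_scene(512, 512, n_fibers = 30, radius_range = c(8, 20),
                       noise_sd = 0, seed = 7)
  fs <- extract_fibers(sc$mask)
  expect_equal(nrow(fs$fibers), 30)
  idx <- match_design(sc$fibers, fs$fibers)
  expect_identical(fs$fibers$axon_area_px[idx], sc$fibers$axon_area_px)
  expect_identical(fs$fibers$myelin_area_px[idx], sc$fibers$myelin_area_px)
  expect_identical(fs$n_unassigned_myelin_px, 0L)
  # partition invariant
  expect_identical(sum(fs$fibers$axon_area_px), sum(sc$mask == 2L))
  expect_identical(sum(fs$fibers$myelin_area_px) + fs$n_unassigned_myelin_px,
                   sum(sc$mask == 1L))
})

test_that("an all-background mask yields an empty fiber set", {
  fs <- extract_fibers(label_mask(matrix(0L, 32, 32)))
  expect_equal(nrow(fs$fibers), 0)
  expect_equal(nrow(select_fibers(fs)$fibers), 0)
})

test_that("touching rings partition the myelin by geodesic nearest axon", {
  # two annuli close enough that their myelin rings touch
  lab <- matrix(0L, 64, 64)
  put <- function(lab, cr, cc, r, R) {
    idx <- expand.grid(row = 0:63, col = 0:63)
    d2 <- (idx$row - cr)^2 + (idx$col - cc)^2
    lab[d2 <= R^2 & lab == 0L] <- 1L
    lab[d2 <= r^2] <- 2L
    lab
  }
  lab <- put(lab, 31, 20, 7, 12)
  lab <- put(lab, 31, 43, 7, 12)
  m <- label_mask(lab)
  fs <- extract_fibers(m)
  expect_equal(nrow(fs$fibers), 2)
  # every myelin pixel assigned to exactly one fiber; union = myelin class
  expect_identical(fs$n_unassigned_myelin_px, 0L)
  expect_identical(sum(fs$fibers$myelin_area_px), sum(lab == 1L))
  # brute-force geodesic oracle agrees pixel for pixel
  oracle <- geodesic_oracle(fs$axon_labels, lab == 1L)
  expect_identical(fs$myelin_labels, oracle)
})

test_that("myelin with no adjacent axon stays unassigned", {
  lab <- matrix(0L, 32, 32)
  lab[10:14, 10:14] <- 1L   # orphan myelin blob
  lab[25:27, 25:27] <- 2L   # bare axon
  fs <- extract_fibers(label_mask(lab))
  expect_equal(nrow(fs$fibers), 1)
  expect_identical(fs$n_unassigned_myelin_px, 25L)
  expect_identical(fs$fibers$myelin_area_px, 0L)
})

test_that("rasterized eccentricity matches the analytic ellipse value", {
  # ellipse a = 40, b = 10: e = sqrt(1 - (10/40)^2) ~ 0.968
  lab <- matrix(0L, 128, 128)
  idx <- expand.grid(row = 0:127, col = 0:127)
  inside <- ((idx$col - 63.5) / 40)^2 + ((idx$row - 63.5) / 10)^2 <= 1
  lab[as.matrix(idx[inside, c("row", "col")]) + 1L] <- 2L
  fs <- extract_fibers(label_mask(lab))
  expect_equal(fs$fibers$eccentricity, sqrt(1 - (10 / 40)^2), tolerance = 0.01)
  expect_gt(fs$fibers$eccentricity, 0.95)
  sel <- select_fibers(fs)
  expect_false(sel$fibers$selected)
  expect_identical(sel$fibers$exclusion_reasons[[1]], "eccentricity")
})

test_that("selection honors strict threshold inequalities", {
  # 7x7 square: 49 px < 50 -> excluded for area only
  lab49 <- matrix(0L, 32, 32)
  lab49[10:16, 10:16] <- 2L
  f49 <- select_fibers(extract_fibers(label_mask(lab49)))$fibers
  expect_false(f49$selected)
  expect_identical(f49$exclusion_reasons[[1]], "area")
  # 5x10 rectangle: exactly 50 px -> retained ("smaller than 50" is strict)
  lab50 <- matrix(0L, 32, 32)
  lab50[10:14, 10:19] <- 2L
  f50 <- select_fibers(extract_fibers(label_mask(lab50)))$fibers
  expect_identical(f50$axon_area_px, 50L)
  expect_true(f50$selected)
})

test_that("selection is a pure, idempotent, order-preserving filter", {
  sc <- generate_scene(384, 384, n_fibers = 12, radius_range = c(6, 12),
                       defect_counts = c(oblique = 3, undersized = 2),
                       noise_sd = 0, seed = 13)
  fs <- extract_fibers(sc$mask)
  once <- select_fibers(fs)
  twice <- select_fibers(once)
  expect_identical(once$fibers, twice$fibers)
  expect_identical(once$fibers$fiber_id, fs$fibers$fiber_id)
  expect_lte(sum(once$fibers$selected), nrow(fs$fibers))
  # selected <=> no recorded reason
  expect_identical(once$fibers$selected, lengths(once$fibers$exclusion_reasons) == 0L)
})

test_that("border exclusion is off by default but available", {
  lab <- matrix(0L, 40, 40)
  idx <- expand.grid(row = 0:39, col = 0:39)
  d2 <- (idx$row - 0)^2 + (idx$col - 20)^2  # circle clipped by the top border
  lab[as.matrix(idx[d2 <= 100, c("row", "col")]) + 1L] <- 2L
  fs <- extract_fibers(label_mask(lab))
  expect_true(fs$fibers$touches_border)
  default <- select_fibers(fs)$fibers
  flagged <- select_fibers(fs, exclude_border = TRUE)$fibers
  expect_false("border" %in% default$exclusion_reasons[[1]])
  expect_true("border" %in% flagged$exclusion_reasons[[1]])
})
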