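test_that("oracle probabilities behave as a seeded near-one-hot backend", {
  sc <- generate_scene(96, 96, n_fibers = 3, radius_range = c(5, 8),
                       noise_sd = 0, seed = 1)
  pm <- oracle_predict(sc$mask, flip_rate = 0)
  expect_s3_class(pm, "probability_maps")
  amax <- apply(unclass(pm), c(1, 2), which.max) - 1L
  expect_identical(amax, matrix(as.integer(sc$mask), nrow(sc$mask)))

  # per-pixel normalization holds at any flip rate
  for (fr in c(0, 0.1, 0.3)) {
    p <- unclass(oracle_predict(sc$mask, flip_rate = fr, seed = 5))
    expect_lt(max(abs(p[, , 1] + p[, , 2] + p[, , 3] - 1)), 1e-12)
  }

  # exactly floor(rate * H * W) corrupted pixels, reproducibly
  p1 <- oracle_predict(sc$mask, flip_rate = 0.1, seed = 9)
  p2 <- oracle_predict(sc$mask, flip_rate = 0.1, seed = 9)
  expect_identical(unclass(p1), unclass(p2))
  flipped <- apply(unclass(p1), c(1, 2), which.max) - 1L
  expect_equal(sum(flipped != mask_values(sc$mask)), floor(0.1 * 96 * 96))
})

test_that("thresholding applies the class-priority rule", {
  # one-hot input: labels equal argmax exactly
  sc <- generate_scene(96, 96, n_fibers = 3, radius_range = c(5, 8),
                       noise_sd = 0, seed = 2)
  m <- threshold_probabilities(oracle_predict(sc$mask), threshold = 0.8)
  expect_identical(unclass(m), unclass(sc$mask))

  # direct rule application on hand-built pixels
  p <- array(0, dim = c(1, 3, 3))
  p[1, 1, ] <- c(0.15, 0.84, 0.01)  # myelin passes 0.8
  p[1, 2, ] <- c(0.5, 0.3, 0.2)     # nothing passes -> argmax background
  p[1, 3, ] <- c(0.1, 0.1, 0.8)     # axon at exactly the threshold
  m2 <- threshold_probabilities(p, threshold = 0.8)
  expect_identical(as.integer(m2), c(1L, 0L, 2L))

  expect_error(threshold_probabilities(array(NA_real_, c(2, 2, 3))), "missing")
  expect_error(threshold_probabilities(p, threshold = 1.2))
})

test_that("cavity filling follows the size rule and is idempotent", {
  m <- annulus_mask(64, 12, 20)
  lab <- matrix(as.integer(m), 64, 64)

  # 9-px interior hole in the axon -> filled back to axon
  lab9 <- lab
  lab9[30:32, 30:32] <- 0L
  filled <- fill_cavities(label_mask(lab9), min_cavity_px = 5)
  expect_identical(mask_values(filled), lab)

  # 4-px hole (4 <= 5) -> preserved under the default fill-larger rule
  lab4 <- lab
  lab4[30:31, 30:31] <- 0L
  kept <- fill_cavities(label_mask(lab4), min_cavity_px = 5)
  expect_identical(mask_values(kept), lab4)
  # and filled when the direction is inverted
  inv <- fill_cavities(label_mask(lab4), min_cavity_px = 5, fill_direction = "smaller")
  expect_identical(mask_values(inv), lab)

  # idempotence
  twice <- fill_cavities(filled, min_cavity_px = 5)
  expect_identical(mask_values(twice), mask_values(filled))
})

test_that("punched phantom masks are restored exactly", {
  sc <- generate_scene(256, 256, n_fibers = 8, radius_range = c(8, 14),
                       noise_sd = 0, seed = 6)
  lab <- matrix(as.integer(sc$mask), 256, 256)
  corrupted <- lab
  # punch 3x3 holes at interior axon and myelin locations
  punch <- function(lab, cls, n, off) {
    centers <- which(lab == cls)
    # keep holes strictly interior to their region: all 8 neighbours same class
    nr <- nrow(lab)
    ok <- vapply(centers, function(p) {
      r <- (p - 1) %% nr + 1
      c <- (p - 1) %/% nr + 1
      if (r < 3 || r > nr - 2 || c < 3 || c > nr - 2) return(FALSE)
      all(lab[(r - 2):(r + 2), (c - 2):(c + 2)] == cls)
    }, logical(1))
    centers <- centers[ok][seq(1, sum(ok), length.out = n) + off]
    centers[!is.na(centers)]
  }
  for (p in punch(lab, 2L, 4, 0)) {
    r <- (p - 1) %% 256 + 1
    c <- (p - 1) %/% 256 + 1
    corrupted[(r - 1):(r + 1), (c - 1):(c + 1)] <- 0L
  }
  expect_false(identical(corrupted, lab))
  restored <- fill_cavities(label_mask(corrupted), min_cavity_px = 5)
  expect_identical(mask_values(restored), lab)

  # total pixel count preserved; only codes {0,1,2}
  expect_identical(length(restored), length(lab))
  expect_true(all(as.integer(restored) %in% 0:2))
  # monotone: never converts foreground to background
  expect_true(all(restored[corrupted != 0L] == corrupted[corrupted != 0L]))
})
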