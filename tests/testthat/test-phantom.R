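test_that("an empty scene is all background with an empty design table", {
  sc <- generate_scene(128, 128, n_fibers = 0, seed = 1)
  expect_s3_class(sc, "phantom_scene")
  expect_equal(nrow(sc$fibers), 0)
  expect_true(all(sc$mask == 0L))
  expect_identical(dim(sc$image), dim(unclass(sc$mask)))
})

test_that("mask class counts equal the summed per-fiber rasterized areas", {
  sc <- generate_scene(512, 512, n_fibers = 30, radius_range = c(8, 20),
                       noise_sd = 0, seed = 7)
  expect_equal(nrow(sc$fibers), 30)
  expect_true(all(sc$fibers$defect == "none"))
  expect_identical(sum(sc$mask == 2L), sum(sc$fibers$axon_area_px))
  expect_identical(sum(sc$mask == 1L), sum(sc$fibers$myelin_area_px))
  expect_identical(sum(sc$mask == 0L),
                   length(sc$mask) - sum(sc$fibers$axon_area_px) -
                     sum(sc$fibers$myelin_area_px))
})

test_that("identical seeds give bit-identical scenes", {
  a <- generate_scene(160, 160, n_fibers = 6, noise_sd = 0.05, blur_sigma = 0.7,
                      stain_style = "TB_like", seed = 11)
  b <- generate_scene(160, 160, n_fibers = 6, noise_sd = 0.05, blur_sigma = 0.7,
                      stain_style = "TB_like", seed = 11)
  expect_identical(a$image, b$image)
  expect_identical(unclass(a$mask), unclass(b$mask))
  expect_identical(a$fibers, b$fibers)
  c <- generate_scene(160, 160, n_fibers = 6, noise_sd = 0.05, blur_sigma = 0.7,
                      stain_style = "TB_like", seed = 12)
  expect_false(identical(a$image, c$image))
})

test_that("requested defect fractions produce exact designed counts", {
  sc <- generate_scene(512, 512, n_fibers = 20, radius_range = c(8, 14),
                       defect_fractions = c(oblique = 0.25), noise_sd = 0, seed = 3)
  expect_equal(sum(sc$fibers$defect == "oblique"), 5)
  # eccentricity recomputed from the rasterized masks by the moment oracle
  fs <- extract_fibers(sc$mask)
  idx <- match_design(sc$fibers, fs$fibers)
  ecc <- vapply(seq_len(nrow(sc$fibers)), function(i) {
    pix <- which(fs$axon_labels == fs$fibers$fiber_id[idx[i]])
    ecc_moment_oracle((pix - 1) %% nrow(fs$axon_labels),
                      (pix - 1) %/% nrow(fs$axon_labels))
  }, numeric(1))
  expect_equal(sum(ecc > 0.95), 5)
  expect_identical(which(ecc > 0.95), which(sc$fibers$defect == "oblique"))
})

test_that("designed defects land strictly beyond the selection thresholds", {
  sc <- generate_scene(512, 512, n_fibers = 16, radius_range = c(8, 14),
                       defect_counts = c(oblique = 4, incomplete = 4, undersized = 4),
                       noise_sd = 0, seed = 5)
  fs <- extract_fibers(sc$mask)
  expect_equal(nrow(fs$fibers), 16)
  idx <- match_design(sc$fibers, fs$fibers)
  f <- fs$fibers[idx, ]
  expect_true(all(f$eccentricity[sc$fibers$defect == "oblique"] > 0.95))
  expect_true(all(f$solidity[sc$fibers$defect == "incomplete"] < 0.9))
  expect_true(all(f$axon_area_px[sc$fibers$defect == "undersized"] < 50))
  clean <- sc$fibers$defect == "none"
  expect_true(all(f$eccentricity[clean] <= 0.95))
  expect_true(all(f$solidity[clean] >= 0.9))
  expect_true(all(f$axon_area_px[clean] >= 50))
})

test_that("truth table reports exact circular-fiber morphometrics", {
  # circular axon r = 10 px at g = 0.5 -> outer R = 20 px
  sc <- generate_scene(256, 256, n_fibers = 1, radius_range = c(10, 10),
                       g_ratio = 0.5, aspect_range = c(1, 1), noise_sd = 0, seed = 2)
  tt <- scene_truth_table(sc)
  expect_equal(tt$true_g_ratio, 0.5, tolerance = 1e-10)
  expect_equal(tt$true_axon_diameter_um, 2 * 10 * 0.05, tolerance = 1e-10)
  # r = 12, R = 16: thickness (R - r) * 0.05 = 0.2 um
  sc2 <- generate_scene(256, 256, n_fibers = 1, radius_range = c(12, 12),
                        g_ratio = 0.75, aspect_range = c(1, 1), noise_sd = 0, seed = 2)
  tt2 <- scene_truth_table(sc2)
  expect_equal(tt2$true_myelin_thickness_um, 0.2, tolerance = 1e-10)
  # ring-width oracle on the rasterized annulus: equivalent radii differ from
  # the continuous ring width by under half a pixel (0.025 um at 0.05 um/px)
  ax <- sum(sc2$mask == 2L)
  reg <- ax + sum(sc2$mask == 1L)
  expect_lt(abs((sqrt(reg / pi) - sqrt(ax / pi)) * 0.05 - 0.2), 0.025)
})

test_that("fibers have disjoint supports and valid geometry invariants", {
  sc <- generate_scene(384, 384, n_fibers = 12, radius_range = c(6, 14),
                       defect_counts = c(oblique = 3, incomplete = 3),
                       noise_sd = 0, seed = 9)
  f <- sc$fibers
  expect_true(all(f$outer_r_a > f$axon_r_a))
  expect_true(all(f$outer_r_b > f$axon_r_b))
  expect_true(all(f$axon_r_a >= f$axon_r_b))
  expect_true(all(f$true_g_ratio > 0 & f$true_g_ratio < 1))
  clean <- f$defect == "none"
  expect_true(all(f$axon_r_a[clean] / f$axon_r_b[clean] <= 1.2))
  expect_true(all(f$axon_area_px[clean] >= 50))
  # disjoint: extraction finds exactly the designed number of components
  expect_equal(max(extract_fibers(sc$mask)$axon_labels), 12)
})

test_that("overcrowded scenes fail with a density error", {
  expect_error(
    generate_scene(96, 96, n_fibers = 60, radius_range = c(8, 12), seed = 1),
    "density"
  )
  expect_error(generate_scene(128, 128, 5, defect_fractions = c(oblique = 0.9, incomplete = 0.3)),
               "sum")
})

test_that("scenes round-trip to disk losslessly", {
  dir <- withr::local_tempdir()
  sc <- generate_scene(96, 96, n_fibers = 3, radius_range = c(5, 8),
                       noise_sd = 0.02, seed = 4)
  write_scene(sc, dir)
  m <- read_mask_png(file.path(dir, "mask.png"))
  expect_identical(unclass(m), unclass(sc$mask))
  tt <- read.csv(file.path(dir, "truth.csv"))
  expect_equal(tt$true_g_ratio, sc$fibers$true_g_ratio, tolerance = 1e-12)
})
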