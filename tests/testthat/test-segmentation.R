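# Tiny-network tests: the architecture is exercised at desk scale (2-level,
# 4/8 filters, 16-64 px patches); the full 6-level/16..512 config remains
# constructible but is far too heavy for routine runs.

test_that("config validation enforces architecture constraints", {
  expect_error(unet_config(depths = c(16, 8)), "strictly increasing")
  expect_error(unet_config(depths = c(8, 16, 32), patch_size = 130), "multiple")
  cfg <- unet_config_full()
  expect_identical(cfg$depths, c(16L, 32L, 64L, 128L, 256L, 512L))
  expect_identical(cfg$patch_size, 512L)
  expect_identical(cfg$stride, 2L)
  expect_equal(cfg$learning_rate, 1e-3)
})

test_that("analytic gradients match central finite differences", {
  withr::local_seed(1)
  ptr <- gratior:::.unet_create(c(4L, 8L), 42L)
  img <- matrix(runif(16 * 16), 16, 16)
  lab <- matrix(sample(0:2, 256, TRUE), 16, 16)
  w <- gratior:::.unet_get_params(ptr)
  g <- gratior:::.unet_grads(ptr, img, lab)
  eps <- 1e-5
  for (p in seq_along(w)) {
    i <- sample(length(w[[p]]), 1)
    wp <- w
    wp[[p]][i] <- wp[[p]][i] + eps
    gratior:::.unet_set_params(ptr, wp)
    lp <- gratior:::.unet_loss(ptr, img, lab)
    wm <- w
    wm[[p]][i] <- wm[[p]][i] - eps
    gratior:::.unet_set_params(ptr, wm)
    lm <- gratior:::.unet_loss(ptr, img, lab)
    expect_equal(g[[p]][i], (lp - lm) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("training is deterministic and validates its inputs", {
  scenes <- lapply(1:3, function(i) {
    generate_scene(64, 64, n_fibers = 2, radius_range = c(5, 7),
                   noise_sd = 0.02, seed = 40 + i)
  })
  imgs <- lapply(scenes, `[[`, "image")
  msks <- lapply(scenes, `[[`, "mask")
  cfg <- unet_config(depths = c(4, 8), patch_size = 64, epochs = 2, seed = 3)
  m1 <- train_segmenter(imgs, msks, cfg, quiet = TRUE)
  m2 <- train_segmenter(imgs, msks, cfg, quiet = TRUE)
  expect_identical(m1$log, m2$log)   # bit-identical metric logs

  expect_error(train_segmenter(list(), list(), cfg), "empty")
  expect_error(train_segmenter(imgs[1], list(matrix(0L, 32, 32)), cfg), "mismatch")
})

test_that("a degenerate all-background patch is fit to high confidence", {
  # a constant image carries no per-patch contrast, so only bias terms move
  # the logits: the degenerate fit needs many cheap steps at a higher rate
  img <- matrix(0.5, 32, 32)
  msk <- label_mask(matrix(0L, 32, 32))
  cfg <- unet_config(depths = c(4, 8), patch_size = 32, epochs = 300,
                     augmentations = character(0), learning_rate = 1e-2, seed = 1)
  model <- train_segmenter(list(img), list(msk), cfg, quiet = TRUE)
  pm <- predict_probabilities(img, model)
  expect_gte(min(pm[, , 1]), 0.99)
})

test_that("prediction preserves shape and normalization, padding as needed", {
  withr::local_seed(2)
  ptr <- gratior:::.unet_create(c(4L, 8L), 7L)
  model <- structure(list(ptr = ptr, depths = c(4L, 8L)), class = "seg_model")
  img <- matrix(runif(50 * 70), 50, 70)   # not a multiple of the stride
  pm <- predict_probabilities(img, model)
  expect_identical(dim(pm)[1:2], dim(img))
  sums <- pm[, , 1] + pm[, , 2] + pm[, , 3]
  expect_lt(max(abs(sums - 1)), 1e-6)
  # tiled prediction also matches the input shape
  pm2 <- predict_probabilities(img, model, tile = 32, overlap = 8)
  expect_identical(dim(pm2)[1:2], dim(img))
  expect_error(predict_probabilities(matrix(0.1, 8, 8), model), "at least 16")
})

test_that("training improves the fit on average over several seeds", {
  first_last <- sapply(1:3, function(s) {
    scenes <- lapply(1:3, function(i) {
      generate_scene(64, 64, n_fibers = 2, radius_range = c(5, 7),
                     noise_sd = 0.02, seed = 60 + 10 * s + i)
    })
    cfg <- unet_config(depths = c(4, 8), patch_size = 64, epochs = 4, seed = s)
    m <- train_segmenter(lapply(scenes, `[[`, "image"),
                         lapply(scenes, `[[`, "mask"), cfg, quiet = TRUE)
    c(first = m$log$train_loss[1], last = m$log$train_loss[4])
  })
  expect_lt(mean(first_last["last", ]), mean(first_last["first", ]))
})

test_that("checkpoints round-trip through save and load", {
  scenes <- lapply(1:2, function(i) {
    generate_scene(64, 64, n_fibers = 2, radius_range = c(5, 7), seed = 80 + i)
  })
  cfg <- unet_config(depths = c(4, 8), patch_size = 64, epochs = 1, seed = 5)
  model <- train_segmenter(lapply(scenes, `[[`, "image"),
                           lapply(scenes, `[[`, "mask"), cfg, quiet = TRUE)
  path <- withr::local_tempfile(fileext = ".rds")
  save_segmenter(model, path)
  reloaded <- load_segmenter(path)
  img <- scenes[[1]]$image
  expect_identical(unclass(predict_probabilities(img, model)),
                   unclass(predict_probabilities(img, reloaded)))
})
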