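test_that("untrained network with zero biases scores every pixel (0.5, 0.5)", {
  tiny <- fixture_tiny()
  sc <- score_pixels(tiny$model, tiny$image)$scores
  # zero-logit softmax is exactly symmetric only at the head; an untrained
  # net still produces logits, so check the simplex property and symmetry of
  # a genuinely zero-logit model
  expect_lt(max(abs(sc[, , 1] + sc[, , 2] - 1)), 1e-5)
  zero_model <- tiny$model
  for (nm in names(zero_model$params)) {
    zero_model$params[[nm]]$w[] <- 0
    zero_model$params[[nm]]$b[] <- 0
  }
  sc0 <- score_pixels(zero_model, tiny$image)$scores
  expect_lt(max(abs(sc0 - 0.5)), 1e-5)
})

test_that("saturated toy scorer gives near-certain probabilities and the exact mask", {
  sq <- fixture_square_scorer()
  img <- image_tile(array(0.5, dim = c(32, 32, 3)), id = "flat")
  sc <- score_pixels(sq$model, img)$scores
  expect_true(all(sc[, , 2][sq$inside] > 0.99))
  expect_true(all(sc[, , 2][!sq$inside] < 0.01))
  expect_identical(predict_mask(sq$model, img)$mask, sq$inside)
})

test_that("all-background scorer yields an empty mask", {
  m <- toy_seg_model(score_fn = function(image)
    array(c(matrix(0.9, 16, 16), matrix(0.1, 16, 16)), dim = c(16, 16, 2)))
  img <- image_tile(array(0.5, dim = c(16, 16, 3)))
  expect_false(any(predict_mask(m, img)$mask))
})

test_that("training requires data and at least one epoch", {
  expect_error(train_reference_model(list(), epochs = 1), "at least one")
  st <- generate_tile(synth_params(height = 32, width = 32, n_nuclei = 3,
                                   min_spacing = 10, seed = 1))
  expect_error(train_reference_model(list(list(image = st$image, mask = st$mask)),
                                     epochs = 0), "epochs")
})

test_that("training is deterministic: same seed, same data, identical predictions", {
  st <- generate_tile(synth_params(height = 32, width = 32, n_nuclei = 3,
                                   min_spacing = 10, seed = 5))
  pairs <- list(list(image = st$image, mask = st$mask))
  m1 <- train_reference_model(pairs, epochs = 2, seed = 42, base_channels = 4)
  m2 <- train_reference_model(pairs, epochs = 2, seed = 42, base_channels = 4)
  expect_identical(m1$params, m2$params)
  expect_identical(score_pixels(m1, st$image)$scores,
                   score_pixels(m2, st$image)$scores)
})

test_that("feature stacks have the advertised shape and are reproducible", {
  tiny <- fixture_tiny()
  fs <- feature_stack(tiny$model, tiny$image, "dec2")
  expect_identical(dim(fs$maps), c(16L, 16L, 4L))   # input resolution, K = base channels
  expect_identical(fs$n_pixels, 256L)
  fs2 <- feature_stack(tiny$model, tiny$image, "dec2")
  expect_identical(fs$maps, fs2$maps)
  enc2 <- feature_stack(tiny$model, tiny$image, "enc2")
  expect_identical(dim(enc2$maps), c(8L, 8L, 8L))   # one pooling, 2x channels
  expect_error(feature_stack(tiny$model, tiny$image, "nope"), "enc1")
})

test_that("score gradients match central finite differences on a tiny network", {
  for (seed in c(3, 11, 29)) {
    tiny <- fixture_tiny(seed)
    g <- score_gradient(tiny$model, tiny$image, class_index = 2L,
                        region = "all", layer_id = "dec2")
    acts <- feature_stack(tiny$model, tiny$image, "dec2")$maps
    set.seed(seed)
    sample_idx <- sample(length(acts), 50)
    h <- 1e-3
    for (ix in sample_idx) {
      ap <- acts; ap[ix] <- ap[ix] + h
      am <- acts; am[ix] <- am[ix] - h
      yp <- sum(nucleicam:::.forward_from(tiny$model, "dec2", ap)[, , 2])
      ym <- sum(nucleicam:::.forward_from(tiny$model, "dec2", am)[, , 2])
      fd <- (yp - ym) / (2 * h)
      expect_lt(abs(g[ix] - fd) / max(abs(fd), 1e-4), 1e-3)
    }
  }
})

test_that("empty region gives an identically zero gradient", {
  tiny <- fixture_tiny()
  empty <- region_of_interest(matrix(FALSE, 16, 16))
  g <- score_gradient(tiny$model, tiny$image, region = empty, layer_id = "dec2")
  expect_true(all(g == 0))
})

test_that("reference model reaches pixelwise Dice >= 0.80 on held-out tiles", {
  fx <- fixture_pipeline()
  # training-set fit
  train_dice <- vapply(fx$train[1:5], function(s) {
    precision_recall_dice(pixel_confusion(predict_mask(fx$model, s$image),
                                          s$mask))["dice"]
  }, numeric(1))
  expect_gte(mean(train_dice), 0.85)
  # held-out generalization
  test_dice <- vapply(fx$test, function(s) {
    precision_recall_dice(pixel_confusion(predict_mask(fx$model, s$image),
                                          s$mask))["dice"]
  }, numeric(1))
  expect_gte(mean(test_dice), 0.80)
  # predicted mask is nonempty when nuclei are present
  expect_gt(sum(predict_mask(fx$model, fx$test[[1]]$image)$mask), 0)
})

test_that("model checkpoints round-trip through a run directory", {
  st <- generate_tile(synth_params(height = 32, width = 32, n_nuclei = 3,
                                   min_spacing = 10, seed = 5))
  m <- train_reference_model(list(list(image = st$image, mask = st$mask)),
                             epochs = 1, seed = 1, base_channels = 4)
  dir <- withr::local_tempdir()
  save_model(m, dir)
  expect_true(file.exists(file.path(dir, "model.json")))
  m2 <- load_model(dir)
  expect_identical(score_pixels(m2, st$image)$scores,
                   score_pixels(m, st$image)$scores)
})
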