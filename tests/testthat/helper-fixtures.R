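# Shared fixtures. The trained reference model is expensive (~1 min), so it
# is built lazily once per test run and reused by every test that needs it.

.fixture_cache <- new.env(parent = emptyenv())

# 20 easy training tiles + 5 held-out tiles, 128 x 128, ~15 well-separated
# nuclei each; reference model trained 15 epochs from seed 0
fixture_pipeline <- function() {
  if (!is.null(.fixture_cache$pipeline)) return(.fixture_cache$pipeline)
  train_tiles <- lapply(1:20, function(i)
    generate_tile(synth_params(seed = i), id = sprintf("train_%02d", i)))
  test_tiles <- lapply(21:25, function(i)
    generate_tile(synth_params(seed = i), id = sprintf("test_%02d", i)))
  model <- train_reference_model(
    lapply(train_tiles, function(s) list(image = s$image, mask = s$mask)),
    epochs = 15, seed = 0)
  .fixture_cache$pipeline <- list(model = model, train = train_tiles,
                                  test = test_tiles)
  .fixture_cache$pipeline
}

# tiny differentiable network on a 16 x 16 tile, for gradient checks
fixture_tiny <- function(seed = 7) {
  set.seed(seed + 1000)
  img <- image_tile(array(runif(16 * 16 * 3), dim = c(16, 16, 3)), id = "tiny")
  model <- new_seg_model(base_channels = 4, seed = seed)
  list(model = model, image = img)
}

# toy backend whose nucleus score plane IS its single feature map:
# y_c = sum_P A, so d y_c / d A_uv = 1 on P and the CAM is ReLU(A)
fixture_linear_toy <- function(feature_map) {
  H <- nrow(feature_map); W <- ncol(feature_map)
  toy_seg_model(
    score_fn = function(image) {
      array(c(1 - feature_map, feature_map), dim = c(H, W, 2))
    },
    feature_fn = function(image, layer_id) array(feature_map, dim = c(H, W, 1)),
    grad_fn = function(image, class_index, region_mask, layer_id) {
      g <- matrix(0, H, W); g[region_mask] <- 1
      array(g, dim = c(H, W, 1))
    })
}

# toy scorer saturated inside a known square (nucleus logit +10 / -10)
fixture_square_scorer <- function(H = 32, W = 32, r1 = 8, r2 = 16, c1 = 8, c2 = 16) {
  inside <- matrix(FALSE, H, W); inside[r1:r2, c1:c2] <- TRUE
  p_nuc <- ifelse(inside, 1 / (1 + exp(-20)), 1 / (1 + exp(20)))
  list(model = toy_seg_model(score_fn = function(image)
         array(c(1 - p_nuc, p_nuc), dim = c(H, W, 2))),
       inside = inside)
}
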