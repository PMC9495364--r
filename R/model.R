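# Reference segmentation network: a compact 3-level encoder-decoder trained
# with the Dice loss, small enough that the whole detection pipeline runs in
# CPU minutes. The model contract (per-pixel class scores, named feature
# stacks, gradients of score reductions w.r.t. those features) is generic, so
# any backend exposing the three capabilities can be plugged in.

MODEL_CLASSES <- c("background", "nucleus")

.model_ops <- function(base = 16L) {
  list(
    list(kind = "conv", name = "enc1",       relu = TRUE,  k = 3L, cin = 3L,        cout = base),
    list(kind = "pool"),
    list(kind = "conv", name = "enc2",       relu = TRUE,  k = 3L, cin = base,      cout = 2L * base),
    list(kind = "pool"),
    list(kind = "conv", name = "bottleneck", relu = TRUE,  k = 3L, cin = 2L * base, cout = 2L * base),
    list(kind = "up"),
    list(kind = "conv", name = "dec1",       relu = TRUE,  k = 3L, cin = 2L * base, cout = base),
    list(kind = "up"),
    list(kind = "conv", name = "dec2",       relu = TRUE,  k = 3L, cin = base,      cout = base),
    list(kind = "conv", name = "head",       relu = FALSE, k = 1L, cin = base,      cout = 2L)
  )
}

#' Create an untrained reference segmentation network
#'
#' A 3-level encoder-decoder (2x pooling twice, nearest-neighbour upsampling
#' back to input resolution) with `base_channels` channels at the first level
#' and a softmax head over two classes (background, nucleus). Weights are
#' He-initialised from `seed`; biases start at zero, so the untrained network
#' scores every pixel (0.5, 0.5).
#'
#' @param base_channels channels at the first encoder level (default 16).
#' @param seed integer RNG seed for weight initialisation.
#' @return An object of class `seg_model`.
#' @export
new_seg_model <- function(base_channels = 16L, seed = 1L) {
  ops <- .model_ops(as.integer(base_channels))
  set.seed(seed)
  params <- list()
  for (op in ops) {
    if (op$kind != "conv") next
    n <- op$k * op$k * op$cin * op$cout
    sdv <- sqrt(2 / (op$k * op$k * op$cin))
    params[[op$name]] <- list(
      w = array(stats::rnorm(n, 0, sdv), dim = c(op$k, op$k, op$cin, op$cout)),
      b = numeric(op$cout))
  }
  structure(list(ops = ops, params = params, class_names = MODEL_CLASSES,
                 base_channels = as.integer(base_channels),
                 trained = FALSE, training = NULL),
            class = "seg_model")
}

#' Names of the feature layers a model exposes
#' @param model a `seg_model`.
#' @return character vector of exposed layer ids.
#' @export
model_layers <- function(model) {
  vapply(Filter(function(o) o$kind == "conv", model$ops), `[[`, "", "name")
}

.layer_index <- function(model, layer_id) {
  for (i in seq_along(model$ops))
    if (model$ops[[i]]$kind == "conv" && identical(model$ops[[i]]$name, layer_id))
      return(i)
  stop("unknown layer '", layer_id, "'; exposed layers: ",
       paste(model_layers(model), collapse = ", "), call. = FALSE)
}

.check_input <- function(model, x) {
  d <- dim(x)
  if (d[1] %% 4L != 0L || d[2] %% 4L != 0L)
    stop("input height and width must be multiples of 4 (two 2x poolings); got ",
         d[1], " x ", d[2], call. = FALSE)
}

.softmax2 <- function(z) {
  # channelwise softmax, numerically stabilised
  m <- pmax(z[, , 1], z[, , 2])
  e1 <- exp(z[, , 1] - m); e2 <- exp(z[, , 2] - m)
  s <- e1 + e2
  array(c(e1 / s, e2 / s), dim = dim(z))
}

.forward <- function(model, x) {
  caches <- vector("list", length(model$ops))
  for (i in seq_along(model$ops)) {
    op <- model$ops[[i]]
    if (op$kind == "conv") {
      p <- model$params[[op$name]]
      y <- conv2d_fwd(x, p$w, p$b, op$relu)
      caches[[i]] <- list(x = x, y = y)
      x <- y
    } else if (op$kind == "pool") {
      r <- maxpool2_fwd(x)
      caches[[i]] <- list(arg = r$arg, in_dim = dim(x))
      x <- r$y
    } else { # up
      x <- upsample2_fwd(x)
    }
  }
  list(logits = x, scores = .softmax2(x), caches = caches)
}

# Backward from d(loss)/d(scores). Propagates through the softmax and then the
# op stack. If stop_at > 0, returns the gradient w.r.t. the output of op
# `stop_at` without touching parameters; otherwise returns per-layer dw/db.
.backward <- function(model, fwd, dscores, stop_at = 0L) {
  s <- fwd$scores
  inner <- dscores[, , 1] * s[, , 1] + dscores[, , 2] * s[, , 2]
  dy <- array(c(s[, , 1] * (dscores[, , 1] - inner),
                s[, , 2] * (dscores[, , 2] - inner)), dim = dim(s))
  grads <- list()
  for (i in rev(seq_along(model$ops))) {
    if (i == stop_at) return(dy)
    op <- model$ops[[i]]
    if (op$kind == "conv") {
      cc <- fwd$caches[[i]]
      p <- model$params[[op$name]]
      g <- conv2d_bwd(cc$x, p$w, dy, cc$y, op$relu)
      grads[[op$name]] <- list(dw = g$dw, db = g$db)
      dy <- g$dx
    } else if (op$kind == "pool") {
      cc <- fwd$caches[[i]]
      dy <- maxpool2_bwd(dy, cc$arg, cc$in_dim)
    } else {
      dy <- upsample2_bwd(dy)
    }
  }
  grads
}

# Recompute class scores from a replacement activation at `layer_id`,
# holding all downstream weights fixed (used by finite-difference checks).
.forward_from <- function(model, layer_id, acts) {
  li <- .layer_index(model, layer_id)
  x <- acts
  ops <- model$ops
  if (li < length(ops)) for (i in (li + 1L):length(ops)) {
    op <- ops[[i]]
    x <- switch(op$kind,
      conv = conv2d_fwd(x, model$params[[op$name]]$w, model$params[[op$name]]$b, op$relu),
      pool = maxpool2_fwd(x)$y,
      up = upsample2_fwd(x))
  }
  .softmax2(x)
}

.tile_pixels <- function(image) {
  if (inherits(image, "ImageTile")) image$pixels else image
}

#' Per-pixel class probabilities
#'
#' Runs a forward pass and returns the softmax probability of each class at
#' every pixel (probabilities over classes sum to 1 at each pixel).
#'
#' @param model a model satisfying the backend contract (e.g. [new_seg_model()],
#'   [train_reference_model()], or [toy_seg_model()]).
#' @param image an [image_tile()].
#' @return A `ClassScoreMap`: list with `scores` (H x W x C array) and
#'   `class_names`.
#' @export
score_pixels <- function(model, image) UseMethod("score_pixels")

#' @export
score_pixels.seg_model <- function(model, image) {
  x <- .tile_pixels(image)
  .check_input(model, x)
  fwd <- .forward(model, x)
  structure(list(scores = fwd$scores, class_names = model$class_names),
            class = "ClassScoreMap")
}

#' Activations of a named feature layer
#'
#' Captures the (post-ReLU) activation stack A^k at `layer_id` during a
#' forward pass. For the reference network the default Grad-CAM layer `dec2`
#' sits at input resolution, so h = H and w = W.
#'
#' @inheritParams score_pixels
#' @param layer_id one of [model_layers()].
#' @return A `FeatureStack`: list with `maps` (h x w x K array), `layer_id`,
#'   `n_pixels` (= h * w).
#' @export
feature_stack <- function(model, image, layer_id = "dec2") UseMethod("feature_stack")

#' @export
feature_stack.seg_model <- function(model, image, layer_id = "dec2") {
  x <- .tile_pixels(image)
  .check_input(model, x)
  li <- .layer_index(model, layer_id)
  maps <- .forward(model, x)$caches[[li]]$y
  structure(list(maps = maps, layer_id = layer_id,
                 n_pixels = dim(maps)[1] * dim(maps)[2]),
            class = "FeatureStack")
}

#' Gradient of a reduced class score w.r.t. a feature layer
#'
#' Reduces the per-pixel post-softmax scores of class `class_index` over
#' `region` to a scalar and returns its gradient with respect to each element
#' of the activation stack at `layer_id`. An empty region yields an all-zero
#' gradient.
#'
#' @inheritParams feature_stack
#' @param class_index 1-based class index (2 = nucleus by default ordering).
#' @param region a [region_of_interest()], `"all"`, or a logical matrix.
#' @return h x w x K numeric array of gradients.
#' @export
score_gradient <- function(model, image, class_index = 2L, region = "all",
                           layer_id = "dec2") UseMethod("score_gradient")

#' @export
score_gradient.seg_model <- function(model, image, class_index = 2L,
                                     region = "all", layer_id = "dec2") {
  x <- .tile_pixels(image)
  .check_input(model, x)
  if (class_index < 1L || class_index > length(model$class_names))
    stop("class_index out of range", call. = FALSE)
  li <- .layer_index(model, layer_id)
  fwd <- .forward(model, x)
  d <- dim(fwd$scores)
  rm_ <- region_mask(region, d[1], d[2])
  dscores <- array(0, dim = d)
  plane <- matrix(0, d[1], d[2]); plane[rm_] <- 1
  dscores[, , class_index] <- plane
  .backward(model, fwd, dscores, stop_at = li)
}

#' Predicted binary nucleus mask
#'
#' Argmax over classes; a pixel is nucleus iff its nucleus probability is
#' strictly greater than its background probability (ties go to background).
#'
#' @inheritParams score_pixels
#' @return A [binary_mask()].
#' @export
predict_mask <- function(model, image) UseMethod("predict_mask")

#' @export
predict_mask.seg_model <- function(model, image) {
  sc <- score_pixels(model, image)$scores
  binary_mask(sc[, , 2] > sc[, , 1],
              id = if (inherits(image, "ImageTile")) image$id else "mask")
}

# Class-averaged (generalised) Dice loss over the two softmax planes;
# averaging over background and nucleus keeps the all-foreground and
# all-background configurations away from the loss plateau.
.dice_loss_grad <- function(scores, t, eps = 1e-6) {
  # scores: H x W x 2 softmax array; t: 0/1 nucleus truth plane
  dsc <- array(0, dim = dim(scores))
  loss <- 0
  for (ch in 1:2) {
    p <- scores[, , ch]
    tc <- if (ch == 2) t else 1 - t
    num <- 2 * sum(p * tc) + eps
    den <- sum(p) + sum(tc) + eps
    loss <- loss + (1 - num / den) / 2
    dsc[, , ch] <- -(2 * tc * den - num) / den^2 / 2
  }
  list(loss = loss, dscores = dsc)
}

#' Train the reference network on image/mask pairs
#'
#' Dice-loss training with SGD plus momentum and a piecewise learning-rate
#' schedule (multiplied by `lr_drop` every `lr_period` epochs), L2 weight
#' decay. Fully deterministic given `seed`: same seed, same data, same
#' platform give bitwise-identical weights.
#'
#' @param train_pairs list of `list(image = ImageTile, mask = BinaryMask)`.
#' @param epochs number of passes over the training set (>= 1).
#' @param seed integer seed controlling initialisation and tile order.
#' @param base_channels first-level channel count.
#' @param lr,momentum,l2 optimiser settings (SGD with momentum).
#' @param lr_drop,lr_period learning-rate schedule: `lr * lr_drop^(floor(epoch/lr_period))`.
#' @param warmup epochs of linear learning-rate warmup (stabilises the first
#'   momentum updates).
#' @param clip_norm global L2 gradient-norm ceiling per update; ordinary
#'   Dice-loss gradients sit far below it, so only rare spikes are rescaled.
#' @param verbose print per-epoch mean Dice loss.
#' @return A trained `seg_model`; `$training$loss` holds the per-epoch mean
#'   Dice loss trajectory.
#' @export
train_reference_model <- function(train_pairs, epochs = 15L, seed = 1L,
                                  base_channels = 16L, lr = 0.005,
                                  momentum = 0.9, l2 = 5e-4,
                                  lr_drop = 0.94, lr_period = 2L,
                                  warmup = 3L, clip_norm = 1,
                                  verbose = FALSE) {
  if (length(train_pairs) < 1L) stop("need at least one training pair", call. = FALSE)
  epochs <- as.integer(epochs)
  if (epochs < 1L) stop("epochs must be >= 1", call. = FALSE)
  for (pr in train_pairs) {
    if (!inherits(pr$image, "ImageTile") || !inherits(pr$mask, "BinaryMask"))
      stop("train_pairs must be lists of (image = ImageTile, mask = BinaryMask)",
           call. = FALSE)
    if (!identical(dim(pr$image$pixels)[1:2], dim(pr$mask$mask)))
      stop("image/mask shape mismatch for tile '", pr$image$id, "'", call. = FALSE)
  }
  model <- new_seg_model(base_channels = base_channels, seed = seed)
  vel <- lapply(model$params, function(p) list(w = array(0, dim(p$w)), b = numeric(length(p$b))))
  loss_hist <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    # linear warmup over the first warmup epochs guards against early
    # momentum spikes killing every rectifier, then piecewise decay
    lr_ep <- lr * lr_drop^((ep - 1L) %/% lr_period) * min(1, ep / warmup)
    ord <- sample.int(length(train_pairs))
    losses <- numeric(length(ord))
    for (t in seq_along(ord)) {
      pr <- train_pairs[[ord[t]]]
      x <- pr$image$pixels
      .check_input(model, x)
      fwd <- .forward(model, x)
      dl <- .dice_loss_grad(fwd$scores, pr$mask$mask * 1)
      losses[t] <- dl$loss
      grads <- .backward(model, fwd, dl$dscores)
      # global-norm gradient clipping: rare loss spikes near softmax
      # saturation otherwise produce one huge update that deadens every
      # rectifier and ends training on a zero-gradient plateau
      gn <- sqrt(sum(vapply(grads, function(g) sum(g$dw^2) + sum(g$db^2),
                            numeric(1))))
      clip_scale <- if (gn > clip_norm) clip_norm / gn else 1
      for (nm in names(grads)) {
        g <- grads[[nm]]
        if (clip_scale < 1) { g$dw <- g$dw * clip_scale; g$db <- g$db * clip_scale }
        vel[[nm]]$w <- momentum * vel[[nm]]$w - lr_ep * (g$dw + l2 * model$params[[nm]]$w)
        vel[[nm]]$b <- momentum * vel[[nm]]$b - lr_ep * g$db
        model$params[[nm]]$w <- model$params[[nm]]$w + vel[[nm]]$w
        model$params[[nm]]$b <- model$params[[nm]]$b + vel[[nm]]$b
      }
    }
    loss_hist[ep] <- mean(losses)
    if (verbose) message(sprintf("epoch %d/%d  lr %.4f  dice loss %.4f",
                                 ep, epochs, lr_ep, loss_hist[ep]))
  }
  model$trained <- TRUE
  model$training <- list(epochs = epochs, seed = seed, lr = lr,
                         momentum = momentum, l2 = l2, lr_drop = lr_drop,
                         lr_period = lr_period, n_tiles = length(train_pairs),
                         loss = loss_hist)
  model
}

#' Save / load a model checkpoint
#'
#' The weights are stored in R's native serialized form; a JSON sidecar
#' records layer names, class names, and the training configuration.
#'
#' @param model a `seg_model`.
#' @param dir run directory (created if missing).
#' @return `save_model` returns `dir` invisibly; `load_model` returns the model.
#' @export
save_model <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "model.rds"))
  side <- list(layers = as.list(model_layers(model)),
               class_names = as.list(model$class_names),
               base_channels = model$base_channels,
               trained = model$trained,
               training = model$training[setdiff(names(model$training), "loss")])
  jsonlite::write_json(side, file.path(dir, "model.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  f <- file.path(dir, "model.rds")
  if (!file.exists(f)) stop("no checkpoint found in '", dir, "'", call. = FALSE)
  readRDS(f)
}

#' Wrap arbitrary functions into the model contract
#'
#' Builds a model object from three user functions so that toy or external
#' backends can drive the Grad-CAM pipeline. Any of the three capabilities
#' may be omitted; calling the missing one raises a capability error.
#'
#' @param score_fn function(image) -> H x W x C score array (softmax scale).
#' @param feature_fn function(image, layer_id) -> h x w x K activation array.
#' @param grad_fn function(image, class_index, region_mask, layer_id) ->
#'   h x w x K gradient array. If `NULL` the backend is non-differentiable.
#' @param class_names class labels (default background/nucleus).
#' @param layers ids accepted by `feature_fn`.
#' @return An object of class `toy_seg_model` satisfying the backend contract.
#' @export
toy_seg_model <- function(score_fn, feature_fn = NULL, grad_fn = NULL,
                          class_names = MODEL_CLASSES, layers = "toy") {
  structure(list(score_fn = score_fn, feature_fn = feature_fn,
                 grad_fn = grad_fn, class_names = class_names, layers = layers),
            class = "toy_seg_model")
}

#' @export
score_pixels.toy_seg_model <- function(model, image) {
  structure(list(scores = model$score_fn(image), class_names = model$class_names),
            class = "ClassScoreMap")
}

#' @export
feature_stack.toy_seg_model <- function(model, image, layer_id = model$layers[1]) {
  if (is.null(model$feature_fn))
    stop("this backend does not expose feature stacks", call. = FALSE)
  if (!layer_id %in% model$layers)
    stop("unknown layer '", layer_id, "'; exposed layers: ",
         paste(model$layers, collapse = ", "), call. = FALSE)
  maps <- model$feature_fn(image, layer_id)
  structure(list(maps = maps, layer_id = layer_id,
                 n_pixels = dim(maps)[1] * dim(maps)[2]),
            class = "FeatureStack")
}

#' @export
score_gradient.toy_seg_model <- function(model, image, class_index = 2L,
                                         region = "all",
                                         layer_id = model$layers[1]) {
  if (is.null(model$grad_fn))
    stop("this backend is not differentiable", call. = FALSE)
  sc <- model$score_fn(image)
  rm_ <- region_mask(region, dim(sc)[1], dim(sc)[2])
  model$grad_fn(image, class_index, rm_, layer_id)
}

#' @export
predict_mask.toy_seg_model <- function(model, image) {
  sc <- score_pixels(model, image)$scores
  binary_mask(sc[, , 2] > sc[, , 1],
              id = if (inherits(image, "ImageTile")) image$id else "mask")
}

#' @export
print.seg_model <- function(x, ...) {
  cat("<seg_model> 3-level encoder-decoder,", x$base_channels, "base channels,",
      if (x$trained) "trained" else "untrained", "\n")
  cat("  layers:", paste(model_layers(x), collapse = " > "), "\n")
  invisible(x)
}
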