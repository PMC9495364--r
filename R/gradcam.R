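# Grad-CAM for semantic segmentation. The per-pixel post-softmax scores of
# the class of interest are reduced over a pixel region P to a scalar
#   y_c = sum_{(u,v) in P} Y^c_(u,v),
# the gradient of y_c with respect to a chosen activation stack A^k is
# averaged over pixels to give one weight per channel,
#   a_c^k = (1/N) sum_{u,v} d y_c / d A^k_(u,v),
# and the saliency map is the rectified weighted sum
#   L_c = ReLU( sum_k a_c^k A^k ),
# bilinearly upsampled to input resolution. For a segmentation network this
# map peaks near nucleus centroids, which is what the detector exploits.

#' Reduce per-pixel class scores to a scalar
#'
#' Sums the post-softmax score of class `class_index` over the pixels of
#' `region`.
#'
#' @param scores a `ClassScoreMap` (from [score_pixels()]) or an H x W x C array.
#' @param class_index 1-based class index.
#' @param region a [region_of_interest()], `"all"`, or a logical matrix.
#' @return scalar class score y_c.
#' @export
class_score <- function(scores, class_index = 2L, region = "all") {
  sc <- if (inherits(scores, "ClassScoreMap")) scores$scores else scores
  if (class_index < 1L || class_index > dim(sc)[3])
    stop("class_index out of range", call. = FALSE)
  rm_ <- region_mask(region, dim(sc)[1], dim(sc)[2])
  sum(sc[, , class_index][rm_])
}

#' Channel weights from score gradients
#'
#' Global-average-pools the gradient grid: one weight per channel,
#' a_c^k = (1/N) sum over the h x w pixels of the gradient for channel k.
#'
#' @param gradients h x w x K numeric array (from [score_gradient()]).
#' @param n_pixels N = h * w; must match the grid.
#' @param class_index class the gradients refer to (carried as metadata).
#' @return A `CamWeights`: list with `weights` (length K) and `class_index`.
#' @export
channel_weights <- function(gradients, n_pixels = NULL, class_index = 2L) {
  d <- dim(gradients)
  if (is.null(d) || length(d) != 3L)
    stop("`gradients` must be an h x w x K array", call. = FALSE)
  if (is.null(n_pixels)) n_pixels <- d[1] * d[2]
  if (n_pixels != d[1] * d[2])
    stop("n_pixels (", n_pixels, ") does not match the gradient grid (",
         d[1] * d[2], ")", call. = FALSE)
  w <- apply(gradients, 3L, sum) / n_pixels
  structure(list(weights = as.numeric(w), class_index = as.integer(class_index)),
            class = "CamWeights")
}

#' Bilinear image resize
#'
#' Corner-aligned bilinear interpolation of a matrix to a target size
#' (used to bring feature-resolution saliency maps to input resolution).
#'
#' @param m numeric matrix.
#' @param H,W target size; must be >= the source size.
#' @return H x W numeric matrix.
#' @export
bilinear_resize <- function(m, H, W) {
  h <- nrow(m); w <- ncol(m)
  if (H < h || W < w)
    stop("target size must not be smaller than the source grid", call. = FALSE)
  if (h == H && w == W) return(m)
  src_r <- if (H == 1L) rep(1, H) else 1 + (seq_len(H) - 1) * (h - 1) / (H - 1)
  src_c <- if (W == 1L) rep(1, W) else 1 + (seq_len(W) - 1) * (w - 1) / (W - 1)
  r0 <- pmin(floor(src_r), h - 1L); r0[h == 1] <- 1
  c0 <- pmin(floor(src_c), w - 1L); c0[w == 1] <- 1
  if (h == 1L) { r0 <- rep(1L, H); fr <- rep(0, H) } else fr <- src_r - r0
  if (w == 1L) { c0 <- rep(1L, W); fc <- rep(0, W) } else fc <- src_c - c0
  r1 <- pmin(r0 + 1L, h); c1 <- pmin(c0 + 1L, w)
  a <- m[r0, c0, drop = FALSE]; b <- m[r0, c1, drop = FALSE]
  cc <- m[r1, c0, drop = FALSE]; dd <- m[r1, c1, drop = FALSE]
  FR <- matrix(fr, H, W); FC <- matrix(fc, H, W, byrow = TRUE)
  a * (1 - FR) * (1 - FC) + b * (1 - FR) * FC + cc * FR * (1 - FC) + dd * FR * FC
}

#' Build the CAM saliency map from weights and features
#'
#' Computes ReLU(sum_k a_c^k A^k) at feature resolution, then bilinearly
#' upsamples to `target_size`. The result is nonnegative everywhere.
#'
#' @param weights a [channel_weights()] result (or numeric vector of length K).
#' @param features a [feature_stack()] result (or h x w x K array).
#' @param target_size integer (H, W); defaults to the feature grid size.
#' @return A `CamMap`: list with `values` (H x W, >= 0), `class_index`,
#'   `layer_id`.
#' @export
cam <- function(weights, features, target_size = NULL) {
  wv <- if (inherits(weights, "CamWeights")) weights$weights else as.numeric(weights)
  maps <- if (inherits(features, "FeatureStack")) features$maps else features
  d <- dim(maps)
  if (length(wv) != d[3])
    stop("got ", length(wv), " weights for ", d[3], " feature channels", call. = FALSE)
  if (is.null(target_size)) target_size <- d[1:2]
  acc <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) acc <- acc + wv[k] * maps[, , k]
  acc <- pmax(acc, 0)
  vals <- bilinear_resize(acc, target_size[1], target_size[2])
  vals <- pmax(vals, 0)  # interpolation of nonnegative values stays >= 0; guard rounding
  structure(list(values = vals,
                 class_index = if (inherits(weights, "CamWeights")) weights$class_index else NA_integer_,
                 layer_id = if (inherits(features, "FeatureStack")) features$layer_id else NA_character_),
            class = "CamMap")
}

#' Grad-CAM saliency map for a segmentation model
#'
#' Full composition: reduce the class scores over `region`, differentiate
#' with respect to the activations at `layer_id`, average the gradients into
#' channel weights, and form the rectified weighted activation sum, upsampled
#' to input resolution. Deterministic for a fixed model and image.
#'
#' @inheritParams score_gradient
#' @return A `CamMap` at input resolution.
#' @export
gradcam_for_segmentation <- function(model, image, class_index = 2L,
                                     region = "all", layer_id = "dec2") {
  x <- .tile_pixels(image)
  H <- dim(x)[1]; W <- dim(x)[2]
  feats <- feature_stack(model, image, layer_id)
  grads <- score_gradient(model, image, class_index = class_index,
                          region = region, layer_id = layer_id)
  wts <- channel_weights(grads, n_pixels = feats$n_pixels,
                         class_index = class_index)
  cam(wts, feats, target_size = c(H, W))
}

#' Normalise a CAM to \[0, 1\] for visualisation
#'
#' Min-max scaling, used only for export/display; detection operates on the
#' raw map because regional maxima are invariant to monotone rescaling.
#'
#' @param cam_map a `CamMap`.
#' @return the `CamMap` with rescaled values.
#' @export
normalize_cam <- function(cam_map) {
  v <- cam_map$values
  rng <- range(v)
  cam_map$values <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else v * 0
  cam_map
}

#' @export
print.CamMap <- function(x, ...) {
  cat("<CamMap>", nrow(x$values), "x", ncol(x$values),
      "layer:", x$layer_id, " range: [", signif(min(x$values), 4), ",",
      signif(max(x$values), 4), "]\n")
  invisible(x)
}
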