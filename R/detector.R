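# Detection workflow: CAM -> grayscale dilation (disk) -> regional maxima
# (optionally intersected with the predicted semantic mask) -> connected
# components -> centroids -> K-means assignment of foreground pixels to
# instances. Dilation enlarges the activation basins so that secondary
# maxima near a dominant peak are absorbed rather than reported as extra
# nuclei.

#' Detection parameters
#'
#' @param dilation_radius radius (px) of the discrete-disk structuring
#'   element used for grayscale dilation of the CAM (default 7).
#' @param restrict_to_mask keep only maxima inside the predicted semantic
#'   mask (default TRUE); background maxima would otherwise surface as false
#'   detections.
#' @param kmeans_seed seed for the instance-assignment clustering.
#' @param kmeans_max_iter Lloyd iteration cap (default 100).
#' @param layer_id Grad-CAM feature layer (default `"dec2"`).
#' @return A `DetectParams` list.
#' @export
detect_params <- function(dilation_radius = 7L, restrict_to_mask = TRUE,
                          kmeans_seed = 1L, kmeans_max_iter = 100L,
                          layer_id = "dec2") {
  if (dilation_radius < 1L) stop("dilation_radius must be >= 1", call. = FALSE)
  structure(list(dilation_radius = as.integer(dilation_radius),
                 restrict_to_mask = isTRUE(restrict_to_mask),
                 kmeans_seed = as.integer(kmeans_seed),
                 kmeans_max_iter = as.integer(kmeans_max_iter),
                 layer_id = layer_id),
            class = "DetectParams")
}

#' Grayscale dilation with a disk structuring element
#'
#' Each output pixel is the maximum of the input over the discrete disk
#' \{(du, dv): du^2 + dv^2 <= radius^2\}; at the border the neighbourhood is
#' truncated to pixels inside the image.
#'
#' @param cam_map a `CamMap` or numeric matrix.
#' @param radius disk radius in pixels (>= 1).
#' @return same type as the input, dilated.
#' @export
dilate_grayscale <- function(cam_map, radius = 7L) {
  if (radius < 1L) stop("radius must be >= 1", call. = FALSE)
  m <- if (inherits(cam_map, "CamMap")) cam_map$values else cam_map
  out <- dilate_disk_cpp(m, as.integer(radius))
  if (inherits(cam_map, "CamMap")) { cam_map$values <- out; cam_map } else out
}

#' Regional maxima of a grayscale map
#'
#' Plateau-aware, 8-connected: a connected set of pixels of equal value is a
#' regional maximum iff every strictly-neighbouring pixel has a lower value.
#' A constant map is therefore one single regional maximum covering the
#' whole image (degenerate but well-defined).
#'
#' @param cam_map a `CamMap` or numeric matrix with finite values.
#' @return A [binary_mask()] marking the maxima.
#' @export
regional_maxima <- function(cam_map) {
  m <- if (inherits(cam_map, "CamMap")) cam_map$values else cam_map
  if (!all(is.finite(m))) stop("map values must be finite", call. = FALSE)
  binary_mask(regional_maxima_cpp(m), id = "regional_maxima")
}

#' Connected components and their centroids
#'
#' Labels the 8-connected components of a binary mask and returns the mean
#' (row, col) coordinate of each component's pixels, 0-based.
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param image_id id recorded on the resulting detection set.
#' @return A [detection_set()], one centroid per component (possibly empty).
#' @export
components_and_centroids <- function(mask, image_id = NULL) {
  m <- if (inherits(mask, "BinaryMask")) mask$mask else mask
  if (is.null(image_id))
    image_id <- if (inherits(mask, "BinaryMask")) mask$id else "tile"
  lab <- label_components_cpp(m)
  k <- max(lab)
  if (k == 0L) return(detection_set(image_id = image_id))
  idx <- which(lab > 0L, arr.ind = TRUE)
  l <- lab[lab > 0L]
  cent <- cbind(row = tapply(idx[, 1] - 1, l, mean),
                col = tapply(idx[, 2] - 1, l, mean))
  detection_set(cent[order(as.integer(rownames(cent))), , drop = FALSE], image_id)
}

# Lloyd K-means on (row, col) coordinates, centers initialised at the
# detected centroids. Ties go to the lowest cluster index; an emptied
# cluster is repaired by stealing the farthest point of the largest cluster.
.lloyd_assign <- function(pts, centers, max_iter = 100L) {
  k <- nrow(centers)
  n <- nrow(pts)
  assign_nearest <- function(cen) {
    d2 <- outer(pts[, 1], cen[, 1], "-")^2 + outer(pts[, 2], cen[, 2], "-")^2
    max.col(-d2, ties.method = "first")
  }
  lab <- assign_nearest(centers)
  for (it in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      if (!any(lab == j)) {
        big <- which.max(tabulate(lab, k))
        members <- which(lab == big)
        d2b <- (pts[members, 1] - centers[big, 1])^2 +
               (pts[members, 2] - centers[big, 2])^2
        lab[members[which.max(d2b)]] <- j
      }
    }
    centers <- cbind(tapply(pts[, 1], factor(lab, seq_len(k)), mean),
                     tapply(pts[, 2], factor(lab, seq_len(k)), mean))
    centers[is.na(centers)] <- 0  # guarded above; keeps arithmetic total
    new_lab <- assign_nearest(centers)
    if (identical(new_lab, lab)) break
    lab <- new_lab
  }
  # final guarantee: every cluster keeps at least one pixel (so the label
  # count always equals the detection count) as long as n >= k
  if (n >= k) for (j in seq_len(k)) {
    if (!any(lab == j)) {
      sizes <- tabulate(lab, k); sizes[sizes <= 1L] <- -1L
      big <- which.max(sizes)
      members <- which(lab == big)
      d2b <- (pts[members, 1] - centers[big, 1])^2 +
             (pts[members, 2] - centers[big, 2])^2
      lab[members[which.max(d2b)]] <- j
    }
  }
  list(labels = lab, centers = centers)
}

#' Assign foreground pixels to nucleus instances
#'
#' Partitions the `TRUE` pixels of the semantic mask into K clusters by
#' K-means on their (row, col) coordinates, with cluster centers initialised
#' at the detected centroids (K = number of detections). This splits mask
#' components that contain several detected nuclei along the spatial
#' proximity boundary. Deterministic given `params$kmeans_seed`.
#'
#' @param mask a [binary_mask()].
#' @param centroids a [detection_set()]; must be nonempty when the mask is.
#' @param params a [detect_params()].
#' @return An [instance_label_map()]; label i corresponds to centroid i.
#' @export
assign_instances <- function(mask, centroids, params = detect_params()) {
  m <- if (inherits(mask, "BinaryMask")) mask$mask else mask
  lab <- matrix(0L, nrow(m), ncol(m))
  fg <- which(m, arr.ind = TRUE)
  if (nrow(fg) == 0L)
    return(instance_label_map(lab, id = centroids$image_id))
  k <- n_detections(centroids)
  if (k == 0L)
    stop("nonempty mask but no centroids: detection failed upstream", call. = FALSE)
  # centroid-initialised Lloyd with fixed tie-breaking consumes no random
  # numbers, so the assignment is deterministic outright (kmeans_seed is part
  # of the interface for alternative initialisations)
  pts <- cbind(fg[, 1] - 1, fg[, 2] - 1)  # 0-based, matching centroid convention
  res <- .lloyd_assign(pts, centroids$centroids, params$kmeans_max_iter)
  used <- sort(unique(res$labels))
  relabel <- integer(k); relabel[used] <- seq_along(used)
  lab[fg] <- relabel[res$labels]
  instance_label_map(lab, id = centroids$image_id)
}

#' End-to-end nucleus detection on one tile
#'
#' Runs the full workflow: semantic mask prediction, Grad-CAM over the
#' nucleus class, grayscale dilation of the CAM, regional maxima (intersected
#' with the predicted mask when `restrict_to_mask`), connected components and
#' centroids, and K-means instance assignment. An empty predicted mask gives
#' an empty detection set and an all-zero label map.
#'
#' @param model a model satisfying the backend contract.
#' @param image an [image_tile()].
#' @param params a [detect_params()].
#' @return list with `detections` ([detection_set()]), `instances`
#'   ([instance_label_map()]), `cam` (`CamMap`, dilated), and `mask`
#'   (predicted [binary_mask()]).
#' @export
detect_nuclei <- function(model, image, params = detect_params()) {
  mask <- predict_mask(model, image)
  cam_map <- gradcam_for_segmentation(model, image, class_index = 2L,
                                      region = "all", layer_id = params$layer_id)
  dil <- dilate_grayscale(cam_map, params$dilation_radius)
  maxima <- regional_maxima(dil)$mask
  if (params$restrict_to_mask) maxima <- maxima & mask$mask
  dets <- components_and_centroids(binary_mask(maxima, id = image$id))
  instances <- if (n_detections(dets) == 0L)
    instance_label_map(matrix(0L, nrow(mask$mask), ncol(mask$mask)), id = image$id)
  else
    assign_instances(mask, dets, params)
  list(detections = dets, instances = instances, cam = dil, mask = mask)
}
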