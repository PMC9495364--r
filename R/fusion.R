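# Detector fusion: merge the CAM-based detections with a second detector's
# centroids under a proximity rule. Nuclei found by only one detector are
# kept; where both fire within `proximity` pixels, the secondary detector's
# point wins. The secondary detector is typically an instance-segmentation
# model whose outputs are ingested from files; the motivation is recall —
# the union recovers nuclei either detector misses.

#' Fusion parameters
#'
#' @param proximity distance (px) under which a primary detection is
#'   considered a duplicate of a secondary one and dropped. Default 6 px
#'   (about one nuclear radius, the same scale as the matching rescue
#'   threshold); no canonical value exists, so tune per dataset.
#' @param secondary_priority keep the secondary point when both detectors
#'   fire nearby (default TRUE). With FALSE the roles are swapped.
#' @return A `FusionParams` list.
#' @export
fusion_params <- function(proximity = 6, secondary_priority = TRUE) {
  if (proximity < 0) stop("proximity must be >= 0", call. = FALSE)
  structure(list(proximity = as.numeric(proximity),
                 secondary_priority = isTRUE(secondary_priority)),
            class = "FusionParams")
}

#' Combine two detection sets
#'
#' Every secondary detection is retained; a primary detection is retained
#' iff no secondary detection lies within `params$proximity` of it (boundary
#' inclusive: a primary at exactly `proximity` from a secondary is dropped).
#' Output order: secondary detections first, then surviving primary ones.
#' Secondary detections are never deduplicated among themselves.
#'
#' @param primary,secondary [detection_set()]s for the same image.
#' @param params a [fusion_params()].
#' @return A [detection_set()].
#' @export
combine_detections <- function(primary, secondary, params = fusion_params()) {
  if (!identical(primary$image_id, secondary$image_id))
    stop("detection sets refer to different images: '", primary$image_id,
         "' vs '", secondary$image_id, "'", call. = FALSE)
  if (!params$secondary_priority) { tmp <- primary; primary <- secondary; secondary <- tmp }
  np <- n_detections(primary); ns <- n_detections(secondary)
  if (np == 0L) return(secondary)
  keep <- if (ns == 0L) rep(TRUE, np) else {
    D <- .dist_mat(primary$centroids, secondary$centroids)
    apply(D, 1, min) > params$proximity
  }
  detection_set(rbind(secondary$centroids, primary$centroids[keep, , drop = FALSE]),
                image_id = secondary$image_id)
}

#' Read secondary detections from a JSON centroid list
#'
#' Accepts a minimal list `[{"image_id": ..., "row": ..., "col": ...}, ...]`.
#'
#' @param path JSON file.
#' @return named list of [detection_set()]s, one per image_id present.
#' @export
read_detections_json <- function(path) {
  df <- jsonlite::fromJSON(path)
  if (length(df) == 0L || is.null(nrow(df)) || nrow(df) == 0L)
    return(list())
  if (!all(c("image_id", "row", "col") %in% names(df)))
    stop("detection JSON needs fields image_id, row, col", call. = FALSE)
  lapply(split(df, df$image_id), function(g)
    detection_set(cbind(row = g$row, col = g$col), image_id = g$image_id[1]))
}

#' Reduce COCO-style instance annotations to centroids
#'
#' Converts a COCO instance JSON (`images`, `annotations` with `bbox`
#' `[x, y, w, h]` and optionally `segmentation` polygons) into detection
#' sets: the polygon vertex centroid when a polygon is present, otherwise
#' the bounding-box center. COCO x/y are column/row.
#'
#' @param path COCO JSON file.
#' @return named list of [detection_set()]s keyed by image file name.
#' @export
read_detections_coco <- function(path) {
  cc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(cc$images) || is.null(cc$annotations))
    stop("not a COCO instance file: needs images and annotations", call. = FALSE)
  img_name <- vapply(cc$images, function(im) as.character(im$file_name), character(1))
  names(img_name) <- vapply(cc$images, function(im) as.character(im$id), character(1))
  rows <- lapply(cc$annotations, function(an) {
    seg <- an$segmentation
    if (is.list(seg) && length(seg)) seg <- seg[[1]]   # first polygon
    v <- suppressWarnings(as.numeric(unlist(seg)))
    if (length(v) >= 6L && !anyNA(v)) {
      xs <- v[seq(1, length(v), 2)]; ys <- v[seq(2, length(v), 2)]
      c(row = mean(ys), col = mean(xs), id = an$image_id)
    } else {
      bb <- unlist(an$bbox)
      c(row = bb[2] + bb[4] / 2, col = bb[1] + bb[3] / 2, id = an$image_id)
    }
  })
  m <- do.call(rbind, rows)
  if (is.null(m)) return(list())
  coords <- matrix(as.numeric(m[, 1:2]), ncol = 2,
                   dimnames = list(NULL, c("row", "col")))
  out <- lapply(split(seq_len(nrow(m)), as.character(m[, 3])), function(ix)
    detection_set(coords[ix, , drop = FALSE],
                  image_id = img_name[[as.character(m[ix[1], 3])]]))
  names(out) <- vapply(out, `[[`, "", "image_id")
  out
}
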