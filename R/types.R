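#' Construct an image tile
#'
#' The unit of processing: an RGB intensity grid with values in \[0, 1\].
#' Histology tiles read from disk (PNG/TIFF/JPEG) are converted to this form
#' by [read_image()].
#'
#' @param pixels numeric array of dimension H x W x 3, values in \[0, 1\].
#' @param id character tile identifier.
#' @return An object of class `ImageTile` with fields `pixels` and `id`.
#' @export
image_tile <- function(pixels, id = "tile") {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array", call. = FALSE)
  d <- dim(pixels)
  if (d[1] < 16L || d[2] < 16L)
    stop("tiles must be at least 16 x 16 pixels", call. = FALSE)
  if (anyNA(pixels) || !all(is.finite(pixels)))
    stop("pixel values must be finite", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("pixel values must lie in [0, 1]", call. = FALSE)
  structure(list(pixels = pixels, id = as.character(id)), class = "ImageTile")
}

#' Construct a binary mask
#'
#' @param mask logical H x W matrix (`TRUE` = nucleus/foreground).
#' @param id character identifier, usually the tile id.
#' @return An object of class `BinaryMask`.
#' @export
binary_mask <- function(mask, id = "mask") {
  if (is.numeric(mask)) { storage.mode(mask) <- "logical" }
  if (!is.matrix(mask) || !is.logical(mask))
    stop("`mask` must be a logical matrix", call. = FALSE)
  if (anyNA(mask)) stop("mask must not contain NA", call. = FALSE)
  structure(list(mask = mask, id = as.character(id)), class = "BinaryMask")
}

#' Construct an instance label map
#'
#' Integer grid assigning each foreground pixel to one nucleus instance:
#' 0 = background, 1..K = instances. Labels must be contiguous.
#'
#' @param labels integer H x W matrix.
#' @param id character identifier.
#' @return An object of class `InstanceLabelMap`.
#' @export
instance_label_map <- function(labels, id = "labels") {
  if (!is.matrix(labels)) stop("`labels` must be a matrix", call. = FALSE)
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L))
    stop("labels must be non-negative integers", call. = FALSE)
  k <- max(labels)
  if (k > 0L && !setequal(unique(labels[labels > 0L]), seq_len(k)))
    stop("nonzero labels must be contiguous 1..K", call. = FALSE)
  structure(list(labels = labels, id = as.character(id)), class = "InstanceLabelMap")
}

#' Construct a detection set
#'
#' A list of nucleus centroids in 0-based (row, col) pixel coordinates.
#'
#' @param centroids numeric matrix with columns `row`, `col` (may have 0 rows),
#'   or a data.frame with those columns.
#' @param image_id character tile identifier.
#' @return An object of class `DetectionSet`.
#' @export
detection_set <- function(centroids = matrix(numeric(), 0, 2), image_id = "tile") {
  if (is.data.frame(centroids))
    centroids <- as.matrix(centroids[, c("row", "col"), drop = FALSE])
  if (!is.matrix(centroids) || ncol(centroids) != 2L)
    stop("`centroids` must be a 2-column (row, col) matrix", call. = FALSE)
  storage.mode(centroids) <- "double"
  if (nrow(centroids) && (anyNA(centroids) || !all(is.finite(centroids))))
    stop("centroid coordinates must be finite", call. = FALSE)
  colnames(centroids) <- c("row", "col")
  structure(list(centroids = centroids, image_id = as.character(image_id)),
            class = "DetectionSet")
}

#' @export
print.DetectionSet <- function(x, ...) {
  cat("<DetectionSet> image_id:", x$image_id, "-", nrow(x$centroids), "centroids\n")
  invisible(x)
}

#' @export
print.ImageTile <- function(x, ...) {
  d <- dim(x$pixels)
  cat("<ImageTile>", x$id, sprintf("(%d x %d RGB)\n", d[1], d[2]))
  invisible(x)
}

#' Number of centroids in a detection set
#' @param dets a [detection_set()].
#' @return integer count.
#' @export
n_detections <- function(dets) nrow(dets$centroids)

#' Region of interest over a score map
#'
#' The pixel index set P over which per-pixel class scores are reduced to the
#' scalar class score that Grad-CAM differentiates. `"all"` selects every
#' pixel; a logical matrix selects its `TRUE` pixels (which may be none, an
#' explicitly empty region).
#'
#' @param x `"all"` or a logical H x W matrix.
#' @return An object of class `RegionOfInterest`.
#' @export
region_of_interest <- function(x = "all") {
  if (identical(x, "all"))
    return(structure(list(all = TRUE, mask = NULL), class = "RegionOfInterest"))
  if (is.numeric(x)) storage.mode(x) <- "logical"
  if (!is.matrix(x) || !is.logical(x))
    stop('region must be "all" or a logical matrix', call. = FALSE)
  structure(list(all = FALSE, mask = x), class = "RegionOfInterest")
}

region_mask <- function(region, H, W) {
  if (!inherits(region, "RegionOfInterest")) region <- region_of_interest(region)
  if (region$all) return(matrix(TRUE, H, W))
  m <- region$mask
  if (nrow(m) != H || ncol(m) != W)
    stop("region dimensions do not match the score map", call. = FALSE)
  m
}
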