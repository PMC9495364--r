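# Readers/writers for the annotation and image dialects the pipeline
# touches. Coordinate convention is uniform: 0-based (row, col), origin
# top-left. The contour XML dialect stores vertices as X/Y attributes
# (X = column, Y = row); that reader/writer pair is the only place the axes
# swap. Centroid annotations shipped as MATLAB .mat files are not parsed
# natively — convert them once to the centroid CSV dialect (e.g.
# `scipy.io.loadmat` + a two-line CSV dump) and feed the CSV.

#' Contour annotation
#'
#' Nuclear boundary polygons for one image, each with >= 3 vertices in
#' 0-based (row, col) pixel coordinates.
#'
#' @param regions list of numeric matrices with columns row, col.
#' @param image_id character identifier.
#' @return A `ContourAnnotation` list.
#' @export
contour_annotation <- function(regions = list(), image_id = "tile") {
  regions <- lapply(regions, function(v) {
    v <- as.matrix(v)
    if (ncol(v) != 2L || nrow(v) < 3L)
      stop("each region needs >= 3 (row, col) vertices", call. = FALSE)
    if (anyNA(v) || !all(is.finite(v)))
      stop("vertex coordinates must be finite", call. = FALSE)
    colnames(v) <- c("row", "col")
    v
  })
  structure(list(regions = regions, image_id = as.character(image_id)),
            class = "ContourAnnotation")
}

#' Read a vertex-list contour XML file
#'
#' Parses the `Annotation > Regions > Region > Vertices > Vertex` dialect
#' with X/Y vertex attributes; X maps to column and Y to row, both kept
#' 0-based floating point. An empty `Regions` element yields an empty
#' annotation.
#'
#' @param path XML file.
#' @param image_id id to record; defaults to the file name without extension.
#' @return A [contour_annotation()].
#' @export
read_contour_xml <- function(path, image_id = NULL) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("malformed XML in '", path, "': ", conditionMessage(e), call. = FALSE))
  if (is.null(image_id)) {
    id_attr <- xml2::xml_attr(doc, "ImageId")
    image_id <- if (!is.na(id_attr)) id_attr else
      sub("\\.[^.]*$", "", basename(path))
  }
  region_nodes <- xml2::xml_find_all(doc, ".//Region")
  regions <- lapply(region_nodes, function(rn) {
    vx <- xml2::xml_find_all(rn, ".//Vertex")
    if (length(vx) < 3L)
      stop("Region with fewer than 3 vertices at ", xml2::xml_path(rn), call. = FALSE)
    x <- as.numeric(xml2::xml_attr(vx, "X"))
    y <- as.numeric(xml2::xml_attr(vx, "Y"))
    if (anyNA(x) || anyNA(y))
      stop("non-numeric Vertex X/Y at ", xml2::xml_path(rn), call. = FALSE)
    cbind(row = y, col = x)
  })
  contour_annotation(regions, image_id = image_id)
}

#' Write a contour annotation as vertex-list XML
#'
#' Emits the same dialect [read_contour_xml()] accepts (row -> Y, col -> X).
#'
#' @param ann a [contour_annotation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contour_xml <- function(ann, path) {
  doc <- xml2::xml_new_root("Annotation", ImageId = ann$image_id)
  regs <- xml2::xml_add_child(doc, "Regions")
  for (i in seq_along(ann$regions)) {
    reg <- xml2::xml_add_child(regs, "Region", Id = as.character(i))
    verts <- xml2::xml_add_child(reg, "Vertices")
    v <- ann$regions[[i]]
    for (j in seq_len(nrow(v)))
      xml2::xml_add_child(verts, "Vertex",
                          X = format(v[j, "col"], digits = 17),
                          Y = format(v[j, "row"], digits = 17))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Rasterise contour polygons into an instance label map
#'
#' Even-odd (crossing-number) polygon fill over pixel centers; later regions
#' overwrite earlier ones where they overlap, and labels follow file order.
#' Vertices outside the canvas are allowed — the filled area is clipped to
#' the canvas with a warning.
#'
#' @param ann a [contour_annotation()].
#' @param shape integer (H, W).
#' @return An [instance_label_map()].
#' @export
contours_to_instances <- function(ann, shape) {
  H <- shape[1]; W <- shape[2]
  if (H < 1L || W < 1L) stop("shape must be positive", call. = FALSE)
  lab <- matrix(0L, H, W)
  clipped <- FALSE
  for (i in seq_along(ann$regions)) {
    v <- ann$regions[[i]]
    if (any(v[, "row"] < -0.5 | v[, "row"] > H - 0.5 |
            v[, "col"] < -0.5 | v[, "col"] > W - 0.5)) clipped <- TRUE
    r0 <- max(0L, floor(min(v[, "row"]))); r1 <- min(H - 1L, ceiling(max(v[, "row"])))
    c0 <- max(0L, floor(min(v[, "col"]))); c1 <- min(W - 1L, ceiling(max(v[, "col"])))
    if (r1 < r0 || c1 < c0) next
    rows <- r0:r1; cols <- c0:c1
    py <- v[, "row"]; px <- v[, "col"]
    n <- length(py)
    inside <- matrix(FALSE, length(rows), length(cols))
    gy <- matrix(rows, length(rows), length(cols))
    gx <- matrix(cols, length(rows), length(cols), byrow = TRUE)
    for (e in seq_len(n)) {
      e2 <- if (e == n) 1L else e + 1L
      y1 <- py[e]; y2 <- py[e2]; x1 <- px[e]; x2 <- px[e2]
      if (y1 == y2) next
      crosses <- ((y1 > gy) != (y2 > gy)) &
        (gx < x1 + (gy - y1) * (x2 - x1) / (y2 - y1))
      inside <- xor(inside, crosses)
    }
    lab[cbind(gy[inside] + 1L, gx[inside] + 1L)] <- i
  }
  if (clipped)
    warning("contour vertices outside the canvas were clipped", call. = FALSE)
  # overwriting can wipe out a region entirely; keep labels contiguous
  present <- sort(unique(lab[lab > 0L]))
  if (length(present) && !identical(present, seq_along(present))) {
    relabel <- integer(max(present)); relabel[present] <- seq_along(present)
    lab[lab > 0L] <- relabel[lab[lab > 0L]]
  }
  instance_label_map(lab, id = ann$image_id)
}

#' Read / write centroid CSV
#'
#' Dialect: header `image_id,row,col`, floating 0-based coordinates. The
#' reader rejects files without the expected columns.
#'
#' @param path CSV file.
#' @param image_id optional filter: return only this image's centroids (a
#'   single [detection_set()]); otherwise a named list, one set per image.
#' @return see `image_id`.
#' @export
read_centroids_csv <- function(path, image_id = NULL) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "row", "col")
  if (!all(need %in% names(df)))
    stop("centroid CSV must have columns ", paste(need, collapse = ", "),
         "; got: ", paste(names(df), collapse = ", "), call. = FALSE)
  if (!is.null(image_id)) {
    g <- df[df$image_id == image_id, , drop = FALSE]
    return(detection_set(cbind(row = g$row, col = g$col), image_id = image_id))
  }
  out <- lapply(split(df, df$image_id), function(g)
    detection_set(cbind(row = g$row, col = g$col), image_id = g$image_id[1]))
  out[unique(df$image_id)]
}

#' @rdname read_centroids_csv
#' @param dets a [detection_set()] or list of them.
#' @export
write_centroids_csv <- function(dets, path) {
  if (inherits(dets, "DetectionSet")) dets <- list(dets)
  rows <- lapply(dets, function(d)
    data.frame(image_id = rep(d$image_id, nrow(d$centroids)),
               row = d$centroids[, "row"], col = d$centroids[, "col"]))
  df <- do.call(rbind, c(rows, list(
    data.frame(image_id = character(), row = numeric(), col = numeric()))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write image tiles
#'
#' RGB tiles: PNG/JPEG via their native readers, TIFF via the tiff package;
#' grayscale files are replicated to three channels. Writing uses 8-bit PNG.
#'
#' @param path image file (.png, .tif/.tiff — lossless only for writing).
#' @param id tile id; defaults to the file name without extension.
#' @return An [image_tile()].
#' @export
read_image <- function(path, id = NULL) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = stop("JPEG input requires re-encoding to PNG/TIFF first",
                        call. = FALSE),
    stop("unsupported image format '.", ext, "'", call. = FALSE))
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), dim = c(dim(px), 3))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  image_tile(px, id = if (is.null(id)) sub("\\.[^.]*$", "", basename(path)) else id)
}

#' @rdname read_image
#' @param tile an [image_tile()].
#' @export
write_image <- function(tile, path) {
  png::writePNG(tile$pixels, path)
  invisible(path)
}

#' Read / write binary masks as 8-bit PNG (0/255)
#'
#' @param path PNG file.
#' @param id mask id.
#' @return A [binary_mask()].
#' @export
read_mask_png <- function(path, id = NULL) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  binary_mask(px > 0.5,
              id = if (is.null(id)) sub("\\.[^.]*$", "", basename(path)) else id)
}

#' @rdname read_mask_png
#' @param mask a [binary_mask()].
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask$mask * 1, path)
  invisible(path)
}

#' Read / write instance label maps as 16-bit single-channel TIFF
#'
#' Labels up to 65535 survive losslessly. (The PNG writer available to this
#' package is 8-bit only, so label images use 16-bit TIFF instead.)
#'
#' @param path TIFF file.
#' @param id map id.
#' @return An [instance_label_map()].
#' @export
read_label_image <- function(path, id = NULL) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  lab <- matrix(as.integer(round(px * 65535)), nrow(px), ncol(px))
  instance_label_map(lab,
                     id = if (is.null(id)) sub("\\.[^.]*$", "", basename(path)) else id)
}

#' @rdname read_label_image
#' @param labels an [instance_label_map()].
#' @export
write_label_image <- function(labels, path) {
  if (max(labels$labels) > 65535L)
    stop("label values exceed 16-bit range", call. = FALSE)
  tiff::writeTIFF(labels$labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Export a CAM as 32-bit float TIFF or 8-bit PNG heatmap
#'
#' Both formats store the min-max-normalised map (the TIFF writer's float
#' range is \[0, 1\]); this monotone rescaling leaves the regional-maxima
#' structure the detector uses untouched. The TIFF keeps 32-bit float
#' precision, the PNG is an 8-bit visualisation.
#'
#' @param cam_map a `CamMap`.
#' @param path output file; `.tif` writes float TIFF, `.png` a grayscale
#'   heatmap.
#' @return `path`, invisibly.
#' @export
write_cam <- function(cam_map, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(normalize_cam(cam_map)$values, path, bits.per.sample = 32L)
  } else if (ext == "png") {
    png::writePNG(normalize_cam(cam_map)$values, path)
  } else stop("unsupported CAM format '.", ext, "'", call. = FALSE)
  invisible(path)
}

#' @rdname write_cam
#' @export
read_cam_tiff <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  v <- tiff::readTIFF(path)
  if (length(dim(v)) == 3L) v <- v[, , 1]
  structure(list(values = v, class_index = NA_integer_, layer_id = NA_character_),
            class = "CamMap")
}
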