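# Synthetic H&E-like tile generator. Renders dark purple elliptical nuclei
# on a pink background with per-pixel Gaussian noise, and returns exact
# ground truth (instance map, semantic mask, centroids, contours) so every
# pipeline stage is testable without real slides. The colour model is a
# two-tone caricature of hematoxylin/eosin sufficient for a 2-class CNN; it
# makes no attempt at stain physics or texture realism.

NUCLEUS_RGB <- c(0.35, 0.20, 0.55)
BACKGROUND_RGB <- c(0.93, 0.75, 0.85)

#' Synthetic tile parameters
#'
#' @param height,width tile size in pixels.
#' @param n_nuclei number of nuclei to place (>= 0).
#' @param radius_range (min, max) of the ellipse semi-axes, pixels.
#' @param min_spacing minimum center-to-center distance for non-overlapping
#'   placements; may be < 2 * max radius to force contact.
#' @param overlap_fraction fraction in \[0, 1\] of nuclei deliberately placed
#'   to overlap a neighbour (what makes instance separation non-trivial).
#' @param noise_sd per-pixel Gaussian noise standard deviation.
#' @param seed integer RNG seed; the tile is fully determined by it.
#' @return A `SynthParams` list.
#' @export
synth_params <- function(height = 128L, width = 128L, n_nuclei = 15L,
                         radius_range = c(4, 7), min_spacing = 18,
                         overlap_fraction = 0, noise_sd = 0.03, seed = 1L) {
  if (height < 16L || width < 16L) stop("tiles must be at least 16 x 16", call. = FALSE)
  if (n_nuclei < 0L) stop("n_nuclei must be >= 0", call. = FALSE)
  if (length(radius_range) != 2L || any(radius_range <= 0) ||
      radius_range[1] > radius_range[2])
    stop("radius_range must be positive (min, max)", call. = FALSE)
  if (overlap_fraction < 0 || overlap_fraction > 1)
    stop("overlap_fraction must be in [0, 1]", call. = FALSE)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_nuclei = as.integer(n_nuclei),
                 radius_range = as.numeric(radius_range),
                 min_spacing = as.numeric(min_spacing),
                 overlap_fraction = as.numeric(overlap_fraction),
                 noise_sd = as.numeric(noise_sd), seed = as.integer(seed)),
            class = "SynthParams")
}

.ellipse_mask_idx <- function(H, W, cy, cx, a, b, theta) {
  # pixel centers inside the rotated ellipse, as an index matrix
  r0 <- max(0L, floor(cy - max(a, b))); r1 <- min(H - 1L, ceiling(cy + max(a, b)))
  c0 <- max(0L, floor(cx - max(a, b))); c1 <- min(W - 1L, ceiling(cx + max(a, b)))
  if (r1 < r0 || c1 < c0) return(cbind(integer(), integer()))
  rr <- r0:r1; cc <- c0:c1
  dy <- matrix(rr - cy, length(rr), length(cc))
  dx <- matrix(cc - cx, length(rr), length(cc), byrow = TRUE)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- which(u^2 + v^2 <= 1, arr.ind = TRUE)
  cbind(rr[inside[, 1]] + 1L, cc[inside[, 2]] + 1L)  # 1-based matrix indices
}

#' Generate one synthetic H&E-like tile
#'
#' Places `n_nuclei` random ellipses (axes within `radius_range`, uniform
#' orientation): a fraction `overlap_fraction` of them is deliberately
#' anchored to overlap an earlier nucleus, the rest keep `min_spacing`
#' between centers. Later nuclei occlude earlier ones in the instance map
#' (one label per pixel, as in real semantic masks of touching nuclei).
#' Colours are jittered per nucleus and per-pixel Gaussian noise of sd
#' `noise_sd` is added, clipped to \[0, 1\]. Deterministic given
#' `params$seed`.
#'
#' @param params a [synth_params()].
#' @param id tile identifier.
#' @return A `SynthTile`: list with `image` ([image_tile()]), `instances`
#'   ([instance_label_map()]), `mask` ([binary_mask()]), `centroids`
#'   ([detection_set()] of instance centroids), `contours` (per-instance
#'   vertex matrices, columns row/col).
#' @export
generate_tile <- function(params = synth_params(), id = "synth") {
  set.seed(params$seed)
  H <- params$height; W <- params$width
  n <- params$n_nuclei
  rr <- params$radius_range
  lab <- matrix(0L, H, W)
  n_overlap <- round(params$overlap_fraction * n)
  centers <- matrix(numeric(), 0, 2)
  shapes <- list()
  margin <- rr[2] + 1
  for (k in seq_len(n)) {
    a <- stats::runif(1, rr[1], rr[2]); b <- stats::runif(1, rr[1], rr[2])
    theta <- stats::runif(1, 0, pi)
    placed <- FALSE
    for (try in seq_len(200L)) {
      if (k > n - n_overlap && nrow(centers) > 0) {
        # anchor to a random earlier nucleus at a distance that guarantees
        # overlap but leaves most of both nuclei visible
        anchor <- centers[sample.int(nrow(centers), 1L), ]
        dist <- stats::runif(1, 0.6, 0.9) * (max(a, b) + rr[2])
        ang <- stats::runif(1, 0, 2 * pi)
        cy <- anchor[1] + dist * sin(ang); cx <- anchor[2] + dist * cos(ang)
        if (cy < margin || cy > H - 1 - margin || cx < margin || cx > W - 1 - margin)
          next
      } else {
        cy <- stats::runif(1, margin, H - 1 - margin)
        cx <- stats::runif(1, margin, W - 1 - margin)
        if (nrow(centers) > 0) {
          d <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
          if (min(d) < params$min_spacing) next
        }
      }
      placed <- TRUE
      break
    }
    if (!placed)
      stop("could not place nucleus ", k, " of ", n,
           " after 200 attempts (achieved ", k - 1L, "); loosen spacing",
           call. = FALSE)
    idx <- .ellipse_mask_idx(H, W, cy, cx, a, b, theta)
    lab[idx] <- k
    centers <- rbind(centers, c(cy, cx))
    shapes[[k]] <- list(cy = cy, cx = cx, a = a, b = b, theta = theta)
  }
  # occlusion can leave an earlier label with no pixels; relabel contiguously
  present <- sort(unique(lab[lab > 0L]))
  relabel <- integer(max(1L, n)); relabel[present] <- seq_along(present)
  if (n > 0L) lab[lab > 0L] <- relabel[lab[lab > 0L]]
  shapes <- shapes[present]
  k_final <- length(present)

  img <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- BACKGROUND_RGB[ch] + stats::rnorm(1, 0, 0.02)
  for (k in seq_len(k_final)) {
    jit <- stats::rnorm(3, 0, 0.03)
    pix <- which(lab == k)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[pix] <- NUCLEUS_RGB[ch] + jit[ch]
      img[, , ch] <- plane
    }
  }
  img <- img + array(stats::rnorm(length(img), 0, params$noise_sd), dim = dim(img))
  img <- pmin(pmax(img, 0), 1)

  if (k_final > 0L) {
    idxs <- which(lab > 0L, arr.ind = TRUE)
    l <- lab[lab > 0L]
    cent <- cbind(row = tapply(idxs[, 1] - 1, l, mean),
                  col = tapply(idxs[, 2] - 1, l, mean))
    cent <- cent[order(as.integer(rownames(cent))), , drop = FALSE]
  } else cent <- matrix(numeric(), 0, 2)
  contours <- lapply(shapes, function(s) {
    t_ <- seq(0, 2 * pi, length.out = 33L)[-33L]
    ex <- s$a * cos(t_); ey <- s$b * sin(t_)
    cbind(row = s$cy + ex * sin(s$theta) + ey * cos(s$theta),
          col = s$cx + ex * cos(s$theta) - ey * sin(s$theta))
  })
  list(image = image_tile(img, id = id),
       instances = instance_label_map(lab, id = id),
       mask = binary_mask(lab > 0L, id = id),
       centroids = detection_set(cent, image_id = id),
       contours = contours)
}

#' Generate and write a synthetic dataset
#'
#' Writes, per tile: RGB image (PNG), semantic mask (PNG), instance label
#' image (16-bit TIFF), centroid CSV, and contour XML, plus a JSON manifest
#' listing every file and the nucleus counts. Tile i uses seed
#' `params$seed + i - 1`, so the dataset is reproducible file-by-file.
#'
#' @param n_tiles number of tiles (>= 1).
#' @param params a [synth_params()]; per-tile seeds are derived from
#'   `params$seed`.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly (also written to `manifest.json`).
#' @export
generate_dataset <- function(n_tiles, params = synth_params(), out_dir) {
  if (n_tiles < 1L) stop("n_tiles must be >= 1", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create '", out_dir, "'", call. = FALSE)
  tiles <- list()
  for (i in seq_len(n_tiles)) {
    p <- params; p$seed <- params$seed + i - 1L
    id <- sprintf("tile_%03d", i)
    st <- generate_tile(p, id = id)
    files <- list(image = paste0(id, ".png"),
                  mask = paste0(id, "_mask.png"),
                  labels = paste0(id, "_labels.tif"),
                  centroids = paste0(id, "_centroids.csv"),
                  contours = paste0(id, "_contours.xml"))
    write_image(st$image, file.path(out_dir, files$image))
    write_mask_png(st$mask, file.path(out_dir, files$mask))
    write_label_image(st$instances, file.path(out_dir, files$labels))
    write_centroids_csv(st$centroids, file.path(out_dir, files$centroids))
    write_contour_xml(contour_annotation(st$contours, image_id = id),
                      file.path(out_dir, files$contours))
    tiles[[i]] <- list(id = id, seed = p$seed,
                       n_nuclei = n_detections(st$centroids), files = files)
  }
  manifest <- list(n_tiles = n_tiles,
                   params = unclass(params),
                   total_nuclei = sum(vapply(tiles, `[[`, integer(1), "n_nuclei")),
                   tiles = tiles)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
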