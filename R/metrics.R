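# Detection and segmentation scoring. Pixelwise precision/recall/Dice come
# from a per-pixel confusion; detection metrics come from centroid matching:
# a detection within xi (the mean nuclear radius of the image) of a ground
# truth counts as a TP, duplicates and strays are FPs, missed truths FNs,
# and a final rescue step converts leftover FP/FN pairs closer than epsilon
# (default 6 px, about one nuclear radius) into TPs.

#' Confusion counts
#' @param tp,fp,fn nonnegative integers.
#' @return A `ConfusionCounts` list.
#' @export
confusion_counts <- function(tp = 0L, fp = 0L, fn = 0L) {
  if (tp < 0 || fp < 0 || fn < 0) stop("counts must be >= 0", call. = FALSE)
  structure(list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn)),
            class = "ConfusionCounts")
}

#' Matching parameters
#'
#' @param xi primary distance threshold in pixels (> 0); conventionally the
#'   mean nuclear radius of the image, see [mean_nuclear_radius()].
#' @param epsilon rescue threshold in pixels (>= 0, default 6): leftover
#'   FP/FN pairs strictly closer than `epsilon` become TPs.
#' @return A `MatchParams` list.
#' @export
match_params <- function(xi, epsilon = 6) {
  if (xi <= 0) stop("xi must be > 0", call. = FALSE)
  if (epsilon < 0) stop("epsilon must be >= 0", call. = FALSE)
  structure(list(xi = as.numeric(xi), epsilon = as.numeric(epsilon)),
            class = "MatchParams")
}

#' Pixelwise confusion between predicted and true masks
#'
#' @param pred,truth [binary_mask()]s (or logical matrices) of equal shape.
#' @return A [confusion_counts()] over all pixels.
#' @export
pixel_confusion <- function(pred, truth) {
  p <- if (inherits(pred, "BinaryMask")) pred$mask else pred
  t <- if (inherits(truth, "BinaryMask")) truth$mask else truth
  if (!identical(dim(p), dim(t)))
    stop("mask shapes differ: ", paste(dim(p), collapse = "x"), " vs ",
         paste(dim(t), collapse = "x"), call. = FALSE)
  confusion_counts(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t))
}

#' Precision, recall and Dice from confusion counts
#'
#' Precision = TP/(TP+FP), Recall = TP/(TP+FN),
#' Dice = 2 TP/(2 TP + FP + FN). Any metric whose denominator is zero is 0
#' by convention (applied uniformly; in particular all three are 0 when
#' tp = fp = fn = 0).
#'
#' @param counts a [confusion_counts()].
#' @return named numeric vector `c(precision, recall, dice)`.
#' @export
precision_recall_dice <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  safe <- function(num, den) if (den > 0) num / den else 0
  c(precision = safe(tp, tp + fp),
    recall = safe(tp, tp + fn),
    dice = safe(2 * tp, 2 * tp + fp + fn))
}

#' Nucleus count errors
#'
#' Absolute and signed relative count error: ea = |d - g| / g,
#' es = (d - g) / g, for d detected and g > 0 ground-truth nuclei.
#'
#' @param d number of detected nuclei.
#' @param g number of ground-truth nuclei (> 0).
#' @return A `CountError` list with fields `ea`, `es`, `d`, `g`.
#' @export
count_errors <- function(d, g) {
  if (g <= 0) stop("g must be > 0", call. = FALSE)
  structure(list(ea = abs(d - g) / g, es = (d - g) / g,
                 d = as.integer(d), g = as.integer(g)),
            class = "CountError")
}

#' Mean nuclear radius of an image's ground truth
#'
#' Mean over instances of the equivalent-circle radius sqrt(area / pi);
#' the customary per-image value of the matching threshold xi.
#'
#' @param truth an [instance_label_map()], or a list of polygon vertex
#'   matrices (columns row, col) whose enclosed areas are used instead.
#' @return mean radius in pixels.
#' @export
mean_nuclear_radius <- function(truth) {
  if (inherits(truth, "InstanceLabelMap")) {
    lab <- truth$labels
    if (max(lab) == 0L) stop("no instances in label map", call. = FALSE)
    areas <- tabulate(lab[lab > 0L], max(lab))
  } else if (is.list(truth)) {
    if (length(truth) == 0L) stop("no instances", call. = FALSE)
    areas <- vapply(truth, function(v) {
      # shoelace formula on the polygon vertices
      r <- v[, 1]; c <- v[, 2]
      n <- length(r)
      abs(sum(c * r[c(2:n, 1)] - c[c(2:n, 1)] * r)) / 2
    }, numeric(1))
  } else stop("truth must be an InstanceLabelMap or a list of polygons", call. = FALSE)
  mean(sqrt(areas / pi))
}

.dist_mat <- function(a, b) {
  # Euclidean distances between two (row, col) coordinate matrices
  sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
}

# Greedy matcher used by both the primary (<= xi, inclusive) and the rescue
# (< epsilon, strict) phases: repeatedly pair the globally closest
# (detection, truth) pair that satisfies `ok`, removing both.
.greedy_pairs <- function(D, ok) {
  pairs <- NULL
  if (length(D) == 0L) return(pairs)
  free_d <- rep(TRUE, nrow(D)); free_t <- rep(TRUE, ncol(D))
  repeat {
    M <- D
    M[!free_d, ] <- Inf; M[, !free_t] <- Inf
    M[!ok(D)] <- Inf
    if (!any(is.finite(M))) break
    ij <- arrayInd(which.min(M), dim(M))
    pairs <- rbind(pairs, c(ij[1], ij[2], D[ij[1], ij[2]]))
    free_d[ij[1]] <- FALSE; free_t[ij[2]] <- FALSE
  }
  pairs
}

#' Match detections against ground-truth centroids
#'
#' Builds the Euclidean distance matrix between detected and true centroids
#' and greedily pairs the globally closest (detection, truth) pair with
#' distance <= xi, removing both and repeating; so when several detections
#' fall within xi of one truth, only the closest becomes a TP and the rest
#' count as FPs. Unmatched detections are FPs and unmatched truths FNs.
#' Finally, remaining FP/FN pairs strictly closer than epsilon are rescued
#' (each rescue: fp - 1, fn - 1, tp + 1), again in ascending distance order.
#'
#' @param dets,truth [detection_set()]s (either may be empty).
#' @param params a [match_params()].
#' @return A `MatchResult`: `counts` ([confusion_counts()]), `pairs`
#'   (data.frame det, gt, distance — primary and rescued pairs), `rescued`
#'   (number of rescued pairs).
#' @export
match_detections <- function(dets, truth, params) {
  nd <- n_detections(dets); nt <- n_detections(truth)
  empty_pairs <- data.frame(det = integer(), gt = integer(), distance = numeric())
  if (nd == 0L || nt == 0L) {
    return(structure(list(counts = confusion_counts(0L, nd, nt),
                          pairs = empty_pairs, rescued = 0L),
                     class = "MatchResult"))
  }
  D <- .dist_mat(dets$centroids, truth$centroids)
  prim <- .greedy_pairs(D, function(d) d <= params$xi)
  free_d <- setdiff(seq_len(nd), prim[, 1])
  free_t <- setdiff(seq_len(nt), prim[, 2])
  resc <- NULL
  if (length(free_d) && length(free_t) && params$epsilon > 0) {
    Dr <- D[free_d, free_t, drop = FALSE]
    r <- .greedy_pairs(Dr, function(d) d < params$epsilon)
    if (!is.null(r))
      resc <- cbind(free_d[r[, 1]], free_t[r[, 2]], r[, 3])
  }
  all_pairs <- rbind(prim, resc)
  tp <- if (is.null(all_pairs)) 0L else nrow(all_pairs)
  pairs <- if (is.null(all_pairs)) empty_pairs else
    data.frame(det = as.integer(all_pairs[, 1]), gt = as.integer(all_pairs[, 2]),
               distance = all_pairs[, 3])
  structure(list(counts = confusion_counts(tp, nd - tp, nt - tp),
                 pairs = pairs,
                 rescued = if (is.null(resc)) 0L else nrow(resc)),
            class = "MatchResult")
}

#' Aggregate detection metrics over images
#'
#' Pools confusion counts over all images (pooled precision/recall/Dice) and
#' additionally reports per-case mean and standard deviation of each metric
#' and of the count errors, since per-case averages and pooled values answer
#' different questions. The per-case vectors are included so standard paired
#' tests can be applied externally.
#'
#' @param per_image list of `MatchResult`s (>= 1).
#' @param per_image_counts optional list of [count_errors()] (same length).
#' @return list with `pooled` (counts + metrics), `per_case` (data.frame of
#'   per-image metrics), and `summary` (mean/sd rows).
#' @export
detection_report <- function(per_image, per_image_counts = NULL) {
  if (length(per_image) < 1L) stop("need at least one image", call. = FALSE)
  tp <- sum(vapply(per_image, function(m) m$counts$tp, integer(1)))
  fp <- sum(vapply(per_image, function(m) m$counts$fp, integer(1)))
  fn <- sum(vapply(per_image, function(m) m$counts$fn, integer(1)))
  pooled_counts <- confusion_counts(tp, fp, fn)
  pooled <- precision_recall_dice(pooled_counts)
  per_case <- do.call(rbind, lapply(seq_along(per_image), function(i) {
    m <- per_image[[i]]
    prd <- precision_recall_dice(m$counts)
    data.frame(image = i, tp = m$counts$tp, fp = m$counts$fp, fn = m$counts$fn,
               precision = prd["precision"], recall = prd["recall"],
               dice = prd["dice"], row.names = NULL)
  }))
  if (!is.null(per_image_counts)) {
    per_case$ea <- vapply(per_image_counts, `[[`, numeric(1), "ea")
    per_case$es <- vapply(per_image_counts, `[[`, numeric(1), "es")
  }
  mets <- setdiff(names(per_case), c("image", "tp", "fp", "fn"))
  summary <- data.frame(metric = mets,
                        mean = vapply(per_case[mets], mean, numeric(1)),
                        sd = vapply(per_case[mets], stats::sd, numeric(1)),
                        row.names = NULL)
  list(pooled = c(list(tp = tp, fp = fp, fn = fn), as.list(pooled)),
       per_case = per_case, summary = summary)
}
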