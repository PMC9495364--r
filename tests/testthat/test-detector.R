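test_that("dilation matches its definition on degenerate and random inputs", {
  const <- matrix(2.5, 20, 20)
  expect_equal(dilate_grayscale(const, 7), const)
  imp <- matrix(0, 31, 31); imp[16, 16] <- 3
  got <- dilate_grayscale(imp, 7)
  offs <- expand.grid(du = -7:7, dv = -7:7)
  disk <- offs[offs$du^2 + offs$dv^2 <= 49, ]
  expect_equal(sum(got == 3), nrow(disk))
  expect_true(all(got[cbind(16 + disk$du, 16 + disk$dv)] == 3))
  expect_true(all(got %in% c(0, 3)))
  set.seed(10)
  m <- matrix(rnorm(32 * 32), 32, 32)
  expect_equal(dilate_grayscale(m, 3), dilate_oracle(m, 3))
  expect_error(dilate_grayscale(m, 0), ">= 1")
})

test_that("dilation is extensive and preserves order under monotone maps", {
  set.seed(11)
  m <- matrix(runif(32 * 32), 32, 32)
  d <- dilate_grayscale(m, 5)
  expect_true(all(d >= m))
  f <- function(x) x^3 + 2 * x          # strictly increasing
  expect_equal(dilate_grayscale(f(m), 5), f(d))
})

test_that("regional maxima are plateau-aware with 8-connectivity", {
  peak <- matrix(0, 9, 9); peak[5, 5] <- 1
  got <- regional_maxima(peak)$mask
  expect_identical(which(got), which(peak == 1))
  # constant map: the whole image is one regional maximum
  expect_true(all(regional_maxima(matrix(4, 6, 6))$mask))
  # plateau of equal values surrounded by lower ones
  plat <- matrix(0, 7, 7); plat[3:4, 3:5] <- 2
  expect_identical(regional_maxima(plat)$mask, plat == 2)
  # smoothed random maps vs flood-fill oracle
  set.seed(12)
  for (rep in 1:3) {
    raw <- matrix(runif(32 * 32), 32, 32)
    sm <- dilate_grayscale(raw, 2)   # introduces plateaus
    expect_identical(regional_maxima(sm)$mask, regmax_oracle(sm))
  }
})

test_that("component centroids are per-component coordinate means", {
  m <- matrix(FALSE, 10, 10); m[1:3, 1:3] <- TRUE
  got <- components_and_centroids(binary_mask(m))
  expect_equal(unname(got$centroids[1, ]), c(1.0, 1.0))
  expect_identical(n_detections(components_and_centroids(matrix(FALSE, 5, 5))), 0L)
  set.seed(13)
  m2 <- matrix(FALSE, 20, 20)
  m2[2:5, 2:4] <- TRUE; m2[12:18, 10:16] <- matrix(runif(49) > 0.3, 7, 7)
  m2[15, 13] <- TRUE
  got2 <- components_and_centroids(m2)
  lab <- nucleicam:::label_components_cpp(m2)
  for (k in seq_len(max(lab))) {
    px <- which(lab == k, arr.ind = TRUE)
    expect_equal(unname(got2$centroids[k, ]),
                 c(mean(px[, 1]) - 1, mean(px[, 2]) - 1))
  }
})

test_that("instance assignment follows nearest-centroid K-means", {
  m <- matrix(FALSE, 12, 12); m[3:6, 3:6] <- TRUE
  one <- assign_instances(binary_mask(m),
                          detection_set(cbind(row = 4, col = 4)))
  expect_identical(sort(unique(as.vector(one$labels))), c(0L, 1L))
  expect_true(all(one$labels[m] == 1L))
  # two well-separated blobs, one centroid each -> component partition
  m2 <- matrix(FALSE, 20, 20); m2[2:5, 2:5] <- TRUE; m2[14:17, 14:17] <- TRUE
  two <- assign_instances(binary_mask(m2),
                          detection_set(cbind(row = c(3.5, 15.5), col = c(3.5, 15.5))))
  lab_cc <- nucleicam:::label_components_cpp(m2)
  expect_identical(two$labels, lab_cc)
  # touching blobs bridged by a neck: nearest-final-center oracle
  m3 <- matrix(FALSE, 15, 21)
  m3[4:10, 3:9] <- TRUE; m3[4:10, 13:19] <- TRUE; m3[7, 10:12] <- TRUE
  cents <- detection_set(cbind(row = c(7, 7), col = c(6, 16)))
  got <- assign_instances(binary_mask(m3), cents)
  # recompute converged centers and reassign every pixel exhaustively
  fg <- which(m3, arr.ind = TRUE)
  lab_fg <- got$labels[fg]
  centers <- rbind(
    c(mean(fg[lab_fg == 1, 1] - 1), mean(fg[lab_fg == 1, 2] - 1)),
    c(mean(fg[lab_fg == 2, 1] - 1), mean(fg[lab_fg == 2, 2] - 1)))
  for (r in seq_len(nrow(fg))) {
    d <- (fg[r, 1] - 1 - centers[, 1])^2 + (fg[r, 2] - 1 - centers[, 2])^2
    expect_identical(got$labels[fg[r, 1], fg[r, 2]], which.min(d))
  }
  expect_error(assign_instances(binary_mask(m3), detection_set()), "no centroids")
})

test_that("label count always equals the detection count", {
  set.seed(14)
  for (rep in 1:5) {
    m <- matrix(runif(24 * 24) > 0.6, 24, 24)
    if (!any(m)) next
    k <- sample(1:4, 1)
    fg <- which(m, arr.ind = TRUE)
    pick <- fg[sample(nrow(fg), min(k, nrow(fg))), , drop = FALSE]
    dets <- detection_set(cbind(row = pick[, 1] - 1, col = pick[, 2] - 1))
    lab <- assign_instances(binary_mask(m), dets)
    expect_identical(length(setdiff(unique(as.vector(lab$labels)), 0L)),
                     n_detections(dets))
    expect_true(all(lab$labels[!m] == 0L))
  }
})

test_that("detection is invariant to monotone rescaling of the CAM", {
  set.seed(15)
  cmv <- dilate_grayscale(matrix(runif(40 * 40), 40, 40), 2)
  detect_from <- function(v) {
    mx <- regional_maxima(dilate_grayscale(v, 7))$mask
    components_and_centroids(mx)$centroids
  }
  base <- detect_from(cmv)
  expect_equal(detect_from(exp(3 * cmv)), base)
  expect_equal(detect_from(cmv^3 + 0.1 * cmv), base)
})

test_that("detect_nuclei returns empty results for an all-background scorer", {
  m <- toy_seg_model(
    score_fn = function(image) {
      d <- dim(image$pixels)
      array(c(matrix(0.9, d[1], d[2]), matrix(0.1, d[1], d[2])),
            dim = c(d[1], d[2], 2))
    },
    feature_fn = function(image, layer_id) {
      d <- dim(image$pixels)
      array(0.1, dim = c(d[1], d[2], 1))
    },
    grad_fn = function(image, class_index, region_mask, layer_id) {
      d <- dim(image$pixels)
      array(0, dim = c(d[1], d[2], 1))
    },
    layers = "toy")
  img <- image_tile(array(0.5, dim = c(20, 20, 3)))
  res <- detect_nuclei(m, img, detect_params(layer_id = "toy"))
  expect_identical(n_detections(res$detections), 0L)
  expect_true(all(res$instances$labels == 0L))
})

test_that("end-to-end detection finds well-separated nuclei with F1 >= 0.8", {
  fx <- fixture_pipeline()
  st <- fx$test[[2]]
  res <- detect_nuclei(fx$model, st$image, detect_params(kmeans_seed = 0))
  mr <- match_detections(res$detections, st$centroids,
                         match_params(xi = mean_nuclear_radius(st$instances)))
  prd <- precision_recall_dice(mr$counts)
  expect_gte(prd["dice"], 0.8)
  # detected centroids stay on or near the predicted foreground
  expect_true(all(res$instances$labels[res$mask$mask] > 0L |
                  !any(res$mask$mask)))
})
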