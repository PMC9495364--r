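test_that("pixel confusion counts agree with an exhaustive pixel loop", {
  m <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  same <- pixel_confusion(m, m)
  expect_identical(c(same$fp, same$fn), c(0L, 0L))
  disj <- pixel_confusion(m, !m)
  expect_identical(disj$tp, 0L)
  set.seed(20)
  p <- matrix(runif(256) > 0.5, 16, 16)
  t <- matrix(runif(256) > 0.5, 16, 16)
  got <- pixel_confusion(p, t)
  tp <- fp <- fn <- 0L
  for (i in 1:16) for (j in 1:16) {
    if (p[i, j] && t[i, j]) tp <- tp + 1L
    if (p[i, j] && !t[i, j]) fp <- fp + 1L
    if (!p[i, j] && t[i, j]) fn <- fn + 1L
  }
  expect_identical(c(got$tp, got$fp, got$fn), c(tp, fp, fn))
  expect_error(pixel_confusion(p, t[1:8, ]), "shapes differ")
})

test_that("precision/recall/Dice follow their definitions with the 0/0 -> 0 convention", {
  expect_equal(unname(precision_recall_dice(confusion_counts(0, 0, 0))), c(0, 0, 0))
  expect_equal(unname(precision_recall_dice(confusion_counts(7, 0, 0))), c(1, 1, 1))
  got <- precision_recall_dice(confusion_counts(10, 5, 3))
  expect_equal(unname(got), c(10 / 15, 10 / 13, 20 / 28))
})

test_that("Dice from counts equals the harmonic mean of precision and recall", {
  set.seed(21)
  for (rep in 1:50) {
    cc <- confusion_counts(sample(1:500, 1), sample(0:200, 1), sample(0:200, 1))
    m <- precision_recall_dice(cc)
    expect_equal(unname(m["dice"]),
                 2 * m["precision"] * m["recall"] / (m["precision"] + m["recall"]),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("count errors are the relative signed and absolute differences", {
  eq <- count_errors(100, 100)
  expect_equal(c(eq$ea, eq$es), c(0, 0))
  over <- count_errors(110, 100)
  expect_equal(c(over$ea, over$es), c(0.10, 0.10))
  under <- count_errors(80, 100)
  expect_equal(c(under$ea, under$es), c(0.20, -0.20))
  expect_equal(under$ea, abs(under$es))
  expect_error(count_errors(5, 0), "> 0")
})

test_that("mean nuclear radius recovers equivalent-circle radii", {
  disk_map <- function(radii, H = 64, W = 64) {
    lab <- matrix(0L, H, W)
    cx <- seq(12, W - 12, length.out = length(radii))
    for (k in seq_along(radii)) {
      for (i in 1:H) for (j in 1:W)
        if ((i - 32)^2 + (j - cx[k])^2 <= radii[k]^2) lab[i, j] <- k
    }
    instance_label_map(lab)
  }
  expect_lt(abs(mean_nuclear_radius(disk_map(5)) - 5), 0.5)
  expect_lt(abs(mean_nuclear_radius(disk_map(c(3, 7))) - 5), 0.5)
  # random ellipse areas vs explicit per-label pixel count
  set.seed(22)
  st <- generate_tile(synth_params(n_nuclei = 6, seed = 9))
  lab <- st$instances$labels
  areas <- vapply(1:max(lab), function(k) sum(lab == k), numeric(1))
  expect_equal(mean_nuclear_radius(st$instances), mean(sqrt(areas / pi)))
  expect_error(mean_nuclear_radius(instance_label_map(matrix(0L, 4, 4))),
               "no instances")
})

test_that("matching handles the boundary and degenerate cases as specified", {
  pts <- cbind(row = c(3, 10, 40), col = c(5, 30, 8))
  d <- detection_set(pts); t <- detection_set(pts)
  exact <- match_detections(d, t, match_params(xi = 5))
  expect_identical(c(exact$counts$tp, exact$counts$fp, exact$counts$fn), c(3L, 0L, 0L))
  none <- match_detections(detection_set(), t, match_params(xi = 5))
  expect_identical(c(none$counts$tp, none$counts$fp, none$counts$fn), c(0L, 0L, 3L))
  # distance exactly xi is a match (inclusive)
  at_xi <- match_detections(detection_set(cbind(row = 0, col = 10)),
                            detection_set(cbind(row = 0, col = 0)),
                            match_params(xi = 10))
  expect_identical(at_xi$counts$tp, 1L)
  # distance exactly epsilon is NOT rescued (strict)
  at_eps <- match_detections(detection_set(cbind(row = 0, col = 6)),
                             detection_set(cbind(row = 0, col = 0)),
                             match_params(xi = 2, epsilon = 6))
  expect_identical(at_eps$counts$tp, 0L)
  expect_identical(at_eps$rescued, 0L)
  just_under <- match_detections(detection_set(cbind(row = 0, col = 5.999)),
                                 detection_set(cbind(row = 0, col = 0)),
                                 match_params(xi = 2, epsilon = 6))
  expect_identical(just_under$counts$tp, 1L)
  expect_identical(just_under$rescued, 1L)
})

test_that("a duplicate detection near one truth counts once as TP and once as FP", {
  t <- detection_set(cbind(row = c(10, 30, 50, 70, 90), col = rep(10, 5)))
  d <- detection_set(cbind(row = c(10.5, 12, 30, 50, 70, 200), col = c(10, 10, 10, 10, 10, 200)))
  mr <- match_detections(d, t, match_params(xi = 10, epsilon = 6))
  # 4 primary TPs; det 2 (dist 2 from truth 1) is FP since det 1 is closer;
  # det 6 is a stray FP; truth 5 (row 90) is rescued by nothing within 6
  expect_identical(c(mr$counts$tp, mr$counts$fp, mr$counts$fn), c(4L, 2L, 1L))
  # closest pair won: the matched det for truth 1 is det 1
  expect_identical(mr$pairs$det[mr$pairs$gt == 1], 1L)
})

test_that("matching equals the sort-based greedy oracle on random instances", {
  set.seed(23)
  for (rep in 1:40) {
    nd <- sample(0:8, 1); nt <- sample(0:8, 1)
    dxy <- matrix(runif(2 * nd, 0, 40), ncol = 2)
    txy <- matrix(runif(2 * nt, 0, 40), ncol = 2)
    mr <- match_detections(detection_set(dxy), detection_set(txy),
                           match_params(xi = 10, epsilon = 6))
    or <- match_oracle(dxy, txy, xi = 10, epsilon = 6)
    expect_identical(c(mr$counts$tp, mr$counts$fp, mr$counts$fn),
                     c(or$tp, or$fp, or$fn))
    # conservation identities
    expect_identical(mr$counts$tp + mr$counts$fn, nt)
    expect_identical(mr$counts$tp + mr$counts$fp, nd)
  }
})

test_that("matching counts are invariant to detection order", {
  set.seed(24)
  dxy <- matrix(runif(16, 0, 30), ncol = 2)
  txy <- matrix(runif(14, 0, 30), ncol = 2)
  base <- match_detections(detection_set(dxy), detection_set(txy),
                           match_params(xi = 8))
  for (rep in 1:5) {
    perm <- sample(nrow(dxy))
    got <- match_detections(detection_set(dxy[perm, ]), detection_set(txy),
                            match_params(xi = 8))
    expect_identical(unlist(got$counts), unlist(base$counts))
  }
})

test_that("the report pools counts and summarises per-case metrics", {
  mk <- function(tp, fp, fn)
    structure(list(counts = confusion_counts(tp, fp, fn),
                   pairs = data.frame(), rescued = 0L), class = "MatchResult")
  single <- detection_report(list(mk(8, 2, 1)))
  expect_equal(single$pooled$precision,
               unname(precision_recall_dice(confusion_counts(8, 2, 1))["precision"]))
  twin <- detection_report(list(mk(5, 1, 2), mk(5, 1, 2)))
  expect_equal(twin$pooled$dice,
               unname(precision_recall_dice(confusion_counts(5, 1, 2))["dice"]))
  set.seed(25)
  ms <- lapply(1:6, function(i) mk(sample(1:20, 1), sample(0:5, 1), sample(0:5, 1)))
  rep_ <- detection_report(ms, lapply(ms, function(m)
    count_errors(m$counts$tp + m$counts$fp, m$counts$tp + m$counts$fn)))
  summed <- confusion_counts(sum(rep_$per_case$tp), sum(rep_$per_case$fp),
                             sum(rep_$per_case$fn))
  expect_equal(unlist(rep_$pooled[c("precision", "recall", "dice")]),
               precision_recall_dice(summed), ignore_attr = TRUE)
  expect_true(all(c("ea", "es") %in% rep_$summary$metric))
  expect_error(detection_report(list()), "at least one")
})
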