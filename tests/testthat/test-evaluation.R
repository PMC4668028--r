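test_that("point matching counts TPs, FPs and FNs one-to-one", {
  truth <- tibble::tibble(row = c(10L, 30L, 50L), col = c(10L, 30L, 50L))
  m <- match_points(truth, truth, tolerance_px = 2)
  expect_equal(c(m$tp, m$fp, m$fn), c(3L, 0L, 0L))

  m0 <- match_points(truth[0, ], truth, tolerance_px = 2)
  expect_equal(c(m0$tp, m0$fp, m0$fn), c(0L, 0L, 3L))

  # two detections near one truth point: only one can match
  det <- tibble::tibble(row = c(10L, 11L), col = c(10L, 10L))
  m2 <- match_points(det, truth[1, ], tolerance_px = 3)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(1L, 1L, 0L))
  # the closer detection wins
  expect_equal(m2$matched$detection, 1L)

  m3 <- match_points(det, truth[1, ], tolerance_px = 3, one_to_one = FALSE)
  expect_equal(c(m3$tp, m3$fp, m3$fn), c(2L, 0L, 0L))
})

test_that("greedy matching agrees with exhaustive assignment on small sets", {
  set.seed(88)
  for (i in 1:30) {
    nd <- sample(1:4, 1)
    nt <- sample(1:4, 1)
    det <- tibble::tibble(row = sample(0:8, nd, replace = TRUE),
                          col = sample(0:8, nd, replace = TRUE))
    tru <- tibble::tibble(row = sample(0:8, nt, replace = TRUE),
                          col = sample(0:8, nt, replace = TRUE))
    got <- match_points(det, tru, tolerance_px = 3)
    want <- oracle_match_counts(det, tru, 3)
    # greedy nearest-first matching is one-to-one and consistent; it can
    # never beat the exhaustive maximum matching, and it finds a match
    # whenever one exists
    expect_lte(got$tp, want[["tp"]])
    if (want[["tp"]] > 0) expect_gte(got$tp, 1L)
    expect_equal(got$tp + got$fp, nrow(det))
    expect_equal(got$tp + got$fn, nrow(tru))
    # matched pairs really are within tolerance and one-to-one
    if (nrow(got$matched) > 0) {
      dd <- (det$row[got$matched$detection] - tru$row[got$matched$truth])^2 +
        (det$col[got$matched$detection] - tru$col[got$matched$truth])^2
      expect_true(all(dd <= 9))
      expect_equal(anyDuplicated(got$matched$detection), 0L)
      expect_equal(anyDuplicated(got$matched$truth), 0L)
    }
  }
})

toy_detections <- function() {
  set.seed(12)
  truth <- tibble::tibble(
    image_id = rep(c("a", "b"), each = 5),
    row = rep(seq(10, 90, by = 20), 2),
    col = rep(seq(10, 90, by = 20), 2)
  )
  hits <- truth
  hits$row <- hits$row + sample(-1:1, 10, replace = TRUE)
  hits$score <- runif(10, 0.5, 1)
  misses <- tibble::tibble(
    image_id = sample(c("a", "b"), 10, replace = TRUE),
    row = sample(100:190, 10), col = sample(100:190, 10),
    score = runif(10, 0, 0.8)
  )
  list(truth = truth, det = dplyr::bind_rows(hits, misses))
}

test_that("ROC and PR counts match a brute-force per-threshold recount", {
  toy <- toy_detections()
  thresholds <- sort(unique(toy$det$score))
  roc <- roc_curve(toy$det, toy$truth, total_negatives = 10000,
                   thresholds = thresholds, tolerance_px = 3)
  pr <- pr_curve(toy$det, toy$truth, thresholds = thresholds,
                 tolerance_px = 3)
  for (th in thresholds) {
    kept <- toy$det[toy$det$score >= th, ]
    tp <- fp <- fn <- 0L
    for (id in c("a", "b")) {
      cnt <- oracle_match_counts(kept[kept$image_id == id, ],
                                 toy$truth[toy$truth$image_id == id, ], 3)
      tp <- tp + cnt[["tp"]]; fp <- fp + cnt[["fp"]]; fn <- fn + cnt[["fn"]]
    }
    i <- which(roc$threshold == th)
    expect_equal(unname(c(roc$tp[i], roc$fp[i], roc$fn[i])),
                 unname(c(tp, fp, fn)))
    expect_equal(roc$one_minus_specificity[i], fp / 10000)
    j <- which(pr$threshold == th)
    expect_equal(pr$precision[j], tp / (tp + fp))
  }
  # monotone funnels along descending thresholds
  expect_true(all(diff(roc$tp) >= 0))
  expect_true(all(diff(roc$fp) >= 0))
  expect_true(all(diff(pr$sensitivity) >= 0))
})

test_that("ROC endpoints behave: silence at the top, perfection for a perfect scorer", {
  toy <- toy_detections()
  roc <- roc_curve(toy$det, toy$truth, total_negatives = 1000,
                   thresholds = c(2, 0.4), tolerance_px = 3)
  expect_equal(roc$sensitivity[roc$threshold == 2], 0)
  expect_equal(roc$one_minus_specificity[roc$threshold == 2], 0)

  # perfect scorer: all truth found at high scores, junk below
  truth <- tibble::tibble(image_id = "a", row = c(5L, 20L), col = c(5L, 20L))
  det <- tibble::tibble(image_id = "a", row = c(5L, 20L, 40L),
                        col = c(5L, 20L, 40L), score = c(0.9, 0.95, 0.1))
  roc2 <- roc_curve(det, truth, total_negatives = 100)
  auc <- curve_auc(c(0, roc2$one_minus_specificity, 1),
                   c(0, roc2$sensitivity, 1))
  expect_equal(auc, 1)
})

test_that("FROC counts match a brute-force recount on a 5-image toy set", {
  ann <- tibble::tibble(
    image_id = c("a", "a", "b", "c"), shape = "box",
    row_a = c(0, 50, 10, 10), col_a = c(0, 50, 10, 10),
    row_b = c(20, 70, 30, 30), col_b = c(20, 70, 30, 30)
  )
  cl <- tibble::tibble(
    image_id = c("a", "a", "b", "d", "e", "c"),
    center_row = c(10, 90, 20, 50, 50, 50),
    center_col = c(10, 90, 20, 50, 50, 50),
    score = c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4)
  )
  froc <- froc_curve(cl, ann, n_images = 5)
  for (i in seq_len(nrow(froc))) {
    kept <- cl[cl$score >= froc$threshold[i], ]
    hits <- mapply(function(r, c, id) {
      match_cluster(c(r, c), ann[ann$image_id == id, ])
    }, kept$center_row, kept$center_col, kept$image_id)
    fp <- sum(!hits)
    covered <- mapply(function(j) {
      k <- kept[kept$image_id == ann$image_id[j], ]
      nrow(k) > 0 && any(mapply(function(r, c) {
        match_cluster(c(r, c), ann[j, , drop = FALSE])
      }, k$center_row, k$center_col))
    }, seq_len(nrow(ann)))
    expect_equal(froc$fp_per_image[i], fp / 5)
    expect_equal(froc$sensitivity[i], sum(covered) / nrow(ann))
  }
  # a detector emitting one FP per image at any threshold is a flat line
  flat <- tibble::tibble(image_id = c("a", "b", "c", "d", "e"),
                         center_row = 90, center_col = 90, score = 0.5)
  froc_flat <- froc_curve(flat, ann, n_images = 5,
                          thresholds = c(0.1, 0.3, 0.5))
  expect_true(all(froc_flat$sensitivity == 0))
  expect_true(all(froc_flat$fp_per_image == 1))
  expect_error(froc_curve(cl, ann[0, ], 5), "undefined")
})

test_that("trapezoidal AUC reproduces hand integrals", {
  expect_equal(curve_auc(c(0, 1), c(0, 1)), 0.5)
  expect_equal(curve_auc(c(0, 0, 1), c(0, 1, 1)), 1)
  expect_equal(curve_auc(c(0, 0.5, 1), c(0, 0.8, 1)), 0.65)
  # clipping and normalisation by x_max
  expect_equal(curve_auc(c(0, 2, 4), c(1, 1, 1), x_max = 4), 1)
})

test_that("a random scorer has chance-level AUC", {
  set.seed(71)
  aucs <- replicate(20, {
    score_auc(runif(400), rep(c(0, 1), 200))
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  # and a perfect scorer has AUC 1
  expect_equal(score_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
})

test_that("cross-validation folds partition images with stratification", {
  ids <- sprintf("img%02d", 1:37)
  has <- rep(c(TRUE, FALSE), length.out = 37)
  folds <- cv_folds(ids, has, k = 10, seed = 3)
  expect_setequal(folds$image_id, ids)
  expect_equal(anyDuplicated(folds$image_id), 0L)
  expect_true(all(folds$fold %in% 1:10))
  # each stratum spreads evenly: fold sizes differ by at most one
  for (grp in c(TRUE, FALSE)) {
    sizes <- table(factor(folds$fold[folds$has_mc == grp], levels = 1:10))
    expect_lte(diff(range(sizes)), 1)
  }
})
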