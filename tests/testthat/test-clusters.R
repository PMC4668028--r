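test_that("physical lengths convert to the archive pixel sizes", {
  expect_equal(mm_to_px(10, 0.1), 100)
  expect_equal(mm_to_px(10, 0.05), 200)
  expect_equal(mm_to_px(10, 0.2), 50)
  expect_equal(mm_to_px(4, 0.1, round = FALSE), 40)
})

test_that("the pairwise rule groups constructed point sets correctly", {
  cfg <- cluster_rule_config(spacing_mm = 1)  # distances in mm = px
  three <- tibble::tibble(row = c(0, 3, 0), col = c(0, 0, 3), score = 1)
  cl <- clusters_rule1(three, cfg)  # mutual distances 3, 3, ~4.24 > 4?
  # pairwise distances: 3, 3, 4.24 -> the diagonal pair exceeds d_c1
  expect_equal(nrow(cl), 0)

  tight <- tibble::tibble(row = c(0, 3, 2), col = c(0, 0, 2), score = 1)
  cl2 <- clusters_rule1(tight, cfg)
  expect_equal(nrow(cl2), 1)
  expect_equal(cl2$n_members, 3L)
  expect_equal(cl2$center_row, round(mean(tight$row)))

  two <- tibble::tibble(row = c(0, 1), col = c(0, 0), score = 1)
  expect_equal(nrow(clusters_rule1(two, cfg)), 0)
})

test_that("overlapping candidates resolve to the larger cluster", {
  cfg <- cluster_rule_config(spacing_mm = 1)
  # four points clustered at origin; two more near (6, 0) that only form a
  # triple through the shared point at (3, 0)
  pts <- tibble::tibble(
    row = c(0, 2, 0, 3, 6, 6),
    col = c(0, 0, 2, 0, 0, 2),
    score = 1
  )
  cl <- clusters_rule1(pts, cfg)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_members, 4L)
  expect_setequal(cl$members[[1]], 1:4)
})

test_that("rule-1 output matches the brute-force oracle on random sets", {
  cfg <- cluster_rule_config(spacing_mm = 1)
  set.seed(55)
  for (i in 1:25) {
    n <- sample(3:12, 1)
    pts <- tibble::tibble(row = sample(0:15, n, replace = TRUE) * 1.0,
                          col = sample(0:15, n, replace = TRUE) * 1.0,
                          score = 1)
    pts <- dplyr::distinct(pts, row, col, .keep_all = TRUE)
    cl <- clusters_rule1(pts, cfg)
    oracle <- oracle_rule1(cbind(pts$row, pts$col), cfg$d_c1_mm)
    expect_equal(nrow(cl), length(oracle))
    if (nrow(cl) > 0) {
      got <- lapply(cl$members, sort)
      expect_setequal(lapply(got, paste, collapse = ","),
                      lapply(oracle, paste, collapse = ","))
      # invariants: >= 3 members, pairwise within d_c1, member-disjoint
      all_members <- unlist(cl$members)
      expect_equal(anyDuplicated(all_members), 0L)
      for (m in cl$members) {
        expect_gte(length(m), 3)
        expect_lte(max(stats::dist(cbind(pts$row[m], pts$col[m]))),
                   cfg$d_c1_mm + 1e-12)
      }
    }
  }
})

test_that("the localized-region constraint can reject wide candidates", {
  # a tiny region budget rejects a triple that a roomy one accepts
  roomy <- cluster_rule_config(spacing_mm = 1)
  tiny <- cluster_rule_config(a_c1_mm2 = 4, spacing_mm = 1)
  pts <- tibble::tibble(row = c(0, 3, 2), col = c(0, 0, 2), score = 1)
  expect_equal(nrow(clusters_rule1(pts, roomy)), 1)
  expect_equal(nrow(clusters_rule1(pts, tiny)), 0)
})

test_that("the cumulative map equals nested-loop box sums exactly", {
  m <- matrix(0, 12, 12)
  m[6, 6] <- 0.8
  pc <- cumulative_probability_map(m, 5)
  expect_equal(pc[6, 6], 0.8)
  expect_equal(sort(unique(as.vector(pc))), c(0, 0.8))
  expect_equal(sum(pc == 0.8), 25)

  m[7, 7] <- 0.4  # within one window of the first: peak is additive
  expect_equal(max(cumulative_probability_map(m, 5)), 1.2, tolerance = 1e-12)

  set.seed(66)
  sparse <- matrix(0, 64, 64)
  idx <- sample(64 * 64, 40)
  sparse[idx] <- runif(40)
  expect_equal(cumulative_probability_map(sparse, 11),
               oracle_box_sum(sparse, 11))
  # linear in the scores
  expect_equal(cumulative_probability_map(2 * sparse, 11),
               2 * cumulative_probability_map(sparse, 11))
})

test_that("the cumulative rule thresholds and merges windows", {
  cfg <- cluster_rule_config(p_c_threshold = 1.0, spacing_mm = 1)
  # window side = sqrt(100) / 1 = 10 -> 11 after odd adjustment
  det <- tibble::tibble(row = c(30, 32, 31), col = c(30, 30, 33),
                        score = c(0.6, 0.6, 0.5))
  pm <- detections_to_prob_map(det, c(64, 64))
  cl <- clusters_rule2(pm, cfg, image_id = "x")
  expect_equal(nrow(cl), 1)
  expect_gte(cl$score, 1.7 - 1e-12)
  expect_true(cl$center_row >= cl$row_min && cl$center_row <= cl$row_max)
  # the group centroid lies inside the reported box
  expect_true(mean(det$row) >= cl$row_min && mean(det$row) <= cl$row_max)
  expect_true(mean(det$col) >= cl$col_min && mean(det$col) <= cl$col_max)

  high <- cluster_rule_config(p_c_threshold = 5, spacing_mm = 1)
  expect_equal(nrow(clusters_rule2(pm, high)), 0)

  # lowering the threshold cannot lose supra-threshold pixels
  pc <- cumulative_probability_map(pm, 11)
  expect_true(all((pc >= 1.0) <= (pc >= 0.5)))
})

test_that("cluster matching is inclusive on boundaries", {
  ann <- tibble::tibble(image_id = "a", shape = c("box", "circle"),
                        row_a = c(10, 50), col_a = c(10, 50),
                        row_b = c(20, 5), col_b = c(20, NA))
  expect_true(match_cluster(c(10, 10), ann))   # box corner
  expect_true(match_cluster(c(20, 20), ann))
  expect_false(match_cluster(c(21, 10), ann))
  expect_true(match_cluster(c(55, 50), ann))   # exactly one radius away
  expect_false(match_cluster(c(56, 50), ann))
  expect_false(match_cluster(c(5, 5), ann[0, ]))
})

test_that("perfect detections recover every planted cluster with no false positives", {
  cfg <- cluster_rule_config(spacing_mm = 0.2)
  for (s in c(3L, 14L)) {
    ph <- generate_phantom(phantom_spec(seed = s,
                                        cluster_radius_mm = 4 / 2))
    det <- tibble::tibble(image_id = ph$image_id, row = ph$mc_points$row,
                          col = ph$mc_points$col, score = 1)
    cl <- clusters_rule1(det, cfg)
    hit <- vapply(seq_len(nrow(cl)), function(k) {
      match_cluster(c(cl$center_row[k], cl$center_col[k]), ph$clusters)
    }, logical(1))
    expect_equal(sum(!hit), 0L)
    covered <- vapply(seq_len(nrow(ph$clusters)), function(j) {
      any(vapply(seq_len(nrow(cl)), function(k) {
        match_cluster(c(cl$center_row[k], cl$center_col[k]),
                      ph$clusters[j, , drop = FALSE])
      }, logical(1)))
    }, logical(1))
    expect_true(all(covered))
  }
})
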