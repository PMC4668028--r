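#' Build stage-1 training features from annotated phantoms
#'
#' Positive feature vectors are taken at the annotated microcalcification
#' coordinates; negatives are sampled uniformly from the breast region
#' excluding the annotated cluster bounding boxes.
#'
#' @param phantoms List of phantoms from [generate_phantom()].
#' @param config A `pipeline_config`.
#' @param negatives_per_positive Negative:positive sampling ratio.
#' @param seed Integer seed for negative sampling.
#' @return List with `features` (matrix) and `labels` (0/1 vector).
#' @export
build_rf_training_set <- function(phantoms, config,
                                  negatives_per_positive = 5, seed = 1L) {
  set.seed(seed)
  feats <- list()
  labels <- list()
  for (ph in phantoms) {
    fmap <- feature_map(ph$image, ph$breast_mask, config$scales)
    key <- fmap$coords$row + fmap$coords$col * 1e6
    pos_key <- ph$mc_points$row + ph$mc_points$col * 1e6
    pos_idx <- match(pos_key, key)
    if (anyNA(pos_idx)) stop("annotated point outside mask", call. = FALSE)

    in_box <- rep(FALSE, nrow(fmap$coords))
    for (b in seq_len(nrow(ph$clusters))) {
      in_box <- in_box |
        (fmap$coords$row >= ph$clusters$row_a[b] &
           fmap$coords$row <= ph$clusters$row_b[b] &
           fmap$coords$col >= ph$clusters$col_a[b] &
           fmap$coords$col <= ph$clusters$col_b[b])
    }
    neg_pool <- setdiff(which(!in_box), pos_idx)
    n_neg <- min(length(neg_pool),
                 round(negatives_per_positive * length(pos_idx)))
    neg_idx <- neg_pool[sample.int(length(neg_pool), n_neg)]

    feats[[length(feats) + 1]] <- fmap$features[c(pos_idx, neg_idx), ,
                                                drop = FALSE]
    labels[[length(labels) + 1]] <- c(rep(1L, length(pos_idx)),
                                      rep(0L, length(neg_idx)))
  }
  list(features = do.call(rbind, feats), labels = unlist(labels))
}

#' Build stage-2 patch training set from stage-1 candidates
#'
#' Positive patches are extracted at the annotated coordinates; negative
#' patches at stage-1 candidate peaks that are farther than `tolerance_px`
#' from every annotated point (the stage-1 false positives), subsampled so
#' the negative set has the same size as the stage-1 classifier's negative
#' set (`negatives_per_positive` times the positive count).
#'
#' @param phantoms List of phantoms.
#' @param forest Trained `mc_rf`.
#' @param config A `pipeline_config`.
#' @param tolerance_px Match radius separating stage-1 hits from false
#'   positives; defaults to 0.5 mm at the config's spacing.
#' @param seed Integer seed for subsampling.
#' @param negatives_per_positive Negative:positive cap, mirroring the
#'   stage-1 sampling ratio.
#' @return List with `patches` (matrix) and `labels`.
#' @export
build_drbm_training_set <- function(phantoms, forest, config,
                                    tolerance_px = NULL, seed = 1L,
                                    negatives_per_positive = 5) {
  tolerance_px <- tolerance_px %||% (0.5 / config$spacing_mm)
  set.seed(seed)
  pos <- list()
  neg <- list()
  for (ph in phantoms) {
    fmap <- feature_map(ph$image, ph$breast_mask, config$scales)
    flagged <- classify_candidates(forest, fmap, config$theta_rf)
    comps <- connected_components(flagged)
    patch_at <- function(rc) extract_patch(ph$image, rc, config$patch_side)
    pos[[length(pos) + 1]] <- t(vapply(seq_len(nrow(ph$mc_points)),
      function(i) patch_at(c(ph$mc_points$row[i], ph$mc_points$col[i])),
      numeric(config$patch_side^2)))
    if (length(comps) > 0) {
      peaks <- t(vapply(comps, function(p) {
        nms_peak(ph$image, p, config$nms_sigma_px)
      }, numeric(2)))
      d2 <- outer(peaks[, 1], ph$mc_points$row, "-")^2 +
        outer(peaks[, 2], ph$mc_points$col, "-")^2
      is_fp <- apply(d2, 1, min) > tolerance_px^2
      if (any(is_fp)) {
        fp_peaks <- peaks[is_fp, , drop = FALSE]
        neg[[length(neg) + 1]] <- t(vapply(seq_len(nrow(fp_peaks)),
          function(i) patch_at(fp_peaks[i, ]),
          numeric(config$patch_side^2)))
      }
    }
  }
  pos <- do.call(rbind, pos)
  neg <- if (length(neg) > 0) do.call(rbind, neg) else
    matrix(numeric(0), 0, config$patch_side^2)
  n_neg_max <- round(negatives_per_positive * nrow(pos))
  if (nrow(neg) > n_neg_max) {
    neg <- neg[sample.int(nrow(neg), n_neg_max), , drop = FALSE]
  }
  list(patches = rbind(pos, neg),
       labels = c(rep(1L, nrow(pos)), rep(0L, nrow(neg))))
}

#' Train the full cascade on annotated phantoms
#'
#' @param phantoms Training phantoms.
#' @param config A `pipeline_config`.
#' @param seed Integer seed driving RF training, DRBM training and all
#'   sampling.
#' @param negatives_per_positive Stage-1 negative sampling ratio.
#' @return List with `forest` and `drbm`.
#' @export
train_cascade <- function(phantoms, config, seed = 1L,
                          negatives_per_positive = 5) {
  rf_set <- build_rf_training_set(phantoms, config,
                                  negatives_per_positive, seed = seed)
  forest <- train_forest(rf_set$features, rf_set$labels,
                         n_trees = config$n_trees,
                         max_depth = config$max_depth,
                         min_node_fraction = config$min_node_fraction,
                         n_candidates = config$n_candidates,
                         seed = seed + 1L)
  drbm_set <- build_drbm_training_set(
    phantoms, forest, config, seed = seed + 2L,
    negatives_per_positive = negatives_per_positive)
  drbm <- train_drbm(drbm_set$patches, drbm_set$labels,
                     n_hidden = config$n_hidden,
                     learning_rate = config$learning_rate,
                     n_epochs = config$n_epochs,
                     batch_size = config$batch_size,
                     cd_steps = config$cd_steps, seed = seed + 3L)
  list(forest = forest, drbm = drbm)
}

#' End-to-end detection experiment on synthetic phantoms
#'
#' Generates training and test phantoms, trains the cascade on the training
#' set, runs full-image detection on every test phantom, groups detections
#' with the pairwise-distance cluster rule, and scores: the pixel-level ROC
#' AUC of the stage-1 posterior against ground-truth microcalcification
#' disks (a pixel is positive within `ceiling(sigma)` of a planted bump
#' centre), point-level detection counts, cluster sensitivity and false
#' positive clusters per image, and the cascade's per-stage candidate
#' funnel.
#'
#' @param train_seeds Phantom seeds for the training images.
#' @param test_seeds Phantom seeds for the test images.
#' @param config A `pipeline_config` (default: the `"phantom"` preset).
#' @param spec_template A [phantom_spec()] whose seed is replaced per image.
#' @param seed Integer seed for model training.
#' @return List with `metrics` (one-row tibble), `per_image` (per-test-image
#'   tibble), `models`, `detections` and `clusters`.
#' @export
run_phantom_experiment <- function(train_seeds = 100:115,
                                   test_seeds = 0:19,
                                   config = preset_config("phantom"),
                                   spec_template = phantom_spec(),
                                   seed = 1L) {
  make_phantom <- function(s) {
    spec <- spec_template
    spec$seed <- as.integer(s)
    generate_phantom(spec)
  }
  train_ph <- lapply(train_seeds, make_phantom)
  models <- train_cascade(train_ph, config, seed = seed)

  tolerance_px <- 0.5 / config$spacing_mm
  scored_dets <- list()
  per_image <- list()
  all_scores <- list()
  all_labels <- list()
  all_dets <- list()
  all_clusters <- list()
  all_ann <- list()
  cfg_all <- config
  cfg_all$theta_drbm <- 0  # keep every scored candidate; filter below
  for (s in test_seeds) {
    ph <- make_phantom(s)
    det <- detect_mc(ph$image, models$forest, models$drbm, cfg_all,
                     mask = NULL, image_id = ph$image_id)
    scored <- det$detections
    det$detections <- scored[scored$score >= config$theta_drbm, ,
                             drop = FALSE]
    det$counts$count[det$counts$stage == "final"] <- nrow(det$detections)
    # pixel-level ground truth: disks of radius ceiling(sigma) around bumps
    idx <- which(det$mask$mask)
    nr <- nrow(det$mask$mask)
    prow <- (idx - 1) %% nr
    pcol <- (idx - 1) %/% nr
    lab <- rep(FALSE, length(idx))
    for (i in seq_len(nrow(ph$mc_points))) {
      rad <- ceiling(ph$mc_points$sigma_px[i])
      lab <- lab | ((prow - ph$mc_points$row[i])^2 +
                      (pcol - ph$mc_points$col[i])^2 <= rad^2)
    }
    all_scores[[length(all_scores) + 1]] <- det$rf_prob[idx]
    all_labels[[length(all_labels) + 1]] <- lab

    m <- match_points(det$detections, ph$mc_points, tolerance_px)
    cl <- clusters_rule1(det$detections, config$cluster)
    hit <- if (nrow(cl) > 0) {
      vapply(seq_len(nrow(cl)), function(i) {
        match_cluster(c(cl$center_row[i], cl$center_col[i]), ph$clusters)
      }, logical(1))
    } else logical(0)
    ann_hit <- vapply(seq_len(nrow(ph$clusters)), function(j) {
      nrow(cl) > 0 && any(vapply(seq_len(nrow(cl)), function(i) {
        match_cluster(c(cl$center_row[i], cl$center_col[i]),
                      ph$clusters[j, , drop = FALSE])
      }, logical(1)))
    }, logical(1))

    counts <- setNames(det$counts$count, det$counts$stage)
    per_image[[length(per_image) + 1]] <- tibble::tibble(
      image_id = ph$image_id,
      n_mc = nrow(ph$mc_points), n_clusters = nrow(ph$clusters),
      flagged_pixels = counts["flagged_pixels"],
      components = counts["components"],
      candidates = counts["candidates"], final = counts["final"],
      mask_pixels = length(idx),
      tp = m$tp, fp = m$fp, fn = m$fn,
      clusters_detected = nrow(cl), clusters_tp = sum(hit),
      clusters_fp = sum(!hit), ann_clusters_hit = sum(ann_hit)
    )
    all_dets[[length(all_dets) + 1]] <- det$detections
    all_clusters[[length(all_clusters) + 1]] <- cl
    all_ann[[length(all_ann) + 1]] <- ph$clusters
    scored_dets[[length(scored_dets) + 1]] <- scored
  }
  per_image <- dplyr::bind_rows(per_image)
  scores <- unlist(all_scores)
  labels <- unlist(all_labels)

  froc <- rule1_froc(scored_dets, all_ann, config$cluster)
  ok <- froc$fp_per_image <= 1
  sens_at_1fp <- if (any(ok)) max(froc$sensitivity[ok]) else 0

  metrics <- tibble::tibble(
    pixel_roc_auc = score_auc(scores, labels),
    point_sensitivity = sum(per_image$tp) /
      (sum(per_image$tp) + sum(per_image$fn)),
    point_precision = sum(per_image$tp) /
      max(1, sum(per_image$tp) + sum(per_image$fp)),
    cluster_sensitivity = sum(per_image$ann_clusters_hit) /
      sum(per_image$n_clusters),
    fp_clusters_per_image = sum(per_image$clusters_fp) / nrow(per_image),
    cluster_sensitivity_at_1fp = sens_at_1fp,
    candidate_fraction = sum(per_image$flagged_pixels) /
      sum(per_image$mask_pixels)
  )
  list(metrics = metrics, per_image = per_image, models = models,
       detections = dplyr::bind_rows(all_dets),
       clusters = dplyr::bind_rows(all_clusters),
       annotations = dplyr::bind_rows(all_ann),
       froc = froc)
}

#' FROC sweep of the pairwise cluster rule over the detection threshold
#'
#' The cluster-detection operating point is set by the threshold on the
#' stage-2 probability of the individual detections. For each threshold,
#' detections at or above it are grouped with [clusters_rule1()] per image
#' and matched against the annotations; sensitivity and false positive
#' clusters per image trace the free-response curve.
#'
#' @param detections_list List of per-image scored detection tibbles
#'   (stage-2 scores attached, unthresholded).
#' @param annotations_list List of per-image cluster annotation tibbles
#'   (same order; empty tibbles for images without clusters).
#' @param cluster_config A [cluster_rule_config()].
#' @param thresholds Detection-score thresholds to sweep.
#' @return Tibble `threshold, tp, fp, fn, sensitivity, fp_per_image`.
#' @export
rule1_froc <- function(detections_list, annotations_list, cluster_config,
                       thresholds = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(length(detections_list) == length(annotations_list))
  n_images <- length(detections_list)
  total_ann <- sum(vapply(annotations_list, nrow, integer(1)))
  if (total_ann == 0) {
    stop("no annotated clusters: sensitivity undefined", call. = FALSE)
  }
  rows <- purrr::map(sort(thresholds, decreasing = TRUE), function(th) {
    tp <- fp <- 0L
    for (i in seq_len(n_images)) {
      d <- detections_list[[i]]
      cl <- clusters_rule1(d[d$score >= th, , drop = FALSE], cluster_config)
      ann <- annotations_list[[i]]
      if (nrow(cl) > 0) {
        hit <- vapply(seq_len(nrow(cl)), function(k) {
          match_cluster(c(cl$center_row[k], cl$center_col[k]), ann)
        }, logical(1))
        fp <- fp + sum(!hit)
      }
      if (nrow(ann) > 0 && nrow(cl) > 0) {
        covered <- vapply(seq_len(nrow(ann)), function(j) {
          any(vapply(seq_len(nrow(cl)), function(k) {
            match_cluster(c(cl$center_row[k], cl$center_col[k]),
                          ann[j, , drop = FALSE])
          }, logical(1)))
        }, logical(1))
        tp <- tp + sum(covered)
      }
    }
    tibble::tibble(threshold = th, tp = tp, fp = fp, fn = total_ann - tp,
                   sensitivity = tp / total_ann,
                   fp_per_image = fp / n_images)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mc_curve", class(out))
  attr(out, "curve_type") <- "froc"
  out
}
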