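#' Match detections to ground-truth points
#'
#' Greedy one-to-one matching by ascending detection-truth distance: a
#' detection within `tolerance_px` of a still-unmatched truth point is a
#' true positive; leftover detections are false positives and leftover
#' truth points false negatives. With `one_to_one = FALSE` every detection
#' within tolerance of any truth point is a TP and a truth point is covered
#' if any detection is near it.
#'
#' @param detections Tibble with 0-based `row`, `col` (single image).
#' @param truth Tibble with 0-based `row`, `col` of true points.
#' @param tolerance_px Match radius in pixels.
#' @param one_to_one Enforce one detection per truth point.
#' @return List with counts `tp`, `fp`, `fn` and `matched`, a tibble of
#'   matched (detection, truth) index pairs.
#' @export
match_points <- function(detections, truth, tolerance_px = 5,
                         one_to_one = TRUE) {
  stopifnot(tolerance_px >= 0)
  nd <- nrow(detections)
  nt <- nrow(truth)
  if (nd == 0 || nt == 0) {
    return(list(tp = 0L, fp = nd, fn = nt,
                matched = tibble::tibble(detection = integer(),
                                         truth = integer())))
  }
  d2 <- outer(detections$row, truth$row, "-")^2 +
    outer(detections$col, truth$col, "-")^2
  within <- which(d2 <= tolerance_px^2, arr.ind = TRUE)
  if (!one_to_one) {
    tp_det <- unique(within[, 1])
    covered <- unique(within[, 2])
    return(list(tp = length(tp_det), fp = nd - length(tp_det),
                fn = nt - length(covered),
                matched = tibble::tibble(detection = within[, 1],
                                         truth = within[, 2])))
  }
  ord <- order(d2[within])
  inside <- within[ord, , drop = FALSE]
  dimnames(inside) <- NULL
  det_used <- logical(nd)
  tru_used <- logical(nt)
  md <- integer(0)
  mt <- integer(0)
  for (k in seq_len(nrow(inside))) {
    i <- inside[k, 1]
    j <- inside[k, 2]
    if (det_used[i] || tru_used[j]) next
    det_used[i] <- TRUE
    tru_used[j] <- TRUE
    md <- c(md, i)
    mt <- c(mt, j)
  }
  list(tp = length(md), fp = nd - length(md), fn = nt - length(md),
       matched = tibble::tibble(detection = md, truth = mt))
}

match_counts_at_threshold <- function(detections, truth, threshold,
                                      tolerance_px, one_to_one) {
  kept <- detections[detections$score >= threshold, , drop = FALSE]
  ids <- union(unique(kept$image_id), unique(truth$image_id))
  tp <- fp <- fn <- 0L
  for (id in ids) {
    m <- match_points(kept[kept$image_id == id, , drop = FALSE],
                      truth[truth$image_id == id, , drop = FALSE],
                      tolerance_px, one_to_one)
    tp <- tp + m$tp
    fp <- fp + m$fp
    fn <- fn + m$fn
  }
  c(tp = tp, fp = fp, fn = fn)
}

#' ROC curve for individual microcalcification detection
#'
#' For each threshold, detections scoring at least the threshold are
#' matched per image against the truth points; sensitivity is
#' `tp / (tp + fn)` and the false positive rate is `fp / total_negatives`,
#' with `total_negatives` the number of non-microcalcification pixels
#' inside the breast masks.
#'
#' @param detections Scored detection tibble (`image_id, row, col, score`),
#'   possibly several images.
#' @param truth Truth point tibble (`image_id, row, col`).
#' @param total_negatives Count of non-microcalcification pixels (> 0).
#' @param thresholds Score thresholds; default: every distinct score plus
#'   `Inf`.
#' @param tolerance_px Point match radius in pixels.
#' @param one_to_one Matching mode, see [match_points()].
#' @return An `mc_curve` tibble (type `"roc"`), sorted by threshold
#'   descending: `threshold, tp, fp, fn, tn, sensitivity,
#'   one_minus_specificity, precision`.
#' @export
roc_curve <- function(detections, truth, total_negatives,
                      thresholds = NULL, tolerance_px = 5,
                      one_to_one = TRUE) {
  stopifnot(total_negatives > 0)
  if (is.null(thresholds)) {
    thresholds <- c(sort(unique(detections$score)), Inf)
  }
  thresholds <- sort(thresholds, decreasing = TRUE)
  rows <- purrr::map(thresholds, function(th) {
    m <- match_counts_at_threshold(detections, truth, th, tolerance_px,
                                   one_to_one)
    tibble::tibble(
      threshold = th, tp = m[["tp"]], fp = m[["fp"]], fn = m[["fn"]],
      tn = total_negatives - m[["fp"]],
      sensitivity = if (m[["tp"]] + m[["fn"]] > 0)
        m[["tp"]] / (m[["tp"]] + m[["fn"]]) else NA_real_,
      one_minus_specificity = m[["fp"]] / total_negatives,
      precision = if (m[["tp"]] + m[["fp"]] > 0)
        m[["tp"]] / (m[["tp"]] + m[["fp"]]) else NA_real_
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mc_curve", class(out))
  attr(out, "curve_type") <- "roc"
  out
}

#' Precision-recall curve for individual detection
#'
#' As [roc_curve()] but reporting precision `tp / (tp + fp)` against recall
#' (= sensitivity); thresholds that keep no detections are omitted since
#' precision is undefined there.
#'
#' @inheritParams roc_curve
#' @return An `mc_curve` tibble (type `"pr"`).
#' @export
pr_curve <- function(detections, truth, thresholds = NULL,
                     tolerance_px = 5, one_to_one = TRUE) {
  if (is.null(thresholds)) {
    thresholds <- sort(unique(detections$score))
  }
  thresholds <- sort(thresholds, decreasing = TRUE)
  rows <- purrr::map(thresholds, function(th) {
    m <- match_counts_at_threshold(detections, truth, th, tolerance_px,
                                   one_to_one)
    if (m[["tp"]] + m[["fp"]] == 0) return(NULL)
    tibble::tibble(
      threshold = th, tp = m[["tp"]], fp = m[["fp"]], fn = m[["fn"]],
      sensitivity = m[["tp"]] / (m[["tp"]] + m[["fn"]]),
      precision = m[["tp"]] / (m[["tp"]] + m[["fp"]])
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mc_curve", class(out))
  attr(out, "curve_type") <- "pr"
  out
}

#' FROC curve for cluster detection
#'
#' Free-response ROC: per threshold, detected clusters scoring at least the
#' threshold are matched by centre containment against the annotated
#' cluster regions. Sensitivity is the fraction of annotated clusters hit;
#' the x-axis is unmatched detected clusters divided by the number of
#' images (images without annotations contribute false positives only).
#'
#' @param clusters Detected cluster tibble (`image_id, center_row,
#'   center_col, score`).
#' @param annotations Cluster annotation tibble (`image_id, shape, ...`).
#' @param n_images Total number of evaluated images (>= 1), including
#'   annotation-free ones.
#' @param thresholds Score thresholds; default: distinct scores plus `Inf`.
#' @return An `mc_curve` tibble (type `"froc"`): `threshold, tp, fp, fn,
#'   sensitivity, fp_per_image`.
#' @export
froc_curve <- function(clusters, annotations, n_images, thresholds = NULL) {
  stopifnot(n_images >= 1)
  if (nrow(annotations) == 0) {
    stop("no annotated clusters: sensitivity undefined", call. = FALSE)
  }
  if (is.null(thresholds)) {
    thresholds <- c(sort(unique(clusters$score)), Inf)
  }
  thresholds <- sort(thresholds, decreasing = TRUE)
  total_ann <- nrow(annotations)
  rows <- purrr::map(thresholds, function(th) {
    kept <- clusters[clusters$score >= th, , drop = FALSE]
    tp_ann <- 0L
    fp <- 0L
    for (id in unique(c(kept$image_id, annotations$image_id))) {
      k <- kept[kept$image_id == id, , drop = FALSE]
      a <- annotations[annotations$image_id == id, , drop = FALSE]
      if (nrow(k) > 0) {
        hit <- vapply(seq_len(nrow(k)), function(i) {
          match_cluster(c(k$center_row[i], k$center_col[i]), a)
        }, logical(1))
        fp <- fp + sum(!hit)
      }
      if (nrow(a) > 0) {
        covered <- vapply(seq_len(nrow(a)), function(j) {
          aj <- a[j, , drop = FALSE]
          nrow(k) > 0 && any(vapply(seq_len(nrow(k)), function(i) {
            match_cluster(c(k$center_row[i], k$center_col[i]), aj)
          }, logical(1)))
        }, logical(1))
        tp_ann <- tp_ann + sum(covered)
      }
    }
    tibble::tibble(threshold = th, tp = tp_ann, fp = fp,
                   fn = total_ann - tp_ann,
                   sensitivity = tp_ann / total_ann,
                   fp_per_image = fp / n_images)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("mc_curve", class(out))
  attr(out, "curve_type") <- "froc"
  out
}

#' Trapezoidal area under a curve
#'
#' Sorts by x, clips to `[0, x_max]` and integrates by the trapezoid rule,
#' normalised by `x_max` so the result lies in `[0, 1]`. For ROC and
#' precision-recall curves `x_max = 1`; for FROC curves pass the
#' false-positive-per-image cap in use (default: the largest observed x).
#'
#' @param x,y Curve coordinates (>= 2 points), or an `mc_curve` as `x`.
#' @param x_max Upper integration limit.
#' @return Area in `[0, 1]`.
#' @export
curve_auc <- function(x, y = NULL, x_max = NULL) {
  if (inherits(x, "mc_curve")) {
    type <- attr(x, "curve_type")
    if (type == "roc") {
      y <- x$sensitivity
      x <- x$one_minus_specificity
      x_max <- x_max %||% 1
    } else if (type == "pr") {
      y <- x$precision
      x <- x$sensitivity
      x_max <- x_max %||% 1
    } else {
      y <- x$sensitivity
      x <- x$fp_per_image
      x_max <- x_max %||% max(x)
    }
  }
  stopifnot(length(x) == length(y), length(x) >= 2)
  x_max <- x_max %||% max(x)
  ord <- order(x)
  x <- pmin(pmax(x[ord], 0), x_max)
  y <- y[ord]
  sum(diff(x) * (head(y, -1) + y[-1]) / 2) / x_max
}

#' Rank-based (Wilcoxon) ROC AUC of a scorer
#'
#' Probability that a random positive outscores a random negative, with the
#' half-credit tie convention; identical to the area under the full
#' empirical ROC curve over pixels.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels (1 = positive).
#' @return AUC in `[0, 1]`.
#' @export
score_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- as.numeric(sum(labels))
  n0 <- as.numeric(sum(!labels))
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified image-level cross-validation folds
#'
#' Images (never pixels) are partitioned into `k` folds; images with and
#' without microcalcifications are each spread uniformly across folds so
#' every test fold sees both kinds.
#'
#' @param image_ids Character vector of image identifiers.
#' @param has_mc Logical, per image.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Tibble `image_id, has_mc, fold`.
#' @export
cv_folds <- function(image_ids, has_mc, k = 10L, seed = 1L) {
  stopifnot(length(image_ids) == length(has_mc), k >= 2,
            !anyDuplicated(image_ids))
  set.seed(seed)
  fold <- integer(length(image_ids))
  for (grp in c(TRUE, FALSE)) {
    idx <- which(has_mc == grp)
    if (length(idx) == 0) next
    fold[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(k), length(idx))
  }
  tibble::tibble(image_id = image_ids, has_mc = has_mc, fold = fold)
}
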