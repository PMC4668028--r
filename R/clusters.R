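#' Convert a physical length to pixels
#'
#' `length_mm / spacing_mm`, rounded to the nearest integer when used as a
#' window side. At the three spacings of the public mammogram archives
#' (0.1, 0.05 and 0.2 mm/pixel) a 1 cm side maps to 100, 200 and 50 pixels.
#'
#' @param length_mm Physical length in mm.
#' @param spacing_mm Pixel spacing in mm/pixel.
#' @param round Round to the nearest integer (default) or return the exact
#'   value.
#' @return Length in pixels.
#' @export
mm_to_px <- function(length_mm, spacing_mm, round = TRUE) {
  stopifnot(spacing_mm > 0)
  v <- length_mm / spacing_mm
  if (round) round(v) else v
}

#' Cluster grouping rule config
#'
#' Defaults are the classical values: a cluster is at least three
#' microcalcifications with pairwise distances within `d_c1 = 4` mm inside a
#' localized region of `A_c1 = 1` cm²; the cumulative-probability rule
#' accumulates over an `A_c2 = 1` cm² window.
#'
#' @param d_c1_mm Pairwise distance bound (mm) for the grouping rule.
#' @param a_c1_mm2 Localized-region area (mm²) for the grouping rule.
#' @param a_c2_mm2 Accumulation-window area (mm²) for the cumulative rule.
#' @param p_c_threshold Threshold on the cumulative local probability.
#' @param spacing_mm Pixel spacing in mm/pixel.
#' @return A `cluster_rule_config` list.
#' @export
cluster_rule_config <- function(d_c1_mm = 4, a_c1_mm2 = 100,
                                a_c2_mm2 = 100, p_c_threshold = 1.0,
                                spacing_mm = 0.1) {
  stopifnot(d_c1_mm > 0, a_c1_mm2 > 0, a_c2_mm2 > 0, p_c_threshold >= 0,
            spacing_mm > 0)
  structure(list(d_c1_mm = d_c1_mm, a_c1_mm2 = a_c1_mm2,
                 a_c2_mm2 = a_c2_mm2, p_c_threshold = p_c_threshold,
                 spacing_mm = spacing_mm),
            class = "cluster_rule_config")
}

empty_cluster_tibble <- function() {
  tibble::tibble(image_id = character(), rule = character(),
                 center_row = integer(), center_col = integer(),
                 row_min = integer(), col_min = integer(),
                 row_max = integer(), col_max = integer(),
                 score = numeric(), n_members = integer(),
                 members = list())
}

#' Pairwise-distance cluster rule
#'
#' For each detection, a candidate cluster is grown from its
#' `d_c1`-neighbourhood by adding members in order of distance from the
#' seed, keeping a member only when it stays within `d_c1` (in mm) of every
#' member already in — so every emitted cluster satisfies the rule's
#' premise that all pairwise member distances are within `d_c1`. Candidates
#' with at least 3 members that fit inside a square of area `A_c1` centred
#' at their centroid are then resolved greedily: keep the candidate with
#' most members (ties to the smallest seed `(row, col)`), drop candidates
#' sharing members with it, repeat. Emitted clusters are member-disjoint.
#'
#' @param detections Detection tibble (0-based `row`, `col`; optional
#'   `image_id`).
#' @param config A [cluster_rule_config()] (supplies `spacing_mm`).
#' @return Cluster tibble: `image_id, rule, center_row, center_col, row_min,
#'   col_min, row_max, col_max, score, n_members, members` where `score` is
#'   the member count, center the rounded member centroid and the box the
#'   tight member box; `members` is a list-column of member index vectors
#'   into `detections`.
#' @export
clusters_rule1 <- function(detections, config) {
  stopifnot(inherits(config, "cluster_rule_config"))
  n <- nrow(detections)
  if (n < 3) return(empty_cluster_tibble())
  image_id <- if ("image_id" %in% names(detections) && n > 0) {
    detections$image_id[1]
  } else "image"
  r <- detections$row
  c <- detections$col
  dmat <- as.matrix(stats::dist(cbind(r, c))) * config$spacing_mm
  half_side <- sqrt(config$a_c1_mm2) / 2

  candidates <- list()
  for (seed in seq_len(n)) {
    nb <- which(dmat[seed, ] <= config$d_c1_mm)
    nb <- nb[order(dmat[seed, nb], nb)]
    members <- integer(0)
    for (q in nb) {
      if (length(members) == 0 ||
          all(dmat[q, members] <= config$d_c1_mm)) {
        members <- c(members, q)
      }
    }
    if (length(members) < 3) next
    cr <- mean(r[members])
    cc <- mean(c[members])
    if (any(abs(r[members] - cr) * config$spacing_mm > half_side) ||
        any(abs(c[members] - cc) * config$spacing_mm > half_side)) next
    candidates[[length(candidates) + 1]] <-
      list(seed = seed, members = sort(members))
  }
  if (length(candidates) == 0) return(empty_cluster_tibble())

  sizes <- vapply(candidates, function(x) length(x$members), integer(1))
  ord <- order(-sizes, r[vapply(candidates, `[[`, integer(1), "seed")],
               c[vapply(candidates, `[[`, integer(1), "seed")])
  kept <- list()
  used <- logical(n)
  for (i in ord) {
    m <- candidates[[i]]$members
    if (any(used[m])) next
    used[m] <- TRUE
    kept[[length(kept) + 1]] <- m
  }

  dplyr::bind_rows(purrr::map(kept, function(m) {
    tibble::tibble(
      image_id = image_id, rule = "pairwise",
      center_row = as.integer(round(mean(r[m]))),
      center_col = as.integer(round(mean(c[m]))),
      row_min = min(r[m]), col_min = min(c[m]),
      row_max = max(r[m]), col_max = max(c[m]),
      score = length(m), n_members = length(m), members = list(m)
    )
  }))
}

#' Cumulative local probability map (box sum)
#'
#' The cumulative local probability at a pixel is the sum of individual
#' detection probabilities over the `window_side_px` square window centred
#' there (zero-padded at borders), computed exactly with an integral image.
#' The map is linear in the input scores.
#'
#' @param prob_map Numeric matrix of per-pixel individual probabilities
#'   (typically sparse: detection scores at detection coordinates, zero
#'   elsewhere — see [detections_to_prob_map()]).
#' @param window_side_px Odd window side in pixels.
#' @return Numeric matrix of the same shape.
#' @export
cumulative_probability_map <- function(prob_map, window_side_px) {
  stopifnot(window_side_px >= 1, window_side_px %% 2 == 1)
  half <- (window_side_px - 1) / 2
  nr <- nrow(prob_map)
  nc <- ncol(prob_map)
  padded <- matrix(0, nr + 2 * half, nc + 2 * half)
  padded[half + seq_len(nr), half + seq_len(nc)] <- prob_map
  ii <- apply(apply(padded, 2, cumsum), 1, cumsum)  # transposed integral
  ii <- rbind(0, cbind(0, t(ii)))
  w <- window_side_px
  r1 <- seq_len(nr)
  c1 <- seq_len(nc)
  ii[r1 + w, c1 + w, drop = FALSE] - ii[r1, c1 + w, drop = FALSE] -
    ii[r1 + w, c1, drop = FALSE] + ii[r1, c1, drop = FALSE]
}

#' Sparse individual-probability map from detections
#'
#' @param detections Detection tibble with `row`, `col`, `score`.
#' @param shape `(rows, cols)` of the image.
#' @return Numeric matrix: each detection's score at its coordinate, zero
#'   elsewhere (coincident detections sum).
#' @export
detections_to_prob_map <- function(detections, shape) {
  m <- matrix(0, shape[1], shape[2])
  for (i in seq_len(nrow(detections))) {
    m[detections$row[i] + 1, detections$col[i] + 1] <-
      m[detections$row[i] + 1, detections$col[i] + 1] + detections$score[i]
  }
  m
}

#' Cumulative-probability cluster rule
#'
#' Thresholds the cumulative local probability map at `p_c_threshold`;
#' 8-connected components of supra-threshold window centres become
#' clusters. A cluster's bounding box is the union of its member pixels'
#' window extents (clipped to the image), its centre the component
#' centroid, and its score the maximum cumulative probability inside.
#'
#' @param prob_map Sparse individual-probability matrix.
#' @param config A [cluster_rule_config()] (`a_c2_mm2`, `p_c_threshold`,
#'   `spacing_mm`).
#' @param image_id Identifier for the output rows.
#' @return Cluster tibble in the same shape as [clusters_rule1()]
#'   (`members` holds the component pixels as a tibble).
#' @export
clusters_rule2 <- function(prob_map, config, image_id = "image") {
  stopifnot(inherits(config, "cluster_rule_config"))
  side <- mm_to_px(sqrt(config$a_c2_mm2), config$spacing_mm)
  if (side %% 2 == 0) side <- side + 1
  half <- (side - 1) / 2
  pc <- cumulative_probability_map(prob_map, side)
  bin <- pc >= config$p_c_threshold
  comps <- connected_components(bin)
  if (length(comps) == 0) return(empty_cluster_tibble())
  dplyr::bind_rows(purrr::map(comps, function(p) {
    tibble::tibble(
      image_id = image_id, rule = "cumulative",
      center_row = as.integer(round(mean(p$row))),
      center_col = as.integer(round(mean(p$col))),
      row_min = max(0L, min(p$row) - half),
      col_min = max(0L, min(p$col) - half),
      row_max = min(nrow(prob_map) - 1L, max(p$row) + half),
      col_max = min(ncol(prob_map) - 1L, max(p$col) + half),
      score = max(pc[cbind(p$row + 1, p$col + 1)]),
      n_members = nrow(p), members = list(p)
    )
  }))
}

#' Does a detected cluster centre hit an annotated cluster?
#'
#' True when the centre lies inside any annotated box or circle, with
#' inclusive boundaries (a centre exactly on a box edge or at exactly the
#' circle radius counts).
#'
#' @param center 0-based `(row, col)` of the detected cluster centre.
#' @param annotations Cluster annotation tibble ([read_mc_clusters()]
#'   dialect).
#' @return Logical scalar.
#' @export
match_cluster <- function(center, annotations) {
  if (nrow(annotations) == 0) return(FALSE)
  box <- annotations$shape == "box"
  hit_box <- box &
    center[1] >= annotations$row_a & center[1] <= annotations$row_b &
    center[2] >= annotations$col_a & center[2] <= annotations$col_b
  hit_circ <- !box &
    sqrt((center[1] - annotations$row_a)^2 +
           (center[2] - annotations$col_a)^2) <= annotations$row_b
  any(hit_box | hit_circ)
}
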