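#' 8-connected components of a binary map
#'
#' @param map Logical matrix.
#' @return List of tibbles (0-based `row`, `col`), one per component, in
#'   row-major scan order of first encounter; diagonal neighbours connect.
#' @export
connected_components <- function(map) {
  stopifnot(is.matrix(map))
  lab <- rcpp_label_components(map)
  n <- max(lab)
  if (n == 0) return(list())
  idx <- which(lab > 0)
  nr <- nrow(map)
  df <- data.frame(lab = lab[idx],
                   row = (idx - 1) %% nr, col = (idx - 1) %/% nr)
  lapply(split(df[c("row", "col")], df$lab), tibble::as_tibble)
}

#' Non-maximum suppression peak of a component
#'
#' Reduces a connected component of flagged pixels to the single pixel
#' whose local window has the maximum zero-normalised cross-correlation
#' with a 2-D Gaussian template of standard deviation `nms_sigma_px`
#' (window side `2 * ceiling(3 * sigma) + 1`, reflect-padded at borders).
#' Ties break to the lexicographically smallest `(row, col)`; a window with
#' zero intensity variance scores `-Inf` and is only chosen if every window
#' does.
#'
#' @param image A [mammogram_image()].
#' @param pixels Tibble/data frame of the component's 0-based `row`, `col`.
#' @param nms_sigma_px Gaussian template standard deviation in pixels.
#' @return 0-based `(row, col)` of the peak.
#' @export
nms_peak <- function(image, pixels, nms_sigma_px) {
  stopifnot(nrow(pixels) > 0, nms_sigma_px > 0)
  half <- ceiling(3 * nms_sigma_px)
  u <- -half:half
  tmpl <- exp(-outer(u^2, u^2, "+") / (2 * nms_sigma_px^2))
  tmpl <- tmpl - mean(tmpl)
  tmpl_norm <- sqrt(sum(tmpl^2))
  px <- image$pixels
  ord <- order(pixels$row, pixels$col)
  best <- -Inf
  best_i <- ord[1]
  for (i in ord) {
    ri <- reflect_clip(pixels$row[i] + u, nrow(px))
    ci <- reflect_clip(pixels$col[i] + u, ncol(px))
    win <- px[ri, ci]
    win <- win - mean(win)
    wn <- sqrt(sum(win^2))
    ncc <- if (wn == 0) -Inf else sum(win * tmpl) / (wn * tmpl_norm)
    if (ncc > best) {  # strict: earlier (lexicographic) pixel wins ties
      best <- ncc
      best_i <- i
    }
  }
  c(pixels$row[best_i], pixels$col[best_i])
}

#' Full-image cascaded microcalcification detection
#'
#' Runs the whole chain on one image: breast segmentation, multi-scale
#' Hessian feature map, random-forest posterior thresholded at
#' `theta_rf`, 8-connected grouping of flagged pixels, one NMS peak per
#' component, and DRBM patch classification of the peaks at `theta_drbm`.
#' Deterministic given the models and config.
#'
#' @param image A [mammogram_image()].
#' @param forest A trained `mc_rf`.
#' @param drbm A trained `mc_drbm`.
#' @param config A pipeline config from [preset_config()] / [load_config()].
#' @param mask Optional precomputed `breast_mask` (skips segmentation).
#' @param image_id Identifier for the detection records.
#' @return An `mc_detection`: list with `detections` (final tibble),
#'   `candidates` (NMS peaks tibble with RF component sizes), `mask`,
#'   `rf_prob` (posterior matrix), `flagged` (logical matrix) and `counts`
#'   (per-stage tibble: flagged pixels >= components = candidates >= final).
#' @export
detect_mc <- function(image, forest, drbm, config, mask = NULL,
                      image_id = "image") {
  stopifnot(inherits(image, "mammogram"))
  if (forest$feature_length != 4 * length(config$scales)) {
    stop("forest feature length does not match config scales", call. = FALSE)
  }
  if (drbm$n_visible != config$patch_side^2) {
    stop("DRBM visible size does not match config patch_side", call. = FALSE)
  }
  if (is.null(mask)) {
    mask <- segment_breast(image, config$n_bins, config$n_examine,
                           config$dilate_radius_px)
  }
  fmap <- feature_map(image, mask, config$scales)
  rf_prob <- rf_posterior_map(forest, fmap)
  flagged <- classify_candidates(forest, fmap, config$theta_rf)
  comps <- connected_components(flagged)
  if (length(comps) > 0) {
    peaks <- t(vapply(comps, function(p) {
      nms_peak(image, p, config$nms_sigma_px)
    }, numeric(2)))
    candidates <- tibble::tibble(
      row = as.integer(peaks[, 1]), col = as.integer(peaks[, 2]),
      component_size = vapply(comps, nrow, integer(1)),
      rf_score = rf_prob[peaks + 1]
    )
  } else {
    candidates <- tibble::tibble(row = integer(), col = integer(),
                                 component_size = integer(),
                                 rf_score = numeric())
  }
  detections <- classify_patches(drbm, candidates, image, config$theta_drbm,
                                 config$patch_side, image_id = image_id)
  counts <- tibble::tibble(
    stage = c("flagged_pixels", "components", "candidates", "final"),
    count = c(sum(flagged), length(comps), nrow(candidates),
              nrow(detections))
  )
  structure(
    list(detections = detections, candidates = candidates, mask = mask,
         rf_prob = rf_prob, flagged = flagged, counts = counts,
         image_id = image_id),
    class = "mc_detection"
  )
}

#' @export
print.mc_detection <- function(x, ...) {
  cat(sprintf("<mc_detection> %s: %s\n", x$image_id,
              paste(sprintf("%s=%d", x$counts$stage, x$counts$count),
                    collapse = ", ")))
  invisible(x)
}
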