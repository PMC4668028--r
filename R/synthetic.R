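#' Specify a synthetic mammogram phantom
#'
#' Describes a mammogram-like test image: a bright breast region (half-ellipse
#' against near-zero empty space, as in a processed mammogram), spatially
#' correlated tissue texture, sub-millimetre Gaussian-bump
#' microcalcifications — a stated fraction grouped into compact clusters —
#' bright tubular (vessel-like) ridge distractors, and additive noise.
#'
#' Defaults emulate a digitised film mammogram at 0.2 mm/pixel: a 512 x 512
#' frame covers roughly 10 x 10 cm of tissue, microcalcifications have
#' Gaussian radii 0.8-1.6 px (0.16-0.32 mm) and clusters collect >= 3 of them
#' within a 2 mm radius, so that every planted cluster satisfies the
#' pairwise-distance premise of the 4 mm grouping rule.
#'
#' @param image_shape `(rows, cols)` of the image.
#' @param spacing_mm Pixel spacing in mm/pixel.
#' @param breast_mask_shape `"half-ellipse"` (breast against the left edge)
#'   or `"full"` (whole frame is tissue).
#' @param base_level,tissue_amp,tissue_corr_len_px Background model: mean
#'   tissue intensity, the standard deviation of the smoothed tissue texture,
#'   and its correlation length in pixels.
#' @param mc_count Number of planted microcalcifications.
#' @param mc_amplitude_range,mc_sigma_px_range Uniform ranges for bump peak
#'   amplitude (intensity units) and Gaussian radius (pixels).
#' @param cluster_fraction Fraction of microcalcifications placed in
#'   clusters; the rest are isolated.
#' @param cluster_radius_mm Cluster members are placed within this distance
#'   of their cluster centre (so pairwise member distances stay below twice
#'   this value).
#' @param cluster_min_size Minimum members per planted cluster (>= 3).
#' @param ridge_count,ridge_amp,ridge_sigma_px Tubular distractors: count,
#'   peak amplitude and Gaussian cross-section radius.
#' @param noise_sd Additive Gaussian pixel noise inside the breast.
#' @param bit_depth Image bit depth.
#' @param seed Integer seed; the whole phantom is a deterministic function
#'   of the spec including this seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(image_shape = c(512L, 512L),
                         spacing_mm = 0.2,
                         breast_mask_shape = c("half-ellipse", "full"),
                         base_level = 60,
                         tissue_amp = 10,
                         tissue_corr_len_px = 6,
                         mc_count = 50L,
                         mc_amplitude_range = c(40, 90),
                         mc_sigma_px_range = c(0.8, 1.6),
                         cluster_fraction = 0.6,
                         cluster_radius_mm = 2,
                         cluster_min_size = 3L,
                         ridge_count = 3L,
                         ridge_amp = 25,
                         ridge_sigma_px = 2,
                         noise_sd = 5,
                         bit_depth = 8L,
                         seed = 1L) {
  breast_mask_shape <- match.arg(breast_mask_shape)
  stopifnot(
    length(image_shape) == 2, all(image_shape >= 32),
    spacing_mm > 0, tissue_corr_len_px > 0,
    mc_count >= 0, diff(mc_amplitude_range) >= 0,
    all(mc_sigma_px_range > 0), diff(mc_sigma_px_range) >= 0,
    cluster_fraction >= 0, cluster_fraction <= 1,
    cluster_radius_mm > 0, cluster_min_size >= 3,
    ridge_count >= 0, noise_sd >= 0
  )
  max_int <- 2^bit_depth - 1
  if (base_level + 3 * tissue_amp + max(mc_amplitude_range) + ridge_amp >
      2 * max_int) {
    stop("amplitudes far exceed bit depth; phantom would be all-clipped",
         call. = FALSE)
  }
  spec <- as.list(environment())
  structure(spec, class = "phantom_spec")
}

#' Generate a synthetic mammogram phantom with ground truth
#'
#' Deterministic given the spec (including its seed). Microcalcifications are
#' isotropic Gaussian bumps added to a smoothed-noise tissue background
#' inside the breast mask; pixels outside the mask are set to a near-zero
#' level emulating the empty space that surrounds the breast in a real
#' mammogram. Cluster members lie within `cluster_radius_mm` of their
#' cluster centre; isolated microcalcifications keep a minimum separation of
#' `3 * max(mc_sigma_px_range)` pixels from every other microcalcification.
#'
#' @param spec A [phantom_spec()].
#' @param image_id Identifier attached to the annotations.
#' @return A `phantom`: list with `image` ([mammogram_image()]), `mc_points`
#'   (tibble `image_id,row,col` plus the per-bump `amplitude`, `sigma_px` and
#'   `cluster` id used to render it), `clusters` (box annotations in the
#'   [read_mc_clusters()] dialect), `breast_mask` (logical matrix) and
#'   `spec`.
#' @export
generate_phantom <- function(spec, image_id = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(image_id)) image_id <- paste0("phantom_", spec$seed)
  set.seed(spec$seed)
  nr <- spec$image_shape[1]
  nc <- spec$image_shape[2]
  max_int <- 2^spec$bit_depth - 1

  mask <- make_breast_mask(nr, nc, spec$breast_mask_shape)

  # tissue: white noise smoothed to the stated correlation length, then
  # standardised inside the mask and scaled
  tissue <- matrix(0, nr, nc)
  if (spec$tissue_amp > 0) {
    wn <- matrix(rnorm(nr * nc), nr, nc)
    g <- gaussian_kernel(spec$tissue_corr_len_px, 0L)
    sm <- conv_sep(wn, g, g)
    tissue <- (sm - mean(sm[mask])) / stats::sd(sm[mask]) * spec$tissue_amp
  }

  ridges <- matrix(0, nr, nc)
  if (spec$ridge_count > 0) {
    rows <- matrix(seq_len(nr) - 1, nr, nc)
    cols <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
    in_idx <- which(mask)
    for (i in seq_len(spec$ridge_count)) {
      p0 <- in_idx[sample.int(length(in_idx), 1)]
      r0 <- (p0 - 1) %% nr
      c0 <- (p0 - 1) %/% nr
      th <- runif(1, 0, pi)
      d <- abs(-sin(th) * (rows - r0) + cos(th) * (cols - c0))
      ridges <- ridges + spec$ridge_amp * exp(-d^2 / (2 * spec$ridge_sigma_px^2))
    }
  }

  placement <- place_mc_points(spec, mask)
  pts <- placement$points

  bumps <- matrix(0, nr, nc)
  if (nrow(pts) > 0) {
    for (i in seq_len(nrow(pts))) {
      bumps <- add_gaussian_bump(bumps, c(pts$row[i], pts$col[i]),
                                 pts$amplitude[i], pts$sigma_px[i])
    }
  }

  noise <- if (spec$noise_sd > 0) {
    matrix(rnorm(nr * nc, sd = spec$noise_sd), nr, nc)
  } else {
    matrix(0, nr, nc)
  }

  img <- matrix(2, nr, nc)  # near-zero empty space
  inside <- spec$base_level + tissue + ridges + bumps + noise
  img[mask] <- pmin(pmax(inside[mask], 0), max_int)

  mc_points <- tibble::tibble(
    image_id = rep(image_id, nrow(pts)),
    row = pts$row, col = pts$col,
    amplitude = pts$amplitude, sigma_px = pts$sigma_px,
    cluster = pts$cluster
  )

  clusters <- cluster_boxes(pts, image_id, nr, nc)

  structure(
    list(image = mammogram_image(img, spec$spacing_mm, spec$bit_depth),
         mc_points = mc_points, clusters = clusters,
         breast_mask = mask, spec = spec, image_id = image_id),
    class = "phantom"
  )
}

make_breast_mask <- function(nr, nc, shape) {
  if (shape == "full") return(matrix(TRUE, nr, nc))
  r0 <- (nr - 1) / 2
  a <- 0.46 * nr
  b <- 0.90 * nc
  rows <- matrix(seq_len(nr) - 1, nr, nc)
  cols <- matrix(seq_len(nc) - 1, nr, nc, byrow = TRUE)
  ((rows - r0) / a)^2 + (cols / b)^2 <= 1
}

add_gaussian_bump <- function(m, center, amplitude, sigma_px) {
  r <- ceiling(4 * sigma_px)
  rr <- max(0, center[1] - r):min(nrow(m) - 1, center[1] + r)
  cc <- max(0, center[2] - r):min(ncol(m) - 1, center[2] + r)
  d2 <- outer((rr - center[1])^2, (cc - center[2])^2, "+")
  m[rr + 1, cc + 1] <- m[rr + 1, cc + 1] +
    amplitude * exp(-d2 / (2 * sigma_px^2))
  m
}

place_mc_points <- function(spec, mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  empty <- data.frame(row = integer(), col = integer(),
                      amplitude = numeric(), sigma_px = numeric(),
                      cluster = integer())
  if (spec$mc_count == 0) return(list(points = empty))

  in_idx <- which(mask)
  if (length(in_idx) == 0) stop("breast mask is empty", call. = FALSE)
  radius_px <- spec$cluster_radius_mm / spec$spacing_mm
  min_sep <- 3 * max(spec$mc_sigma_px_range)

  n_clustered <- round(spec$mc_count * spec$cluster_fraction)
  sizes <- integer(0)
  rem <- n_clustered
  while (rem >= spec$cluster_min_size) {
    s <- min(rem, spec$cluster_min_size + sample.int(3L, 1) - 1L)
    if (rem - s > 0 && rem - s < spec$cluster_min_size) s <- rem
    sizes <- c(sizes, s)
    rem <- rem - s
  }
  n_single <- spec$mc_count - sum(sizes)

  pts <- empty
  draw_mc <- function(row, col, cluster) {
    data.frame(row = row, col = col,
               amplitude = runif(1, spec$mc_amplitude_range[1],
                                 spec$mc_amplitude_range[2]),
               sigma_px = runif(1, spec$mc_sigma_px_range[1],
                                spec$mc_sigma_px_range[2]),
               cluster = cluster)
  }
  centers <- matrix(numeric(0), ncol = 2)
  for (ci in seq_along(sizes)) {
    placed_center <- FALSE
    for (try in seq_len(500)) {
      p0 <- in_idx[sample.int(length(in_idx), 1)]
      r0 <- (p0 - 1) %% nr
      c0 <- (p0 - 1) %/% nr
      # the cluster disk must fit in the mask (checked on its bounding circle)
      probe_r <- round(r0 + radius_px * sin(seq(0, 2 * pi, length.out = 9)))
      probe_c <- round(c0 + radius_px * cos(seq(0, 2 * pi, length.out = 9)))
      if (any(probe_r < 0 | probe_r >= nr | probe_c < 0 | probe_c >= nc)) next
      if (!all(mask[cbind(probe_r + 1, probe_c + 1)])) next
      if (nrow(centers) > 0 &&
          min(sqrt((centers[, 1] - r0)^2 + (centers[, 2] - c0)^2)) <
            4 * radius_px) next
      placed_center <- TRUE
      break
    }
    if (!placed_center) stop("phantom placement failed (cluster centres)",
                             call. = FALSE)
    centers <- rbind(centers, c(r0, c0))
    n_members <- 0
    for (try in seq_len(1000)) {
      if (n_members == sizes[ci]) break
      rad <- radius_px * sqrt(runif(1))
      ang <- runif(1, 0, 2 * pi)
      r <- round(r0 + rad * sin(ang))
      c <- round(c0 + rad * cos(ang))
      if (r < 0 || r >= nr || c < 0 || c >= nc || !mask[r + 1, c + 1]) next
      if (nrow(pts) > 0 && any((pts$row - r)^2 + (pts$col - c)^2 < 4)) next
      pts <- rbind(pts, draw_mc(r, c, ci))
      n_members <- n_members + 1
    }
    if (n_members < sizes[ci]) stop("phantom placement failed (members)",
                                    call. = FALSE)
  }

  for (si in seq_len(n_single)) {
    placed <- FALSE
    for (try in seq_len(500)) {
      p0 <- in_idx[sample.int(length(in_idx), 1)]
      r <- (p0 - 1) %% nr
      c <- (p0 - 1) %/% nr
      if (nrow(pts) > 0 &&
          min(sqrt((pts$row - r)^2 + (pts$col - c)^2)) < min_sep) next
      pts <- rbind(pts, draw_mc(r, c, NA_integer_))
      placed <- TRUE
      break
    }
    if (!placed) stop("phantom placement failed (isolated points)",
                      call. = FALSE)
  }
  list(points = pts)
}

cluster_boxes <- function(pts, image_id, nr, nc, pad = 3) {
  ids <- sort(unique(pts$cluster[!is.na(pts$cluster)]))
  if (length(ids) == 0) {
    return(tibble::tibble(image_id = character(), shape = character(),
                          row_a = numeric(), col_a = numeric(),
                          row_b = numeric(), col_b = numeric()))
  }
  rows <- purrr::map(ids, function(ci) {
    m <- pts[!is.na(pts$cluster) & pts$cluster == ci, ]
    tibble::tibble(image_id = image_id, shape = "box",
                   row_a = max(0, min(m$row) - pad),
                   col_a = max(0, min(m$col) - pad),
                   row_b = min(nr - 1, max(m$row) + pad),
                   col_b = min(nc - 1, max(m$col) + pad))
  })
  dplyr::bind_rows(rows)
}

#' Analytic Gaussian blob image
#'
#' `I(p) = amplitude * exp(-||p - center||^2 / (2 sigma_px^2))` on a zero
#' background, without clipping — the analytic input used to check the
#' Hessian filters against closed forms.
#'
#' @param shape `(rows, cols)`.
#' @param center 0-based `(row, col)` of the blob centre.
#' @param amplitude Peak value.
#' @param sigma_px Gaussian radius in pixels.
#' @param spacing_mm Pixel spacing to attach.
#' @return A [mammogram_image()] (16-bit container).
#' @export
ideal_blob_image <- function(shape, center, amplitude, sigma_px,
                             spacing_mm = 0.1) {
  stopifnot(sigma_px > 0)
  d2 <- outer((seq_len(shape[1]) - 1 - center[1])^2,
              (seq_len(shape[2]) - 1 - center[2])^2, "+")
  mammogram_image(amplitude * exp(-d2 / (2 * sigma_px^2)), spacing_mm,
                  bit_depth = 16L)
}

#' Analytic Gaussian-profile ridge image
#'
#' A bright tubular structure: constant along one axis, Gaussian across it.
#'
#' @param shape `(rows, cols)`.
#' @param position 0-based index of the ridge crest (column for a vertical
#'   ridge, row for a horizontal one).
#' @param orientation `"vertical"` or `"horizontal"`.
#' @inheritParams ideal_blob_image
#' @return A [mammogram_image()] (16-bit container).
#' @export
ideal_ridge_image <- function(shape, position, amplitude, sigma_px,
                              orientation = c("vertical", "horizontal"),
                              spacing_mm = 0.1) {
  orientation <- match.arg(orientation)
  stopifnot(sigma_px > 0)
  if (orientation == "vertical") {
    prof <- amplitude * exp(-(seq_len(shape[2]) - 1 - position)^2 /
                              (2 * sigma_px^2))
    px <- matrix(prof, shape[1], shape[2], byrow = TRUE)
  } else {
    prof <- amplitude * exp(-(seq_len(shape[1]) - 1 - position)^2 /
                              (2 * sigma_px^2))
    px <- matrix(prof, shape[1], shape[2])
  }
  mammogram_image(px, spacing_mm, bit_depth = 16L)
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf(
    "<phantom> %s: %d x %d px at %.3g mm/px, %d microcalcifications (%d clustered in %d clusters), %d ridges\n",
    x$image_id, nrow(x$image$pixels), ncol(x$image$pixels),
    x$image$spacing_mm, nrow(x$mc_points),
    sum(!is.na(x$mc_points$cluster)), nrow(x$clusters),
    x$spec$ridge_count
  ))
  invisible(x)
}
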