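#' Adaptive histogram threshold for breast/background separation
#'
#' Builds an equal-width intensity histogram, finds the maximum-count bin
#' `b_max` (in a mammogram the near-constant empty space around the breast
#' dominates the histogram, so `b_max` is the background mode), and examines
#' the `n_examine` bins immediately to its right. The declivity of bin `k`
#' is `count(k) - count(k + 1)`; the threshold is the left edge of bin
#' `k* + 1` where `k*` maximises the declivity over the examined range (ties
#' broken toward the smallest `k`). Bins partition `[0, 2^bit_depth)` so bin
#' width is `2^bit_depth / n_bins`.
#'
#' @param image A [mammogram_image()].
#' @param n_bins Number of histogram bins (>= 4).
#' @param n_examine Number of bins examined to the right of `b_max`.
#' @return The threshold intensity (left bin edge).
#' @export
adaptive_threshold <- function(image, n_bins = 64L, n_examine = 8L) {
  stopifnot(inherits(image, "mammogram"), n_bins >= 4,
            n_examine >= 1, n_examine < n_bins)
  px <- image$pixels
  if (min(px) == max(px)) {
    stop("degenerate histogram: image is constant", call. = FALSE)
  }
  width <- 2^image$bit_depth / n_bins
  bin <- pmin(floor(px / width), n_bins - 1)  # 0-based bin index
  counts <- tabulate(bin + 1L, nbins = n_bins)
  b_max <- which.max(counts) - 1L
  if (b_max == n_bins - 1L) {
    stop("degenerate histogram: modal bin is the last bin", call. = FALSE)
  }
  ks <- b_max:min(b_max + n_examine - 1L, n_bins - 2L)
  declivity <- counts[ks + 1L] - counts[ks + 2L]
  k_star <- ks[which.max(declivity)]  # which.max takes the first maximum
  (k_star + 1L) * width
}

#' Segment the breast region
#'
#' Binarises the image at the adaptive threshold (pixels `>= threshold` are
#' foreground, since breast tissue is brighter than empty space), smooths
#' the labels by morphological dilation with a disk, and keeps the largest
#' 8-connected component. The result always has exactly one connected
#' foreground component.
#'
#' @inheritParams adaptive_threshold
#' @param dilate_radius_px Disk radius of the dilation structuring element
#'   (0 disables dilation).
#' @return A `breast_mask`: list with `mask` (logical matrix, same shape as
#'   the image) and `threshold_used`.
#' @export
segment_breast <- function(image, n_bins = 64L, n_examine = 8L,
                           dilate_radius_px = 5L) {
  stopifnot(dilate_radius_px >= 0)
  thr <- adaptive_threshold(image, n_bins, n_examine)
  fg <- image$pixels >= thr
  if (!any(fg)) stop("segmentation failure: empty foreground", call. = FALSE)
  fg <- dilate_disk(fg, dilate_radius_px)
  lab <- rcpp_label_components(fg)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0])
    keep <- which.max(sizes)
    fg <- lab == keep
  }
  structure(list(mask = fg, threshold_used = thr), class = "breast_mask")
}

# binary dilation with a disk structuring element, by shift-OR over offsets
dilate_disk <- function(mask, radius) {
  if (radius == 0) return(mask)
  nr <- nrow(mask)
  nc <- ncol(mask)
  offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  offs <- offs[offs$dr^2 + offs$dc^2 <= radius^2, ]
  out <- matrix(FALSE, nr, nc)
  for (i in seq_len(nrow(offs))) {
    dr <- offs$dr[i]
    dc <- offs$dc[i]
    sr <- max(1, 1 - dr):min(nr, nr - dr)
    sc <- max(1, 1 - dc):min(nc, nc - dc)
    out[sr + dr, sc + dc] <- out[sr + dr, sc + dc] | mask[sr, sc]
  }
  out
}

#' @export
print.breast_mask <- function(x, ...) {
  cat(sprintf("<breast_mask> %d x %d, %d foreground px (%.1f%%), threshold %g\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask),
              100 * mean(x$mask), x$threshold_used))
  invisible(x)
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask A `breast_mask` or logical matrix.
#' @param path Output PNG path.
#' @export
write_mask <- function(mask, path) {
  m <- if (inherits(mask, "breast_mask")) mask$mask else mask
  png::writePNG(m * 1.0, path)
  invisible(path)
}
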