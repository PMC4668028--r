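#' Second-derivative (Hessian) filter responses at one scale
#'
#' Convolves the image with second derivative-of-Gaussian kernels of
#' standard deviation `sigma` (in pixels), giving the three distinct entries
#' of the 2x2 Hessian at every pixel. `x` is the column direction, `y` the
#' row direction. Kernels are truncated at radius `ceiling(4 * sigma)` and
#' the image boundary is reflect-padded.
#'
#' @param image A [mammogram_image()].
#' @param sigma Scale in pixels (> 0).
#' @return List with matrices `Ixx`, `Ixy`, `Iyy` and the `sigma` used.
#' @export
hessian_at_scale <- function(image, sigma) {
  stopifnot(inherits(image, "mammogram"), sigma > 0)
  r <- ceiling(4 * sigma)
  if (r > min(dim(image$pixels)) - 1) {
    stop("scale too large: truncated kernel exceeds image extent",
         call. = FALSE)
  }
  g0 <- gaussian_kernel(sigma, 0L)
  g1 <- gaussian_kernel(sigma, 1L)
  g2 <- gaussian_kernel(sigma, 2L)
  m <- image$pixels
  list(
    Ixx = conv_sep(m, g0, g2),  # d2/dx2: 2nd derivative across columns
    Ixy = conv_sep(m, g1, g1),
    Iyy = conv_sep(m, g2, g0),
    sigma = sigma
  )
}

# vectorised closed-form eigen-decomposition of the symmetric 2x2 Hessian;
# eigenvalues ordered so |lambda1| <= |lambda2|, ratio = |l1|/|l2| with the
# 0/0 -> 0 convention (flat regions are maximally non-blob)
eigen_feature_grids <- function(h) {
  tr <- h$Ixx + h$Iyy
  disc <- sqrt((h$Ixx - h$Iyy)^2 + 4 * h$Ixy^2)
  ea <- (tr + disc) / 2
  eb <- (tr - disc) / 2
  swap <- abs(ea) > abs(eb)
  l1 <- ifelse(swap, eb, ea)
  l2 <- ifelse(swap, ea, eb)
  frob <- sqrt(l1^2 + l2^2)
  ratio <- ifelse(l2 == 0, 0, abs(l1) / abs(l2))
  list(lambda1 = l1, lambda2 = l2, frob = frob, ratio = ratio)
}

#' Eigenvalue features of the Hessian at one pixel
#'
#' Closed-form eigenvalues of `[[Ixx, Ixy], [Ixy, Iyy]]`, assigned so that
#' `|lambda1| <= |lambda2|`, with the Frobenius norm and the absolute
#' eigenvalue ratio in `[0, 1]` (`0` when `lambda2 = 0`). At the centre of a
#' bright blob both eigenvalues are strongly negative; on a bright ridge
#' `lambda1` is near zero and `lambda2` strongly negative.
#'
#' @param hessian Output of [hessian_at_scale()].
#' @param pixel 0-based `(row, col)`.
#' @return One-row tibble `lambda1, lambda2, frob, ratio, sigma`.
#' @export
eigen_features <- function(hessian, pixel) {
  r <- pixel[1] + 1
  c <- pixel[2] + 1
  stopifnot(r >= 1, c >= 1, r <= nrow(hessian$Ixx), c <= ncol(hessian$Ixx))
  g <- eigen_feature_grids(list(Ixx = hessian$Ixx[r, c],
                                Ixy = hessian$Ixy[r, c],
                                Iyy = hessian$Iyy[r, c]))
  tibble::tibble(lambda1 = g$lambda1, lambda2 = g$lambda2,
                 frob = g$frob, ratio = g$ratio, sigma = hessian$sigma)
}

#' Multi-scale Hessian feature vector at one pixel
#'
#' Concatenates `(lambda1, lambda2, frob, ratio)` over the given scales (in
#' increasing order), the per-pixel feature the stage-1 classifier consumes.
#'
#' @param image A [mammogram_image()].
#' @param pixel 0-based `(row, col)`.
#' @param scales Strictly increasing positive scales in pixels.
#' @return Named numeric vector of length `4 * length(scales)`.
#' @export
feature_vector <- function(image, pixel, scales) {
  check_scales(scales)
  out <- purrr::map(scales, function(s) {
    f <- eigen_features(hessian_at_scale(image, s), pixel)
    setNames(as.numeric(f[1, c("lambda1", "lambda2", "frob", "ratio")]),
             paste0(c("lambda1", "lambda2", "frob", "ratio"), "_s", s))
  })
  unlist(out)
}

#' Multi-scale Hessian feature map over a masked region
#'
#' Computes each scale's filter responses once over the whole image and
#' gathers the per-pixel feature vectors at the mask pixels; values are
#' identical to per-pixel [feature_vector()] calls.
#'
#' @param image A [mammogram_image()].
#' @param mask A `breast_mask` or logical matrix (same shape as the image).
#' @param scales Strictly increasing positive scales in pixels.
#' @return An `mc_feature_map`: list with `coords` (tibble of 0-based
#'   `row, col`), `features` (matrix, one row per mask pixel, columns in
#'   per-scale `(lambda1, lambda2, frob, ratio)` order), `shape` and
#'   `scales`.
#' @export
feature_map <- function(image, mask, scales) {
  check_scales(scales)
  m <- if (inherits(mask, "breast_mask")) mask$mask else mask
  stopifnot(identical(dim(m), dim(image$pixels)))
  idx <- which(m)
  nr <- nrow(m)
  coords <- tibble::tibble(row = (idx - 1) %% nr,
                           col = (idx - 1) %/% nr)
  feats <- matrix(0, length(idx), 4 * length(scales))
  for (i in seq_along(scales)) {
    g <- eigen_feature_grids(hessian_at_scale(image, scales[i]))
    feats[, 4 * i - 3] <- g$lambda1[idx]
    feats[, 4 * i - 2] <- g$lambda2[idx]
    feats[, 4 * i - 1] <- g$frob[idx]
    feats[, 4 * i] <- g$ratio[idx]
  }
  colnames(feats) <- unlist(purrr::map(
    scales, ~ paste0(c("lambda1", "lambda2", "frob", "ratio"), "_s", .x)))
  structure(list(coords = coords, features = feats,
                 shape = dim(m), scales = scales),
            class = "mc_feature_map")
}

check_scales <- function(scales) {
  if (length(scales) == 0 || any(scales <= 0) ||
      (length(scales) > 1 && any(diff(scales) <= 0))) {
    stop("`scales` must be a non-empty strictly increasing positive vector",
         call. = FALSE)
  }
  invisible(scales)
}
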