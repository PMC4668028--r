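# Separable correlation with reflect (edge-repeating) padding, done as two
# band-matrix products so BLAS carries the cost. Used by the Hessian filters,
# the tissue-texture generator and the NMS template machinery.

reflect_indices <- function(n, r) {
  if (r == 0) return(seq_len(n))
  if (r > n - 1) stop("padding radius exceeds image extent", call. = FALSE)
  c(r:1, seq_len(n), n:(n - r + 1))
}

band_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  a <- matrix(0, n, n + 2L * r)
  for (k in seq_along(kernel)) {
    a[cbind(seq_len(n), seq_len(n) + k - 1L)] <- kernel[k]
  }
  a
}

# ky runs along rows (the y/vertical axis), kx along columns (x/horizontal).
conv_sep <- function(m, ky, kx) {
  ry <- (length(ky) - 1L) / 2L
  rx <- (length(kx) - 1L) / 2L
  mp <- m[reflect_indices(nrow(m), ry), reflect_indices(ncol(m), rx),
          drop = FALSE]
  band_matrix(nrow(m), ky) %*% mp %*% t(band_matrix(ncol(m), kx))
}

# Sampled derivative-of-Gaussian kernels, unit-integral normalisation.
# The 0th order kernel is renormalised to sum exactly 1 and the 2nd order
# kernel is recentred to sum exactly 0, so constant images give flat
# smoothing and exactly-zero second derivatives up to float roundoff.
gaussian_kernel <- function(sigma, order = 0L, radius = ceiling(4 * sigma)) {
  u <- seq(-radius, radius)
  phi <- exp(-u^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
  k <- switch(as.character(order),
    "0" = phi,
    "1" = -u / sigma^2 * phi,
    "2" = (u^2 - sigma^2) / sigma^4 * phi,
    stop("order must be 0, 1 or 2", call. = FALSE)
  )
  if (order == 0L) k <- k / sum(k)
  if (order == 2L) k <- k - mean(k)
  k
}
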