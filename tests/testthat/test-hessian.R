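test_that("constant images give zero second derivatives", {
  img <- mammogram_image(matrix(123, 24, 24), 0.1)
  h <- hessian_at_scale(img, 1.5)
  expect_lt(max(abs(h$Ixx)), 1e-10)
  expect_lt(max(abs(h$Ixy)), 1e-10)
  expect_lt(max(abs(h$Iyy)), 1e-10)
})

test_that("filter responses match the dense 2-D convolution oracle", {
  set.seed(71)
  img <- mammogram_image(matrix(runif(21 * 21, 0, 200), 21, 21), 0.1,
                         bit_depth = 16L)
  for (sigma in c(1, 1.7)) {
    h <- hessian_at_scale(img, sigma)
    expect_equal(h$Ixx,
                 oracle_conv2d(img$pixels, oracle_dog_kernel2d(sigma, 0, 2)),
                 tolerance = 1e-10)
    expect_equal(h$Ixy,
                 oracle_conv2d(img$pixels, oracle_dog_kernel2d(sigma, 1, 1)),
                 tolerance = 1e-10)
    expect_equal(h$Iyy,
                 oracle_conv2d(img$pixels, oracle_dog_kernel2d(sigma, 2, 0)),
                 tolerance = 1e-10)
  }
})

test_that("blob centre responses match the analytic closed form", {
  s <- 2
  amp <- 100
  blob <- ideal_blob_image(c(41, 41), c(20, 20), amp, s)
  for (sigma in c(1, 2, 3)) {
    h <- hessian_at_scale(blob, sigma)
    expected <- -amp * s^2 / (s^2 + sigma^2)^2
    # 4-sigma kernel truncation bounds agreement with the infinite-support
    # closed form; the dense-convolution oracle below is matched far tighter
    expect_equal(h$Ixx[21, 21], expected, tolerance = 1e-3)
    expect_equal(h$Iyy[21, 21], expected, tolerance = 1e-3)
    expect_equal(h$Ixy[21, 21], 0, tolerance = 1e-9)
  }
})

test_that("transposing the image swaps Ixx and Iyy", {
  set.seed(5)
  img <- mammogram_image(matrix(runif(18 * 18, 0, 100), 18, 18), 0.1)
  timg <- mammogram_image(t(img$pixels), 0.1)
  h <- hessian_at_scale(img, 1.2)
  ht <- hessian_at_scale(timg, 1.2)
  expect_equal(ht$Ixx, t(h$Iyy), tolerance = 1e-12)
  expect_equal(ht$Iyy, t(h$Ixx), tolerance = 1e-12)
  expect_equal(ht$Ixy, t(h$Ixy), tolerance = 1e-12)
})

test_that("eigen features follow the closed form and magnitude ordering", {
  # constructed Hessian diag(-3, -1): lambda1 = -1, lambda2 = -3
  h <- list(Ixx = matrix(-3, 3, 3), Ixy = matrix(0, 3, 3),
            Iyy = matrix(-1, 3, 3), sigma = 1)
  f <- eigen_features(h, c(1, 1))
  expect_equal(f$lambda1, -1)
  expect_equal(f$lambda2, -3)
  expect_equal(f$frob, sqrt(10))
  expect_equal(f$ratio, 1 / 3)

  hz <- list(Ixx = matrix(0, 3, 3), Ixy = matrix(0, 3, 3),
             Iyy = matrix(0, 3, 3), sigma = 1)
  fz <- eigen_features(hz, c(1, 1))
  expect_equal(as.numeric(fz[1, 1:4]), c(0, 0, 0, 0))
})

test_that("bright blobs and ridges reproduce the qualitative eigenvalue patterns", {
  blob <- ideal_blob_image(c(41, 41), c(20, 20), 100, 2)
  fb <- eigen_features(hessian_at_scale(blob, 2), c(20, 20))
  expect_lt(fb$lambda2, 0)      # both eigenvalues strongly negative
  expect_lt(fb$lambda1, 0)
  expect_gt(fb$ratio, 0.9)      # nearly isotropic

  ridge <- ideal_ridge_image(c(41, 41), 20, 100, 2, "vertical")
  fr <- eigen_features(hessian_at_scale(ridge, 2), c(20, 20))
  expect_lt(fr$lambda2, 0)      # strong negative across the ridge
  expect_lt(abs(fr$lambda1), 0.05 * abs(fr$lambda2))  # ~0 along it
})

test_that("feature vectors concatenate scales in order", {
  blob <- ideal_blob_image(c(64, 64), c(31, 31), 80, 2)
  fv1 <- feature_vector(blob, c(31, 31), scales = 2)
  expect_length(fv1, 4)
  expect_equal(unname(fv1),
               as.numeric(eigen_features(hessian_at_scale(blob, 2),
                                         c(31, 31))[1, 1:4]))
  fv5 <- feature_vector(blob, c(31, 31), scales = 1:5)
  expect_length(fv5, 20)
  expect_equal(unname(fv5[5:8]), unname(feature_vector(blob, c(31, 31), 2)))
  expect_error(feature_vector(blob, c(31, 31), c(2, 1)), "increasing")
})

test_that("scale-normalised |lambda2| peaks near the blob's own scale", {
  # the raw second-derivative response of a Gaussian blob decays
  # monotonically with the filter scale (-A s^2 / (s^2 + sigma^2)^2), so
  # scale selection needs the classical sigma^2 normalisation; the
  # classifier sees the raw multi-scale responses and learns the decay
  blob <- ideal_blob_image(c(64, 64), c(31, 31), 80, 2)
  sigmas <- seq(0.5, 5, by = 0.5)
  resp <- vapply(sigmas, function(s) {
    s^2 * abs(eigen_features(hessian_at_scale(blob, s), c(31, 31))$lambda2)
  }, numeric(1))
  peak_scale <- sigmas[which.max(resp)]
  expect_lte(abs(peak_scale - 2), 0.5)
  # and the raw response itself is monotone decreasing in sigma
  expect_true(all(diff(resp / sigmas^2) < 0))
})

test_that("feature map equals per-pixel evaluation and respects the mask", {
  set.seed(77)
  img <- mammogram_image(matrix(runif(64 * 64, 0, 255), 64, 64), 0.1)
  mask <- matrix(FALSE, 64, 64)
  mask[10:40, 15:50] <- TRUE
  fm <- feature_map(img, mask, scales = c(1, 2))
  expect_equal(nrow(fm$features), sum(mask))
  expect_equal(ncol(fm$features), 8)
  probe <- sample(nrow(fm$coords), 25)
  for (i in probe) {
    expect_equal(unname(fm$features[i, ]),
                 unname(feature_vector(img, c(fm$coords$row[i],
                                              fm$coords$col[i]),
                                       c(1, 2))),
                 tolerance = 1e-12)
  }
  single <- matrix(FALSE, 64, 64)
  single[23, 31] <- TRUE
  fs <- feature_map(img, single, scales = c(1, 2))
  expect_equal(unname(fs$features[1, ]),
               unname(feature_vector(img, c(22, 30), c(1, 2))))
})

test_that("rotation covariance and intensity scaling hold", {
  set.seed(13)
  px <- matrix(runif(32 * 32, 0, 100), 32, 32)
  img <- mammogram_image(px, 0.1)
  # rotate 90 degrees: rot[r, c] = px[n - 1 - c, r] (0-based)
  rot <- mammogram_image(t(px)[, nrow(px):1], 0.1)
  f_orig <- feature_vector(img, c(12, 20), c(1, 2))
  # pixel (a, b) of the original lands at (b, n - 1 - a) in the rotation
  f_rot <- feature_vector(rot, c(20, 31 - 12), c(1, 2))
  expect_equal(unname(f_orig), unname(f_rot), tolerance = 1e-9)

  scaled <- mammogram_image(3.5 * px, 0.1, bit_depth = 16L)
  f_scaled <- feature_vector(scaled, c(12, 20), c(1, 2))
  idx_l <- c(1, 2, 3, 5, 6, 7)  # lambda1, lambda2, frob per scale
  expect_equal(unname(f_scaled[idx_l]), unname(3.5 * f_orig[idx_l]),
               tolerance = 1e-9)
  expect_equal(unname(f_scaled[c(4, 8)]), unname(f_orig[c(4, 8)]),
               tolerance = 1e-9)
})

test_that("eigen ordering and Frobenius consistency hold everywhere", {
  set.seed(99)
  img <- mammogram_image(matrix(runif(40 * 40, 0, 255), 40, 40), 0.1)
  fm <- feature_map(img, matrix(TRUE, 40, 40), scales = c(1, 2.5))
  for (s in 1:2) {
    l1 <- fm$features[, 4 * s - 3]
    l2 <- fm$features[, 4 * s - 2]
    fro <- fm$features[, 4 * s - 1]
    rat <- fm$features[, 4 * s]
    expect_true(all(abs(l1) <= abs(l2) + 1e-12))
    expect_equal(fro^2, l1^2 + l2^2, tolerance = 1e-9)
    expect_true(all(rat >= 0 & rat <= 1 + 1e-12))
  }
})

test_that("oversized scales are rejected", {
  img <- mammogram_image(matrix(1:64 * 1.0, 8, 8), 0.1)
  expect_error(hessian_at_scale(img, 3), "scale too large")
})
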