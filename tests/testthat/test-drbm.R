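zero_model <- function(nv, nh) {
  m <- drbm_model(nv, nh, seed = 1)
  m$W[] <- 0
  m$U[] <- 0
  m
}

test_that("energy matches term-by-term arithmetic", {
  m <- zero_model(3, 2)
  expect_equal(drbm_energy(m, 1, c(0.5, 0.2, 0.9), c(1, 0)), 0)

  m$W <- matrix(c(1, -2, 0.5, 0, 3, -1), 2, 3)
  m$U <- matrix(c(0.5, -0.5, 2, 1), 2, 2)
  m$b <- c(1, 0, -1)
  m$c <- c(0.25, -0.75)
  m$d <- c(0.1, -0.2)
  x <- c(1, 0.5, 0)
  h <- c(1, 1)
  # hand evaluation of -h'Wx - b'x - c'h - d_y - h'U[, y], y = 1
  wx <- c(1 * 1 + 0.5 * 0.5 + 0 * 0, -2 * 1 + 0 * 0.5 + (-1) * 0)
  hand <- -(sum(h * wx)) - (1 * 1 + 0 * 0.5 + (-1) * 0) -
    (0.25 * 1 + (-0.75) * 1) - (-0.2) - (2 * 1 + 1 * 1)
  expect_equal(drbm_energy(m, 1, x, h), hand)
  # h = 0 leaves only the visible and class bias terms
  expect_equal(drbm_energy(m, 0, x, c(0, 0)), -sum(m$b * x) - m$d[1])
})

test_that("conditional probability matches hidden-state enumeration", {
  expect_equal(conditional_prob(zero_model(4, 3), runif(4)), c(0.5, 0.5))
  m <- zero_model(2, 2)
  m$d <- c(0, 10)
  expect_equal(conditional_prob(m, c(0.3, 0.3))[2], 1 / (1 + exp(-10)),
               tolerance = 1e-12)

  set.seed(21)
  for (i in 1:20) {
    nh <- sample(1:6, 1)
    nv <- sample(1:5, 1)
    m <- drbm_model(nv, nh, seed = i, init_sd = 0.8)
    m$b <- rnorm(nv)
    m$c <- rnorm(nh)
    m$d <- rnorm(2)
    x <- runif(nv)
    p <- conditional_prob(m, x)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(p, oracle_drbm_prob(m, x), tolerance = 1e-10)
  }
})

test_that("swapping class parameters swaps the conditional probabilities", {
  m <- drbm_model(3, 4, seed = 3, init_sd = 0.5)
  m$d <- c(0.3, -0.7)
  sw <- m
  sw$U <- m$U[, 2:1]
  sw$d <- m$d[2:1]
  x <- runif(3)
  expect_equal(conditional_prob(m, x), rev(conditional_prob(sw, x)),
               tolerance = 1e-14)
})

test_that("exact discriminative gradient matches finite differences", {
  set.seed(8)
  m <- drbm_model(3, 2, seed = 8, init_sd = 0.6)
  m$b <- rnorm(3)
  m$c <- rnorm(2)
  m$d <- rnorm(2)
  X <- matrix(runif(6), 2, 3)
  y <- c(1, 0)
  g <- drbm_disc_grad(m, X, y)
  eps <- 1e-6
  fd <- function(set, get_idx) {
    mp <- m; mm <- m
    mp[[set]][get_idx] <- mp[[set]][get_idx] + eps
    mm[[set]][get_idx] <- mm[[set]][get_idx] - eps
    (drbm_nll(mp, X, y) - drbm_nll(mm, X, y)) / (2 * eps) / nrow(X)
  }
  for (idx in list(c(1, 1), c(2, 3))) {
    expect_equal(g$W[idx[1], idx[2]], fd("W", rbind(idx)),
                 tolerance = 1e-5)
  }
  expect_equal(g$U[1, 2], fd("U", rbind(c(1, 2))), tolerance = 1e-5)
  expect_equal(g$c[2], fd("c", 2), tolerance = 1e-5)
  expect_equal(g$d[1], fd("d", 1), tolerance = 1e-5)
  expect_equal(g$b, numeric(3))  # b cancels in p(y|x)
})

test_that("hidden sampling follows its Bernoulli means", {
  m <- zero_model(2, 5)
  m$c <- rep(-50, 5)
  expect_equal(drbm_sample_hidden(m, 1, c(0.5, 0.5)), rep(0, 5))

  m0 <- zero_model(2, 1)
  set.seed(77)
  draws <- replicate(10000, drbm_sample_hidden(m0, 0, c(0.1, 0.9)))
  expect_lt(abs(mean(draws) - 0.5), 3 * sqrt(0.25 / 10000))

  set.seed(5)
  a <- drbm_sample_hidden(m0, 1, c(0.2, 0.2))
  set.seed(5)
  b <- drbm_sample_hidden(m0, 1, c(0.2, 0.2))
  expect_identical(a, b)
})

test_that("a zero learning rate leaves CD updates inert", {
  m <- drbm_model(4, 3, seed = 2)
  set.seed(31)
  m2 <- drbm_cd_update(m, matrix(runif(8), 2, 4), c(0, 1),
                       learning_rate = 0)
  expect_identical(m2$W, m$W)
  expect_identical(m2$b, m$b)
  expect_identical(m2$d, m$d)
})

test_that("one CD step reproduces hand-computed gradient arithmetic", {
  # 1 visible, 1 hidden, 1 sample; replicate the update with the same RNG
  m <- zero_model(1, 1)
  m$W[] <- 0.5
  m$U[] <- c(0.2, -0.3)
  m$b <- 0.1
  m$c <- -0.2
  m$d <- c(0, 0.1)
  x <- 0.8
  y <- 1
  lr <- 0.05
  sig <- function(z) 1 / (1 + exp(-z))
  set.seed(123)
  u_h <- runif(1)
  u_y <- runif(1)
  h0 <- sig(m$c + m$U[1, 2] + m$W[1, 1] * x)
  hs <- as.numeric(u_h < h0)
  xn <- sig(m$b + m$W[1, 1] * hs)
  p1 <- sig((m$d[2] + m$U[1, 2] * hs) - (m$d[1] + m$U[1, 1] * hs))
  ys <- as.numeric(u_y < p1)
  yn <- c(1 - ys, ys)
  hn <- sig(m$c + sum(m$U[1, ] * yn) + m$W[1, 1] * xn)
  expected_W <- m$W[1, 1] + lr * (h0 * x - hn * xn)
  expected_b <- m$b + lr * (x - xn)
  expected_d <- m$d + lr * (c(0, 1) - yn)
  set.seed(123)
  up <- drbm_cd_update(m, matrix(x, 1, 1), y, lr)
  expect_equal(up$W[1, 1], expected_W, tolerance = 1e-14)
  expect_equal(up$b, expected_b, tolerance = 1e-14)
  expect_equal(up$d, expected_d, tolerance = 1e-14)
})

test_that("CD training solves the two-prototype toy problem", {
  X <- rbind(matrix(1, 50, 2), matrix(0, 50, 2))
  y <- rep(c(1, 0), each = 50)
  m <- train_drbm(X, y, n_hidden = 4, learning_rate = 0.1,
                  n_epochs = 200, seed = 2)
  expect_gt(drbm_predict(m, matrix(c(1, 1), 1)), 0.8)
  expect_lt(drbm_predict(m, matrix(c(0, 0), 1)), 0.2)
  # the conditional NLL trends down over training
  expect_lt(m$history$nll[nrow(m$history)], m$history$nll[1])
  # and so does the discriminative trainer
  md <- train_drbm(X, y, n_hidden = 4, learning_rate = 0.5,
                   n_epochs = 300, seed = 2, method = "discriminative")
  expect_gt(drbm_predict(md, matrix(c(1, 1), 1)), 0.8)
})

test_that("the zero model's NLL is N log 2", {
  m <- zero_model(3, 4)
  X <- matrix(runif(15), 5, 3)
  expect_equal(drbm_nll(m, X, c(1, 0, 1, 1, 0)), 5 * log(2))
})

test_that("patches are normalised, centred and reflect-padded", {
  img <- mammogram_image(matrix(200, 20, 20), 0.1)
  p <- extract_patch(img, c(10, 10), 5)
  expect_length(p, 25)
  expect_true(all(p == 200 / 255))

  ramp <- mammogram_image(matrix(rep(0:19, each = 20), 20, 20), 0.1,
                          bit_depth = 8L)
  p0 <- extract_patch(ramp, c(0, 0), 5)
  # explicit reflect-padding oracle
  refl <- function(i, n) ifelse(i < 0, -i - 1, ifelse(i >= n, 2 * n - i - 1, i))
  expected <- outer(-2:2, -2:2, function(dr, dc) {
    ramp$pixels[cbind(refl(0 + dr, 20) + 1, refl(0 + dc, 20) + 1)]
  })
  expect_equal(matrix(p0, 5, 5, byrow = TRUE), expected / 255)
  expect_error(extract_patch(img, c(10, 10), 25), "larger than image")
  expect_length(extract_patch(img, c(10, 10), 15), 225)
})

test_that("patch classification thresholds monotonically", {
  set.seed(41)
  img <- mammogram_image(matrix(runif(40 * 40, 0, 255), 40, 40), 0.1)
  m <- drbm_model(25, 6, seed = 2, init_sd = 0.5)
  cands <- tibble::tibble(row = sample(5:34, 12), col = sample(5:34, 12))
  all_kept <- classify_patches(m, cands, img, 0, patch_side = 5)
  expect_equal(nrow(all_kept), 12)
  expect_true(all(all_kept$stage == "drbm"))
  sizes <- vapply(seq(0.1, 0.9, by = 0.2), function(th) {
    nrow(classify_patches(m, cands, img, th, patch_side = 5))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(nrow(classify_patches(m, cands[0, ], img, 0.5,
                                     patch_side = 5)), 0)
})

test_that("DRBM JSON serialization round-trips predictions", {
  m <- drbm_model(9, 4, seed = 6, init_sd = 0.3)
  path <- withr::local_tempfile(fileext = ".json")
  write_drbm(m, path)
  back <- read_drbm(path)
  X <- matrix(runif(18), 2, 9)
  expect_equal(drbm_predict(back, X), drbm_predict(m, X),
               tolerance = 1e-15)
})
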