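#' Initialise a discriminative restricted Boltzmann machine
#'
#' The model couples a visible patch vector `x` (values in `[0, 1]`), binary
#' hidden units `h` and a one-hot class label `y` through the energy
#' `E(y, x, h) = -h'Wx - b'x - c'h - d_y - h'U[, y]`. Weights start at
#' `Normal(0, init_sd)`, biases at zero.
#'
#' @param n_visible Visible dimension (patch area, `patch_side^2`).
#' @param n_hidden Number of hidden units.
#' @param seed Integer seed for the initial weights.
#' @param init_sd Standard deviation of the weight initialisation.
#' @return An `mc_drbm` object with fields `W` (hidden x visible), `U`
#'   (hidden x 2), `b`, `c`, `d`.
#' @export
drbm_model <- function(n_visible, n_hidden, seed = 1L, init_sd = 0.01) {
  set.seed(seed)
  structure(
    list(W = matrix(rnorm(n_hidden * n_visible, sd = init_sd),
                    n_hidden, n_visible),
         U = matrix(rnorm(n_hidden * 2, sd = init_sd), n_hidden, 2),
         b = numeric(n_visible), c = numeric(n_hidden), d = numeric(2),
         n_visible = as.integer(n_visible), n_hidden = as.integer(n_hidden),
         history = NULL),
    class = "mc_drbm"
  )
}

#' Energy of a joint configuration
#'
#' @param model An `mc_drbm`.
#' @param y Class label, 0 (non-microcalcification) or 1.
#' @param x Visible vector.
#' @param h Binary hidden vector.
#' @return The scalar energy `-h'Wx - b'x - c'h - d_y - h'U[, y]`.
#' @export
drbm_energy <- function(model, y, x, h) {
  stopifnot(length(x) == model$n_visible, length(h) == model$n_hidden,
            y %in% c(0, 1))
  -sum(h * (model$W %*% x)) - sum(model$b * x) - sum(model$c * h) -
    model$d[y + 1] - sum(h * model$U[, y + 1])
}

softplus <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

sigmoid <- function(z) 1 / (1 + exp(-z))

# free energies F_y = d_y + sum_j softplus(c_j + U[j, y] + W[j, ] x) for a
# batch X (n x visible); returns n x 2 matrix
drbm_free_energy <- function(model, X) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  stopifnot(ncol(X) == model$n_visible)
  if (!all(is.finite(model$W)) || !all(is.finite(model$U))) {
    stop("non-finite model parameters", call. = FALSE)
  }
  A <- X %*% t(model$W)  # n x hidden
  f <- vapply(1:2, function(yy) {
    Z <- sweep(A, 2, model$c + model$U[, yy], "+")
    model$d[yy] + rowSums(softplus(Z))
  }, numeric(nrow(X)))
  matrix(f, nrow = nrow(X))
}

#' Exact class-conditional probability p(y | x)
#'
#' Marginalising the hidden layer in closed form gives
#' `p(y | x) = exp(F_y) / sum_y' exp(F_y')` with free energy
#' `F_y = d_y + sum_j softplus(c_j + U[j, y] + W[j, ] x)`; computed in
#' log-space with max subtraction. This makes label inference exact — no
#' sampling is involved at test time.
#'
#' @param model An `mc_drbm`.
#' @param x A single visible vector.
#' @return Probability pair `c(p0, p1)` summing to 1.
#' @export
conditional_prob <- function(model, x) {
  f <- drbm_free_energy(model, x)[1, ]
  f <- f - max(f)
  p <- exp(f)
  p / sum(p)
}

#' Batch microcalcification probabilities
#'
#' @param model An `mc_drbm`.
#' @param X Matrix of visible vectors, one row per patch.
#' @return Vector of `p(y = 1 | x)`.
#' @export
drbm_predict <- function(model, X) {
  f <- drbm_free_energy(model, X)
  sigmoid(f[, 2] - f[, 1])
}

#' Sample the hidden layer given a labelled visible vector
#'
#' Each `h_j ~ Bernoulli(sigmoid(c_j + U[j, y] + W[j, ] x))`, independently,
#' using the current RNG state.
#'
#' @inheritParams drbm_energy
#' @return Binary hidden vector.
#' @export
drbm_sample_hidden <- function(model, y, x) {
  p <- sigmoid(model$c + model$U[, y + 1] + drop(model$W %*% x))
  as.numeric(runif(model$n_hidden) < p)
}

#' One contrastive-divergence parameter update on a mini-batch
#'
#' Positive phase: hidden means with `(y, x)` clamped to the data. Negative
#' phase: `cd_steps` Gibbs alternations — sample the hidden layer, then
#' reconstruct visible means `sigmoid(b + W'h)` and resample the class from
#' `softmax(d + U'h)`; the final negative statistics use the hidden means
#' given the reconstruction. Parameters move by `learning_rate` times the
#' batch-mean gradient.
#'
#' @param model An `mc_drbm`.
#' @param X Batch of visible vectors (rows).
#' @param y Batch labels (0/1).
#' @param learning_rate Step size.
#' @param cd_steps Number of Gibbs alternations (>= 1).
#' @return The updated model.
#' @export
drbm_cd_update <- function(model, X, y, learning_rate, cd_steps = 1L) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  n <- nrow(X)
  stopifnot(length(y) == n, cd_steps >= 1)
  Y0 <- unname(cbind(1 - y, y))  # one-hot rows
  H0 <- sigmoid(sweep(X %*% t(model$W), 2, model$c, "+") + Y0 %*% t(model$U))

  Hs <- matrix(runif(n * model$n_hidden), n) < H0
  mode(Hs) <- "numeric"
  Xn <- X
  Yn <- Y0
  for (k in seq_len(cd_steps)) {
    Xn <- sigmoid(sweep(Hs %*% model$W, 2, model$b, "+"))
    logit_y <- sweep(Hs %*% model$U, 2, model$d, "+")
    p1 <- sigmoid(logit_y[, 2] - logit_y[, 1])
    ys <- as.numeric(runif(n) < p1)
    Yn <- unname(cbind(1 - ys, ys))
    Hn <- sigmoid(sweep(Xn %*% t(model$W), 2, model$c, "+") +
                    Yn %*% t(model$U))
    if (k < cd_steps) {
      Hs <- matrix(runif(n * model$n_hidden), n) < Hn
      mode(Hs) <- "numeric"
    }
  }

  model$W <- model$W + learning_rate * (t(H0) %*% X - t(Hn) %*% Xn) / n
  model$U <- model$U + learning_rate * (t(H0) %*% Y0 - t(Hn) %*% Yn) / n
  model$b <- model$b + learning_rate * (colMeans(X) - colMeans(Xn))
  model$c <- model$c + learning_rate * (colMeans(H0) - colMeans(Hn))
  model$d <- model$d + learning_rate * (colMeans(Y0) - colMeans(Yn))
  model
}

#' Exact gradient of the discriminative objective
#'
#' Batch-mean gradient of the negative conditional log-likelihood
#' `-log p(y | x)` with respect to all parameters, in closed form. `b` does
#' not appear in `p(y | x)` so its gradient is zero. Used to cross-check
#' training numerically and as the optional purely discriminative trainer.
#'
#' @inheritParams drbm_cd_update
#' @return List of gradients `W`, `U`, `b`, `c`, `d` (of the *negative*
#'   log-likelihood: descend by subtracting).
#' @export
drbm_disc_grad <- function(model, X, y) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  n <- nrow(X)
  f <- drbm_free_energy(model, X)
  P <- exp(f - apply(f, 1, max))
  P <- P / rowSums(P)
  Y <- unname(cbind(1 - y, y))
  E <- P - Y  # n x 2, dNLL/dF_y
  A <- X %*% t(model$W)
  gW <- matrix(0, model$n_hidden, model$n_visible)
  gU <- matrix(0, model$n_hidden, 2)
  gc <- numeric(model$n_hidden)
  for (yy in 1:2) {
    S <- sigmoid(sweep(A, 2, model$c + model$U[, yy], "+"))  # n x h
    Se <- S * E[, yy]
    gW <- gW + t(Se) %*% X
    gU[, yy] <- colSums(Se)
    gc <- gc + colSums(Se)
  }
  list(W = gW / n, U = gU / n, b = numeric(model$n_visible),
       c = gc / n, d = colMeans(E))
}

#' Negative conditional log-likelihood
#'
#' `-sum_i log p(y_i | x_i)`; for an untrained (all-zero) model this is
#' `n * log(2)`.
#'
#' @inheritParams drbm_cd_update
#' @return Non-negative scalar.
#' @export
drbm_nll <- function(model, X, y) {
  if (is.vector(X)) X <- matrix(X, nrow = 1)
  stopifnot(length(y) == nrow(X))
  f <- drbm_free_energy(model, X)
  m <- apply(f, 1, max)
  logz <- m + log(exp(f[, 1] - m) + exp(f[, 2] - m))
  fy <- f[cbind(seq_len(nrow(X)), y + 1)]
  -sum(fy - logz)
}

#' Train a DRBM on labelled patches
#'
#' Default training is generative contrastive divergence on the joint
#' `(y, x)`; `method = "discriminative"` instead descends the exact gradient
#' of the conditional objective. Samples are shuffled each epoch under the
#' run seed and processed in mini-batches. The per-epoch conditional
#' negative log-likelihood is recorded in `$history`.
#'
#' @param X Patch matrix (rows in `[0, 1]`).
#' @param y Labels (0/1).
#' @param n_hidden Hidden layer size.
#' @param learning_rate Step size.
#' @param n_epochs Passes over the training set.
#' @param batch_size Mini-batch size.
#' @param cd_steps Gibbs alternations per update (CD only).
#' @param seed Integer seed (initialisation, shuffling, sampling).
#' @param method `"cd"` or `"discriminative"`.
#' @param init_sd Weight initialisation scale.
#' @return A trained `mc_drbm` with a `history` tibble (`epoch`, `nll`).
#' @export
train_drbm <- function(X, y, n_hidden, learning_rate = 0.02,
                       n_epochs = 30L, batch_size = 64L, cd_steps = 1L,
                       seed = 1L, method = c("cd", "discriminative"),
                       init_sd = 0.01) {
  method <- match.arg(method)
  if (is.vector(X)) X <- matrix(X, ncol = 1)
  stopifnot(nrow(X) == length(y), all(X >= 0), all(X <= 1))
  model <- drbm_model(ncol(X), n_hidden, seed = seed, init_sd = init_sd)
  n <- nrow(X)
  history <- vector("list", n_epochs)
  for (ep in seq_len(n_epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      bi <- ord[start:min(start + batch_size - 1, n)]
      if (method == "cd") {
        model <- drbm_cd_update(model, X[bi, , drop = FALSE], y[bi],
                                learning_rate, cd_steps)
      } else {
        g <- drbm_disc_grad(model, X[bi, , drop = FALSE], y[bi])
        model$W <- model$W - learning_rate * g$W
        model$U <- model$U - learning_rate * g$U
        model$c <- model$c - learning_rate * g$c
        model$d <- model$d - learning_rate * g$d
      }
    }
    history[[ep]] <- tibble::tibble(epoch = ep, nll = drbm_nll(model, X, y))
  }
  model$history <- dplyr::bind_rows(history)
  model$method <- method
  model
}

#' Extract a normalised raw patch around a pixel
#'
#' A `patch_side x patch_side` window centred on `center` (0-based
#' `(row, col)`), flattened row-major, intensities divided by
#' `2^bit_depth - 1` so components lie in `[0, 1]`. Windows that extend past
#' the border are reflect-padded, consistent with the convolution boundary
#' handling.
#'
#' @param image A [mammogram_image()].
#' @param center 0-based `(row, col)`.
#' @param patch_side Odd window side.
#' @return Numeric vector of length `patch_side^2`.
#' @export
extract_patch <- function(image, center, patch_side) {
  stopifnot(patch_side %% 2 == 1)
  px <- image$pixels
  if (patch_side > nrow(px) || patch_side > ncol(px)) {
    stop("patch larger than image", call. = FALSE)
  }
  half <- (patch_side - 1) / 2
  ri <- reflect_clip(center[1] + (-half:half), nrow(px))
  ci <- reflect_clip(center[2] + (-half:half), ncol(px))
  as.vector(t(px[ri, ci, drop = FALSE])) / (2^image$bit_depth - 1)
}

# 0-based indices reflected (edge-repeating) into [0, n); returns 1-based
reflect_clip <- function(idx, n) {
  idx <- ifelse(idx < 0, -idx - 1, idx)
  idx <- ifelse(idx >= n, 2 * n - idx - 1, idx)
  idx + 1
}

#' Classify candidate pixels with the DRBM
#'
#' Scores each candidate with the exact conditional probability of the
#' microcalcification class on its raw patch and keeps candidates with
#' `score >= theta_drbm`.
#'
#' @param model A trained `mc_drbm`.
#' @param candidates Tibble/data frame with 0-based `row`, `col`.
#' @param image A [mammogram_image()].
#' @param theta_drbm Probability threshold in `[0, 1]`.
#' @param patch_side Odd patch side matching the model's visible layer.
#' @param image_id Identifier for the output records.
#' @return Detection tibble `image_id, row, col, score, stage` with
#'   `stage = "drbm"`.
#' @export
classify_patches <- function(model, candidates, image, theta_drbm,
                             patch_side = sqrt(model$n_visible),
                             image_id = "image") {
  stopifnot(theta_drbm >= 0, theta_drbm <= 1,
            patch_side^2 == model$n_visible)
  if (nrow(candidates) == 0) {
    return(tibble::tibble(image_id = character(), row = integer(),
                          col = integer(), score = numeric(),
                          stage = character()))
  }
  P <- t(vapply(seq_len(nrow(candidates)), function(i) {
    extract_patch(image, c(candidates$row[i], candidates$col[i]), patch_side)
  }, numeric(patch_side^2)))
  score <- drbm_predict(model, P)
  out <- tibble::tibble(image_id = image_id,
                        row = as.integer(candidates$row),
                        col = as.integer(candidates$col),
                        score = score, stage = "drbm")
  out[out$score >= theta_drbm, ]
}

#' Serialize a DRBM to versioned JSON
#'
#' @param model An `mc_drbm`.
#' @param path Output path.
#' @export
write_drbm <- function(model, path) {
  obj <- list(format = "mammocalc_drbm", version = 1L,
              n_visible = model$n_visible, n_hidden = model$n_hidden,
              W = as.numeric(model$W), U = as.numeric(model$U),
              b = model$b, c = model$c, d = model$d)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_drbm
#' @export
read_drbm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mammocalc_drbm")) {
    stop("not a mammocalc DRBM file", call. = FALSE)
  }
  structure(
    list(W = matrix(obj$W, obj$n_hidden, obj$n_visible),
         U = matrix(obj$U, obj$n_hidden, 2),
         b = obj$b, c = obj$c, d = obj$d,
         n_visible = as.integer(obj$n_visible),
         n_hidden = as.integer(obj$n_hidden), history = NULL),
    class = "mc_drbm"
  )
}

#' @export
print.mc_drbm <- function(x, ...) {
  cat(sprintf("<mc_drbm> %d visible, %d hidden", x$n_visible, x$n_hidden))
  if (!is.null(x$history) && nrow(x$history) > 0) {
    cat(sprintf("; trained %d epochs, final NLL/sample %.4f",
                max(x$history$epoch),
                x$history$nll[nrow(x$history)] /
                  max(1, attr(x$history, "n") %||% 1)))
  }
  cat("\n")
  invisible(x)
}

#' Tidy summaries of a DRBM
#'
#' @param x An `mc_drbm`.
#' @param ... Unused.
#' @return `tidy()`: one row per parameter block with its dimensions and
#'   norms; `glance()`: one-row model summary.
#' @export
tidy.mc_drbm <- function(x, ...) {
  blocks <- list(W = x$W, U = x$U, b = x$b, c = x$c, d = x$d)
  tibble::tibble(
    term = names(blocks),
    n = vapply(blocks, length, integer(1)),
    rms = vapply(blocks, function(p) sqrt(mean(p^2)), numeric(1)),
    max_abs = vapply(blocks, function(p) max(abs(p)), numeric(1))
  )
}

#' @rdname tidy.mc_drbm
#' @export
glance.mc_drbm <- function(x, ...) {
  tibble::tibble(
    n_visible = x$n_visible, n_hidden = x$n_hidden,
    n_epochs = if (is.null(x$history)) NA_integer_ else max(x$history$epoch),
    final_nll = if (is.null(x$history)) NA_real_ else
      x$history$nll[nrow(x$history)]
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
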