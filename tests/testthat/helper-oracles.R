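# Independent brute-force oracles. Deliberately naive: nested loops and
# exhaustive enumeration, never sharing code with the implementation.

# dense 2-D correlation with an explicit (non-separable) kernel matrix,
# edge-repeating reflection at the borders
oracle_conv2d <- function(m, kern) {
  kr <- (nrow(kern) - 1) / 2
  kc <- (ncol(kern) - 1) / 2
  refl <- function(i, n) {
    if (i < 1) 1 - i else if (i > n) 2 * n - i + 1 else i
  }
  out <- matrix(0, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) {
    for (c in seq_len(ncol(m))) {
      acc <- 0
      for (dr in -kr:kr) {
        for (dc in -kc:kc) {
          acc <- acc + kern[dr + kr + 1, dc + kc + 1] *
            m[refl(r + dr, nrow(m)), refl(c + dc, ncol(m))]
        }
      }
      out[r, c] <- acc
    }
  }
  out
}

# sampled 2-D derivative-of-Gaussian kernel (orders per axis), unit-integral
# continuous normalisation, for the convolution oracle
oracle_dog_kernel2d <- function(sigma, order_y, order_x,
                                radius = ceiling(4 * sigma)) {
  u <- seq(-radius, radius)
  g <- function(order) {
    phi <- exp(-u^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi))
    k <- switch(order + 1L, phi, -u / sigma^2 * phi,
                (u^2 - sigma^2) / sigma^4 * phi)
    if (order == 0L) k <- k / sum(k)
    if (order == 2L) k <- k - mean(k)
    k
  }
  outer(g(order_y), g(order_x))
}

# exact p(y | x) by enumerating every hidden configuration
oracle_drbm_prob <- function(model, x) {
  hs <- as.matrix(expand.grid(rep(list(0:1), model$n_hidden)))
  z <- vapply(0:1, function(y) {
    sum(exp(-apply(hs, 1, function(h) drbm_energy(model, y, x, h))))
  }, numeric(1))
  z / sum(z)
}

# queue flood fill, 8-connectivity
oracle_components <- function(map) {
  lab <- matrix(0L, nrow(map), ncol(map))
  nxt <- 0L
  for (r0 in seq_len(nrow(map))) {
    for (c0 in seq_len(ncol(map))) {
      if (!map[r0, c0] || lab[r0, c0] != 0L) next
      nxt <- nxt + 1L
      queue <- list(c(r0, c0))
      lab[r0, c0] <- nxt
      while (length(queue) > 0) {
        p <- queue[[1]]
        queue <- queue[-1]
        for (dr in -1:1) {
          for (dc in -1:1) {
            r <- p[1] + dr
            c <- p[2] + dc
            if (r >= 1 && r <= nrow(map) && c >= 1 && c <= ncol(map) &&
                map[r, c] && lab[r, c] == 0L) {
              lab[r, c] <- nxt
              queue[[length(queue) + 1]] <- c(r, c)
            }
          }
        }
      }
    }
  }
  lab
}

# nested-loop box sum with zero padding
oracle_box_sum <- function(m, side) {
  half <- (side - 1) / 2
  out <- matrix(0, nrow(m), ncol(m))
  for (r in seq_len(nrow(m))) {
    for (c in seq_len(ncol(m))) {
      rr <- max(1, r - half):min(nrow(m), r + half)
      cc <- max(1, c - half):min(ncol(m), c + half)
      out[r, c] <- sum(m[rr, cc])
    }
  }
  out
}

# exhaustive best information gain over every dimension and every midpoint
oracle_best_gain <- function(features, labels) {
  if (is.vector(features)) features <- matrix(features, ncol = 1)
  ent <- function(l) {
    p <- table(l) / length(l)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  best <- 0
  for (d in seq_len(ncol(features))) {
    u <- sort(unique(features[, d]))
    if (length(u) < 2) next
    for (tau in (u[-1] + u[-length(u)]) / 2) {
      lft <- features[, d] < tau
      g <- ent(labels) -
        mean(lft) * ent(labels[lft]) - mean(!lft) * ent(labels[!lft])
      best <- max(best, g)
    }
  }
  best
}

# exhaustive one-to-one point matching over all assignments (<= 5 points)
oracle_match_counts <- function(det, tru, tol) {
  nd <- nrow(det)
  nt <- nrow(tru)
  if (nd == 0 || nt == 0) return(c(tp = 0L, fp = nd, fn = nt))
  ok <- outer(det$row, tru$row, "-")^2 + outer(det$col, tru$col, "-")^2 <=
    tol^2
  k <- min(nd, nt)
  best <- 0L
  # try all injective partial assignments detection -> truth
  search <- function(i, used, count) {
    best <<- max(best, count)
    if (i > nd) return()
    search(i + 1, used, count)
    for (j in seq_len(nt)) {
      if (!used[j] && ok[i, j]) {
        used[j] <- TRUE
        search(i + 1, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  search(1L, logical(nt), 0L)
  c(tp = best, fp = nd - best, fn = nt - best)
}

# direct seed-neighbourhood + greedy reading of the pairwise cluster rule
oracle_rule1 <- function(pts, d_c1_px) {
  n <- nrow(pts)
  if (n < 3) return(list())
  dmat <- as.matrix(stats::dist(pts))
  cand <- list()
  for (s in seq_len(n)) {
    nb <- which(dmat[s, ] <= d_c1_px)
    nb <- nb[order(dmat[s, nb], nb)]
    mem <- integer(0)
    for (q in nb) {
      if (length(mem) == 0 || all(dmat[q, mem] <= d_c1_px)) mem <- c(mem, q)
    }
    if (length(mem) >= 3) cand[[length(cand) + 1]] <-
        list(seed = s, members = sort(mem))
  }
  if (length(cand) == 0) return(list())
  sz <- vapply(cand, function(x) length(x$members), integer(1))
  sd <- vapply(cand, `[[`, integer(1), "seed")
  ord <- order(-sz, pts[sd, 1], pts[sd, 2])
  kept <- list()
  used <- logical(n)
  for (i in ord) {
    m <- cand[[i]]$members
    if (any(used[m])) next
    used[m] <- TRUE
    kept[[length(kept) + 1]] <- m
  }
  kept
}

# small phantom spec used across tests (kept small so suites stay fast)
small_spec <- function(...) {
  phantom_spec(image_shape = c(192L, 192L), mc_count = 15L,
               ridge_count = 2L, ...)
}

# a modest trained cascade shared by the pipeline tests, trained once per
# test run on three small phantoms
test_models <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- test_config()
    train_ph <- lapply(100:102, function(s) {
      sp <- phantom_spec(image_shape = c(256L, 256L), mc_count = 25L)
      sp$seed <- as.integer(s)
      generate_phantom(sp)
    })
    cache <<- train_cascade(train_ph, cfg, seed = 5)
    cache
  }
})

test_config <- function() {
  cfg <- preset_config("phantom")
  cfg$n_trees <- 30L
  cfg$n_epochs <- 80L
  cfg
}
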