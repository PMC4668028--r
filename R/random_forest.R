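#' Shannon entropy of a binary label set
#'
#' Entropy in bits (log base 2), with the `0 * log 0 = 0` convention. The
#' base only rescales information gains and never changes which split wins.
#'
#' @param labels Vector of class labels (any type with two levels; for the
#'   detector, 0 = non-microcalcification, 1 = microcalcification).
#' @return Non-negative entropy in bits.
#' @export
shannon_entropy <- function(labels) {
  if (length(labels) == 0) stop("entropy of an empty set", call. = FALSE)
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Information gain of an axis-aligned split
#'
#' Parent entropy minus the size-weighted entropies of the two children
#' induced by the decision `x[phi] < tau` (left) vs `x[phi] >= tau` (right).
#' A split that leaves one side empty has gain 0.
#'
#' @param features Numeric matrix (samples x dimensions) or vector (1-D).
#' @param labels Class labels, one per sample.
#' @param phi 1-based feature dimension index.
#' @param tau Split threshold.
#' @return The information gain in bits.
#' @export
information_gain <- function(features, labels, phi = 1L, tau) {
  if (is.vector(features)) features <- matrix(features, ncol = 1)
  stopifnot(nrow(features) == length(labels), phi >= 1,
            phi <= ncol(features))
  left <- features[, phi] < tau
  if (all(left) || !any(left)) return(0)
  h <- shannon_entropy(labels)
  nl <- sum(left)
  n <- length(labels)
  h - nl / n * shannon_entropy(labels[left]) -
    (n - nl) / n * shannon_entropy(labels[!left])
}

#' Train a single decision tree
#'
#' At each node, `n_candidates` random decisions are drawn (dimension
#' uniform over features, threshold uniform between that dimension's min and
#' max at the node) and the information-gain maximiser is taken (ties go to
#' the first drawn). A node becomes a leaf when its labels are homogeneous,
#' the depth limit is reached, or every candidate would create a child with
#' fewer than `min_node_fraction` of the *full* training-set size. Leaf
#' posteriors are the empirical label frequencies. Uses the current RNG
#' state; seed the session (or call through [train_forest()]) for
#' reproducibility.
#'
#' @param features Numeric matrix, samples x dimensions.
#' @param labels Integer labels (0 = non-microcalcification, 1 =
#'   microcalcification).
#' @param max_depth Maximum node depth (root = 0).
#' @param min_node_fraction Minimum child size as a fraction of `n_total`.
#' @param n_candidates Random split candidates per node.
#' @param n_total Full training-set size the fraction refers to (defaults to
#'   `nrow(features)`; [train_forest()] passes the pre-bootstrap size).
#' @param exhaustive If `TRUE`, enumerate every dimension with thresholds at
#'   midpoints of consecutive sorted unique values instead of sampling
#'   (used for small-sample oracle checks).
#' @return A tree: data frame of nodes with columns `feature` (0 for a
#'   leaf), `threshold`, `left`, `right` (row indices; 0 for a leaf), `n`,
#'   `p1` (leaf posterior of the microcalcification class) and `depth`.
#' @export
train_tree <- function(features, labels, max_depth = 30L,
                       min_node_fraction = 0.01, n_candidates = 50L,
                       n_total = nrow(features), exhaustive = FALSE) {
  if (is.vector(features)) features <- matrix(features, ncol = 1)
  stopifnot(nrow(features) == length(labels), nrow(features) > 0)
  labels <- as.integer(labels)
  min_count <- min_node_fraction * n_total

  nodes <- list()
  grow <- function(idx, depth) {
    me <- length(nodes) + 1L
    nodes[[me]] <<- list(feature = 0L, threshold = NA_real_, left = 0L,
                         right = 0L, n = length(idx),
                         p1 = mean(labels[idx] == 1L), depth = depth)
    lab <- labels[idx]
    if (length(unique(lab)) < 2 || depth >= max_depth) return(me)

    x <- features[idx, , drop = FALSE]
    if (exhaustive) {
      cand <- do.call(rbind, lapply(seq_len(ncol(x)), function(d) {
        u <- sort(unique(x[, d]))
        if (length(u) < 2) return(NULL)
        data.frame(phi = d, tau = (u[-1] + u[-length(u)]) / 2)
      }))
      if (is.null(cand) || nrow(cand) == 0) return(me)
    } else {
      phi <- sample.int(ncol(x), n_candidates, replace = TRUE)
      lo <- apply(x, 2, min)[phi]
      hi <- apply(x, 2, max)[phi]
      cand <- data.frame(phi = phi, tau = runif(n_candidates, lo, hi))
    }

    best_gain <- -Inf
    best <- NULL
    h_parent <- shannon_entropy(lab)
    n <- length(idx)
    for (ci in seq_len(nrow(cand))) {
      lft <- x[, cand$phi[ci]] < cand$tau[ci]
      nl <- sum(lft)
      if (nl < min_count || n - nl < min_count) next
      g <- h_parent - nl / n * shannon_entropy(lab[lft]) -
        (n - nl) / n * shannon_entropy(lab[!lft])
      if (g > best_gain) {  # strict: ties keep the first drawn
        best_gain <- g
        best <- list(phi = cand$phi[ci], tau = cand$tau[ci], left = lft)
      }
    }
    if (is.null(best)) return(me)

    li <- grow(idx[best$left], depth + 1L)
    ri <- grow(idx[!best$left], depth + 1L)
    nodes[[me]]$feature <<- best$phi
    nodes[[me]]$threshold <<- best$tau
    nodes[[me]]$left <<- li
    nodes[[me]]$right <<- ri
    me
  }
  grow(seq_along(labels), 0L)
  do.call(rbind.data.frame, nodes)
}

#' Train the stage-1 random forest
#'
#' Each of `n_trees` trees is grown with [train_tree()] on a bootstrap
#' sample of the training data (same size as the data, drawn with
#' replacement), each with an independent RNG substream derived from `seed`;
#' the whole forest is deterministic given the seed. The forest posterior
#' for a feature vector is the plain average of the per-tree leaf
#' posteriors.
#'
#' @inheritParams train_tree
#' @param n_trees Number of trees.
#' @param seed Integer seed for bootstrap and split sampling.
#' @return An `mc_rf` object.
#' @export
train_forest <- function(features, labels, n_trees = 100L, max_depth = 30L,
                         min_node_fraction = 0.01, n_candidates = 50L,
                         seed = 1L) {
  if (is.vector(features)) features <- matrix(features, ncol = 1)
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) {
    stop("training data must contain both classes", call. = FALSE)
  }
  n <- nrow(features)
  set.seed(seed)
  tree_seeds <- sample.int(.Machine$integer.max - 1L, n_trees)
  trees <- vector("list", n_trees)
  for (t in seq_len(n_trees)) {
    set.seed(tree_seeds[t])
    boot <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- train_tree(features[boot, , drop = FALSE], labels[boot],
                             max_depth = max_depth,
                             min_node_fraction = min_node_fraction,
                             n_candidates = n_candidates, n_total = n)
  }
  forest <- structure(
    list(trees = trees, n_trees = n_trees, max_depth = max_depth,
         min_node_fraction = min_node_fraction,
         n_candidates = n_candidates, seed = seed,
         feature_length = ncol(features),
         feature_names = colnames(features)),
    class = "mc_rf"
  )
  forest$flat <- flatten_forest(forest)
  forest
}

flatten_forest <- function(forest) {
  sizes <- vapply(forest$trees, nrow, integer(1))
  offset <- cumsum(c(1L, head(sizes, -1)))
  shift <- rep(offset - 1L, sizes)
  feature <- unlist(lapply(forest$trees, `[[`, "feature"))
  left <- unlist(lapply(forest$trees, `[[`, "left"))
  right <- unlist(lapply(forest$trees, `[[`, "right"))
  internal <- feature != 0L
  left[internal] <- left[internal] + shift[internal]
  right[internal] <- right[internal] + shift[internal]
  list(tree_offset = offset,
       feature = as.integer(feature),
       threshold = as.numeric(unlist(lapply(forest$trees, `[[`, "threshold"))),
       left = as.integer(left), right = as.integer(right),
       p1 = as.numeric(unlist(lapply(forest$trees, `[[`, "p1"))))
}

#' Forest posterior probability of the microcalcification class
#'
#' The mean over trees of the leaf posterior reached by each feature vector.
#'
#' @param forest An `mc_rf` from [train_forest()].
#' @param features Feature matrix (samples x dimensions) or single vector.
#' @return Numeric vector of posteriors in `[0, 1]`.
#' @export
predict_posterior <- function(forest, features) {
  stopifnot(inherits(forest, "mc_rf"))
  if (is.vector(features)) features <- matrix(features, nrow = 1)
  if (ncol(features) != forest$feature_length) {
    stop(sprintf("feature length %d does not match forest (%d)",
                 ncol(features), forest$feature_length), call. = FALSE)
  }
  f <- forest$flat
  rcpp_forest_predict(features, f$tree_offset, f$feature, f$threshold,
                      f$left, f$right, f$p1)
}

#' Per-pixel posterior map from a feature map
#'
#' @param forest An `mc_rf`.
#' @param fmap An `mc_feature_map` from [feature_map()].
#' @return Numeric matrix of the image's shape with posteriors at mask
#'   pixels and 0 elsewhere.
#' @export
rf_posterior_map <- function(forest, fmap) {
  stopifnot(inherits(fmap, "mc_feature_map"))
  p <- predict_posterior(forest, fmap$features)
  out <- matrix(0, fmap$shape[1], fmap$shape[2])
  out[cbind(fmap$coords$row + 1, fmap$coords$col + 1)] <- p
  out
}

#' Threshold the forest posterior into a candidate map
#'
#' A mask pixel is flagged when its posterior is `>= theta_rf`. Operating
#' values are dataset profiles (see [preset_config()]); a permissive value
#' like 0.3 keeps stage 1 sensitive so the patch classifier can prune.
#'
#' @inheritParams rf_posterior_map
#' @param theta_rf Posterior threshold in `[0, 1]`.
#' @return Logical matrix of flagged pixels (the image's shape).
#' @export
classify_candidates <- function(forest, fmap, theta_rf) {
  stopifnot(theta_rf >= 0, theta_rf <= 1)
  p <- rf_posterior_map(forest, fmap)
  flagged <- matrix(FALSE, fmap$shape[1], fmap$shape[2])
  flagged[cbind(fmap$coords$row + 1, fmap$coords$col + 1)] <-
    p[cbind(fmap$coords$row + 1, fmap$coords$col + 1)] >= theta_rf
  flagged
}

#' Serialize a forest to versioned JSON
#'
#' @param forest An `mc_rf`.
#' @param path Output path.
#' @export
write_forest <- function(forest, path) {
  obj <- list(
    format = "mammocalc_rf", version = 1L,
    params = forest[c("n_trees", "max_depth", "min_node_fraction",
                      "n_candidates", "seed", "feature_length")],
    feature_names = forest$feature_names,
    trees = forest$trees
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_forest
#' @export
read_forest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mammocalc_rf")) {
    stop("not a mammocalc forest file", call. = FALSE)
  }
  forest <- structure(
    c(list(trees = lapply(obj$trees, as.data.frame)), obj$params,
      list(feature_names = obj$feature_names)),
    class = "mc_rf"
  )
  forest$flat <- flatten_forest(forest)
  forest
}

#' @export
print.mc_rf <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<mc_rf> %d trees, max depth %d, %d features; mean depth %.1f, mean leaves %.1f\n",
    x$n_trees, x$max_depth, x$feature_length, g$mean_depth, g$mean_leaves))
  invisible(x)
}

#' Tidy per-tree summaries of a forest
#'
#' @param x An `mc_rf`.
#' @param ... Unused.
#' @return One row per tree: `tree`, `n_nodes`, `n_leaves`, `depth`.
#' @export
tidy.mc_rf <- function(x, ...) {
  tibble::tibble(
    tree = seq_len(x$n_trees),
    n_nodes = vapply(x$trees, nrow, integer(1)),
    n_leaves = vapply(x$trees, function(t) sum(t$feature == 0L), integer(1)),
    depth = vapply(x$trees, function(t) max(t$depth), numeric(1))
  )
}

#' @rdname tidy.mc_rf
#' @return For `glance()`, a one-row tibble of forest-level summaries.
#' @export
glance.mc_rf <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(n_trees = x$n_trees, feature_length = x$feature_length,
                 max_depth = x$max_depth,
                 mean_depth = mean(td$depth),
                 mean_leaves = mean(td$n_leaves))
}
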