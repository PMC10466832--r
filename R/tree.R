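#' One-vs-one binary tasks
#'
#' Splits a multiclass dataset into the c(c-1)/2 unordered class-pair
#' tasks, each restricted to the rows of its two classes. Pairs involving a
#' class absent from this (sub)set are skipped with a warning.
#'
#' @param subset a \code{\link{labeled_dataset}}.
#' @return A list of tasks; each has \code{pair} (two class codes, global
#'   coding) and \code{idx} (row indices into the subset).
#' @export
make_ovo_tasks <- function(subset) {
  stopifnot(inherits(subset, "labeled_dataset"))
  present <- which(subset$class_counts > 0L)
  absent <- which(subset$class_counts == 0L)
  if (length(absent)) {
    warning("class(es) absent from subset, tasks skipped: ",
            paste(subset$class_names[absent], collapse = ", "))
  }
  if (length(present) < 2L) stop("need at least 2 classes present")
  tasks <- list()
  for (i in seq_along(present)) {
    for (j in seq_along(present)) {
      if (i < j) {
        pair <- c(present[i], present[j])
        tasks[[length(tasks) + 1L]] <-
          list(pair = pair, idx = which(subset$labels %in% pair))
      }
    }
  }
  tasks
}

# --- tree nodes ------------------------------------------------------------
# internal node: feature (column id), breaks, children (list), n, dist
# leaf: prob (length-2 over the task pair), majority (1 or 2, pair-local), n
new_leaf <- function(prob, n) {
  list(type = "leaf", prob = prob, majority = which.max(prob), n = n)
}

#' Grow a stump-spliced tree for one binary task
#'
#' The root is the stump from the (possibly exchanged) per-subset stump set
#' whose size-unweighted Gini, recomputed over the task's samples, is
#' smallest. Each root group becomes a branch; at every deeper node a fresh
#' stump is fit per not-yet-used feature on that branch's samples and the
#' best by the same criterion is spliced in. A branch becomes a leaf
#' (holding its empirical two-class distribution) when it is pure, holds
#' fewer than \code{theta} samples, or sits at \code{max_depth} stump
#' layers; an empty branch inherits its parent's distribution. Ties between
#' equally scoring features break toward the lower feature index, so
#' growth is deterministic.
#'
#' @param X numeric matrix of the task's samples (rows) by features.
#' @param y pair-local labels: 1 for the task's first class, 2 for the
#'   second.
#' @param stump_set a \code{stump_set} covering the columns of \code{X};
#'   NULL makes the root a refit stump like any deeper node.
#' @param theta minimum branch size to keep splitting; default
#'   \code{ceiling(nrow(X) / 10)} (one tenth of the task's root samples).
#' @param max_depth maximum number of stump layers (default 10).
#' @return A \code{stump_tree}: \code{root}, \code{theta},
#'   \code{max_depth}, \code{n_leaves}, \code{depth}.
#' @export
grow_stump_tree <- function(X, y, stump_set = NULL, theta = NULL,
                            max_depth = 10L) {
  n <- nrow(X)
  if (is.null(theta)) theta <- max(1L, ceiling(n / 10))
  stopifnot(theta >= 1L, max_depth >= 1L)
  root_dist <- if (n > 0L) tabulate(y, nbins = 2L) / n else c(0.5, 0.5)
  if (n < 2L || length(unique(y)) < 2L) {
    prob <- if (n < 2L) c(0.5, 0.5) else root_dist
    root <- new_leaf(prob, n)
    return(structure(list(root = root, theta = theta, max_depth = max_depth,
                          n_leaves = 1L, depth = 0L),
                     class = "stump_tree"))
  }
  pair_counts <- tabulate(y, nbins = 2L)  # tie-break: rarer class in task

  build <- function(idx, depth, used, parent_dist) {
    m <- length(idx)
    if (m == 0L) return(new_leaf(parent_dist, 0L))
    cnt <- tabulate(y[idx], nbins = 2L)
    dist <- cnt / m
    if (m < theta || any(cnt == 0L) || depth >= max_depth ||
        length(used) == ncol(X)) {
      return(new_leaf(dist, m))
    }
    avail <- setdiff(seq_len(ncol(X)), used)
    best <- NULL; best_g <- Inf; best_feat <- NA_integer_
    if (depth == 0L && !is.null(stump_set)) {
      # root: re-evaluate the shared pool's stumps on this task's samples
      for (j in avail) {
        s <- stump_set$stumps[[j]]
        if (s$u < 2L) next                   # a no-split stump cannot branch
        grp <- stump_group(s, X[idx, j])
        gc <- matrix(tabulate(grp + s$u * (y[idx] - 1L), nbins = s$u * 2L),
                     nrow = s$u)
        g <- gini_from_counts(gc)
        if (g < best_g - 1e-12) { best_g <- g; best <- s; best_feat <- j }
      }
    } else {
      for (j in avail) {
        s <- build_stump(X[idx, j], y[idx], n_classes = 2L,
                         class_counts = pair_counts, feature_index = j)
        if (s$u < 2L) next
        g <- modified_gini(s)
        if (g < best_g - 1e-12) { best_g <- g; best <- s; best_feat <- j }
      }
    }
    if (is.null(best)) return(new_leaf(dist, m))
    grp <- stump_group(best, X[idx, best_feat])
    kids <- lapply(seq_len(best$u), function(gz) {
      build(idx[grp == gz], depth + 1L, c(used, best_feat), dist)
    })
    list(type = "node", feature = best_feat, breaks = best$breaks,
         children = kids, n = m, dist = dist)
  }

  root <- build(seq_len(n), 0L, integer(0L), root_dist)
  st <- tree_stats_node(root)
  structure(list(root = root, theta = theta, max_depth = max_depth,
                 n_leaves = st[["leaves"]], depth = st[["depth"]]),
            class = "stump_tree")
}

# recursive recount of (leaves, depth); a bare leaf is depth 0, a lone
# root stump depth 1
tree_stats_node <- function(node) {
  if (node$type == "leaf") return(c(leaves = 1L, depth = 0L))
  kid <- vapply(node$children, tree_stats_node, c(leaves = 0L, depth = 0L))
  c(leaves = sum(kid["leaves", ]), depth = 1L + max(kid["depth", ]))
}

# route rows of X to leaf pair-probabilities (m x 2)
tree_leaf_probs <- function(tree, X) {
  out <- matrix(NA_real_, nrow(X), 2L)
  rec <- function(node, idx) {
    if (length(idx) == 0L) return(invisible())
    if (node$type == "leaf") {
      out[idx, 1L] <<- node$prob[1L]
      out[idx, 2L] <<- node$prob[2L]
      return(invisible())
    }
    grp <- findInterval(X[idx, node$feature], node$breaks, left.open = TRUE) + 1L
    for (gz in seq_along(node$children)) rec(node$children[[gz]], idx[grp == gz])
  }
  rec(tree$root, seq_len(nrow(X)))
  out
}

#' Fit a DST: one stump tree per one-vs-one task
#'
#' @param subset a \code{\link{labeled_dataset}} (typically one balanced
#'   bootstrap subset).
#' @param stump_set optional \code{stump_set} fit on the subset (after any
#'   cross-subset exchange); roots are drawn from it when given.
#' @param max_depth,leaf_frac stump-layer cap and the leaf-size fraction:
#'   each task stops splitting branches below
#'   \code{ceiling(leaf_frac * task size)} samples.
#' @return A \code{dst_classifier}: \code{trees}, \code{pairs} (2 x T
#'   matrix of global class codes), \code{class_names}, \code{subset_id}.
#' @export
dst_fit <- function(subset, stump_set = NULL, max_depth = 10L,
                    leaf_frac = 0.1) {
  stopifnot(inherits(subset, "labeled_dataset"))
  tasks <- make_ovo_tasks(subset)
  trees <- vector("list", length(tasks))
  pairs <- matrix(NA_integer_, 2L, length(tasks))
  for (t in seq_along(tasks)) {
    tk <- tasks[[t]]
    Xi <- subset$features[tk$idx, , drop = FALSE]
    yi <- ifelse(subset$labels[tk$idx] == tk$pair[1L], 1L, 2L)
    theta <- max(1L, ceiling(leaf_frac * length(tk$idx)))
    trees[[t]] <- grow_stump_tree(Xi, yi, stump_set = stump_set,
                                  theta = theta, max_depth = max_depth)
    pairs[, t] <- tk$pair
  }
  structure(list(trees = trees, pairs = pairs,
                 class_names = subset$class_names,
                 subset_id = if (is.null(stump_set)) NA_integer_
                             else stump_set$subset_id),
            class = "dst_classifier")
}

#' Soft-vote class probabilities from a DST
#'
#' Each pairwise tree routes a sample to a leaf and contributes that leaf's
#' two-class probability mass to the corresponding classes; the accumulated
#' vector is normalized to sum to 1.
#'
#' @param dst a fitted \code{dst_classifier}.
#' @param X feature matrix with the training columns.
#' @return n x C row-stochastic matrix (columns follow
#'   \code{dst$class_names}).
#' @export
dst_predict_proba <- function(dst, X) {
  stopifnot(inherits(dst, "dst_classifier"))
  X <- as.matrix(X)
  C <- length(dst$class_names)
  acc <- matrix(0, nrow(X), C)
  for (t in seq_along(dst$trees)) {
    lp <- tree_leaf_probs(dst$trees[[t]], X)
    acc[, dst$pairs[1L, t]] <- acc[, dst$pairs[1L, t]] + lp[, 1L]
    acc[, dst$pairs[2L, t]] <- acc[, dst$pairs[2L, t]] + lp[, 2L]
  }
  acc / rowSums(acc)
}
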