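# Independent brute-force references used across tests. These mirror the
# documented algorithms with literal list manipulation and O(n^2) loops,
# deliberately sharing no code with the package internals.

# Multi-branch stump reference: sort, form value runs, coalesce runs into
# positional occupancy bins, majority-label with the rarer-class tie-break,
# merge adjacent same-label bins, midpoint cut-points.
oracle_stump <- function(values, labels, n_classes, class_counts = NULL,
                         min_interval = 1L) {
  if (is.null(class_counts)) class_counts <- tabulate(labels, nbins = n_classes)
  ord <- order(values)
  vs <- values[ord]; ls <- labels[ord]
  p <- length(vs)
  runs <- list(); i <- 1L
  while (i <= p) {
    j <- i
    while (j < p && vs[j + 1L] == vs[i]) j <- j + 1L
    runs[[length(runs) + 1L]] <- list(value = vs[i], labs = ls[i:j],
                                      start0 = i - 1L)
    i <- j + 1L
  }
  if (is.null(min_interval)) {
    min_interval <- if (p / length(runs) >= 3) 1L
                    else as.integer(ceiling(sqrt(p)))
  }
  bins <- list()
  if (min_interval > 1L && length(runs) > 1L) {
    ids <- vapply(runs, function(r) {
      as.integer(r$start0 %/% min_interval + 1L)
    }, 1L)
    ids <- match(ids, unique(ids))
    for (b in sort(unique(ids))) {
      rs <- runs[ids == b]
      bins[[length(bins) + 1L]] <-
        list(labs = unlist(lapply(rs, `[[`, "labs")),
             first = rs[[1L]]$value, last = rs[[length(rs)]]$value)
    }
    nb <- length(bins)
    if (nb > 1L && length(bins[[nb]]$labs) < min_interval) {
      bins[[nb - 1L]] <- list(
        labs = c(bins[[nb - 1L]]$labs, bins[[nb]]$labs),
        first = bins[[nb - 1L]]$first, last = bins[[nb]]$last)
      bins[[nb]] <- NULL
    }
  } else {
    for (r in runs) {
      bins[[length(bins) + 1L]] <-
        list(labs = r$labs, first = r$value, last = r$value)
    }
  }
  maj_of <- function(labs) {
    cnt <- tabulate(labs, nbins = n_classes)
    cand <- which(cnt == max(cnt))
    cand[order(class_counts[cand], cand)][1L]
  }
  maj <- vapply(bins, function(b) maj_of(b$labs), 1L)
  groups <- list()
  for (b in seq_along(bins)) {
    if (length(groups) && maj[b] == groups[[length(groups)]]$maj) {
      g <- groups[[length(groups)]]
      g$labs <- c(g$labs, bins[[b]]$labs)
      g$last <- bins[[b]]$last
      groups[[length(groups)]] <- g
    } else {
      groups[[length(groups) + 1L]] <-
        list(maj = maj[b], labs = bins[[b]]$labs,
             first = bins[[b]]$first, last = bins[[b]]$last)
    }
  }
  u <- length(groups)
  breaks <- numeric(0L)
  if (u > 1L) {
    for (i in seq_len(u - 1L)) {
      breaks <- c(breaks, (groups[[i]]$last + groups[[i + 1L]]$first) / 2)
    }
  }
  dist <- t(vapply(groups, function(g) {
    tabulate(g$labs, nbins = n_classes) / length(g$labs)
  }, numeric(n_classes)))
  list(u = u, breaks = breaks,
       majority = vapply(groups, `[[`, 1L, "maj"),
       counts = vapply(groups, function(g) length(g$labs), 1L),
       distribution = dist,
       gini = sum(apply(dist, 1L, function(pr) 1 - sum(pr^2))))
}

# O(n^2) pair-counting AUC with half-credit for tied scores.
oracle_auc <- function(y, s) {
  pos <- which(y == 1L); neg <- which(y == 0L)
  won <- 0
  for (i in pos) for (j in neg) {
    won <- won + if (s[i] > s[j]) 1 else if (s[i] == s[j]) 0.5 else 0
  }
  won / (length(pos) * length(neg))
}

# Eq-style balanced class probabilities from raw counts.
oracle_alphas <- function(N) (1 / N) / sum(1 / N)

# small labeled dataset from a matrix + label codes
make_ds <- function(X, y, class_names = NULL, ...) {
  cn <- if (is.null(class_names)) paste0("C", sort(unique(y))) else class_names
  labeled_dataset(X, cn[y], class_names = cn, ...)
}

# a single-leaf stump_tree with the given pair probabilities
fake_leaf_tree <- function(prob) {
  structure(list(root = list(type = "leaf", prob = prob,
                             majority = which.max(prob), n = 10L),
                 theta = 1L, max_depth = 10L, n_leaves = 1L, depth = 0L),
            class = "stump_tree")
}

fake_dst <- function(trees, pairs, class_names) {
  structure(list(trees = trees, pairs = pairs, class_names = class_names,
                 subset_id = NA_integer_),
            class = "dst_classifier")
}
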