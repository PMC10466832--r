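#' Build the per-subset stump set
#'
#' Fits one multi-branch stump per feature on a bootstrap subset and caches
#' each stump's predicted class codes on the full training set — the
#' classification results the similarity measure compares.
#'
#' @param subset a \code{\link{labeled_dataset}} (one balanced bootstrap
#'   subset).
#' @param full_features feature matrix of the complete training set (same
#'   columns as the subset) used for the prediction cache.
#' @param subset_id integer tag.
#' @return A \code{stump_set}: \code{stumps} (one per column),
#'   \code{pred_cache} (n_full x v matrix of class codes),
#'   \code{subset_id}.
#' @export
build_stump_set <- function(subset, full_features, subset_id = NA_integer_) {
  stopifnot(inherits(subset, "labeled_dataset"))
  v <- ncol(subset$features)
  if (ncol(full_features) != v) stop("feature count mismatch")
  C <- length(subset$class_names)
  counts <- subset$class_counts
  stumps <- vector("list", v)
  cache <- matrix(NA_integer_, nrow(full_features), v)
  for (j in seq_len(v)) {
    s <- build_stump(subset$features[, j], subset$labels, n_classes = C,
                     class_counts = counts, feature_index = j)
    stumps[[j]] <- s
    cache[, j] <- s$majority[stump_group(s, full_features[, j])]
  }
  structure(list(stumps = stumps, pred_cache = cache,
                 subset_id = as.integer(subset_id)),
            class = "stump_set")
}

#' Cosine similarity of two stumps' predictions
#'
#' Similarity between two stumps is the cosine of their predicted
#' class-code vectors over the shared training set,
#' \eqn{\sum x_p y_p / \sqrt{\sum x_p^2 \sum y_p^2}}. With positive
#' 1-based codes the value lies in (0, 1]; proportional codings (e.g. all-1
#' vs all-2) score 1 even though the labels differ — a known quirk of the
#' integer coding, acceptable because such stumps are equally uninformative.
#'
#' @param pred_a,pred_b equal-length vectors of positive class codes.
#' @return A number in (0, 1].
#' @export
stump_similarity <- function(pred_a, pred_b) {
  if (length(pred_a) != length(pred_b)) {
    stop("prediction vectors differ in length")
  }
  sum(pred_a * pred_b) / sqrt(sum(pred_a^2) * sum(pred_b^2))
}

#' Pick each set's low-information stumps
#'
#' Within a stump set, each stump's similarity to every other stump of the
#' same set is summed; the top 50\% (floor) by similarity sum — the stumps
#' whose predictions say least beyond what the rest already say — become
#' that set's exchange candidates.
#'
#' @param sets list of \code{stump_set} objects (at least 2).
#' @return A list, per set, of candidate feature indices.
#' @export
select_exchange_candidates <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 stump sets")
  lapply(sets, function(st) {
    v <- ncol(st$pred_cache)
    if (v < 2L) return(integer(0L))
    M <- st$pred_cache
    nrm <- sqrt(colSums(M^2))
    S <- crossprod(M) / outer(nrm, nrm)
    sums <- colSums(S) - diag(S)         # exclude self-similarity
    take <- floor(v / 2)
    if (take == 0L) return(integer(0L))
    order(-sums, seq_len(v))[seq_len(take)]
  })
}

#' Exchange same-feature stumps across subsets
#'
#' Features flagged as low-information candidates in two or more sets are
#' eligible; a random selection of eligible features — capped at
#' \code{ceiling(proportion * stumps per set)} exchanged features per set —
#' has its stumps randomly permuted across the sets holding the feature as
#' a candidate. The multiset of stumps per feature over all sets is
#' conserved; only their assignment to subsets changes, letting information
#' move between bootstrap subsets.
#'
#' @param sets list of \code{stump_set} objects.
#' @param proportion fraction in [0, 1]; default 0.1 (one stump in ten).
#' @param candidates as returned by \code{\link{select_exchange_candidates}};
#'   computed when omitted.
#' @return The list of sets with stumps (and caches) permuted.
#' @export
exchange_stumps <- function(sets, proportion = 0.1, candidates = NULL) {
  stopifnot(proportion >= 0, proportion <= 1)
  if (length(sets) < 2L || proportion == 0) return(sets)
  if (is.null(candidates)) candidates <- select_exchange_candidates(sets)
  v <- ncol(sets[[1L]]$pred_cache)
  cap <- ceiling(proportion * v)
  # which sets hold each feature as a candidate
  holders <- lapply(seq_len(v), function(f) {
    which(vapply(candidates, function(cd) f %in% cd, logical(1L)))
  })
  shared <- which(lengths(holders) >= 2L)
  if (length(shared) == 0L) return(sets)
  shared <- shared[sample.int(length(shared))]   # random feature order
  budget <- rep.int(cap, length(sets))
  for (f in shared) {
    hs <- holders[[f]]
    hs <- hs[budget[hs] > 0L]
    if (length(hs) < 2L) next
    perm <- sample(length(hs))
    if (all(perm == seq_along(hs))) next       # identity draw: no trade
    from <- hs[perm]
    st <- lapply(from, function(i) sets[[i]]$stumps[[f]])
    pc <- lapply(from, function(i) sets[[i]]$pred_cache[, f])
    for (i in seq_along(hs)) {
      sets[[hs[i]]]$stumps[[f]] <- st[[i]]
      sets[[hs[i]]]$pred_cache[, f] <- pc[[i]]
    }
    moved <- hs[hs != from]
    budget[moved] <- budget[moved] - 1L
  }
  sets
}
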