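#' Build a multi-branch decision stump on one feature
#'
#' Samples are sorted by the feature value and partitioned into initial
#' intervals; each interval is labeled by its majority class; adjacent
#' intervals with the same majority label are merged into groups.
#' Cut-points sit at midpoints between adjacent groups' boundary values,
#' the first group opens at -Inf and the last closes at +Inf, so the
#' groups tile the real line with half-open intervals (lo, hi].
#'
#' Initial intervals are maximal runs of equal feature value. When values
#' repeat (the drug-signature case: one value per drug, many samples per
#' drug) each run already holds enough samples for a meaningful majority
#' and the per-value partition is used as is. When values are continuous
#' and runs are singletons, per-run majorities are vacuous (every
#' singleton is pure), so runs are coalesced into occupancy bins of at
#' least \code{min_interval} samples before labeling: run i joins bin
#' \code{floor(start_i / min_interval)} where \code{start_i} is the
#' 0-based sort position of the run's first sample, and a trailing bin
#' holding fewer than \code{min_interval} samples merges into its
#' predecessor. Value-run boundaries are never split. The adaptive
#' default keeps the per-value partition (\code{min_interval = 1}) when
#' the mean run occupancy p / #runs is at least 3 — values genuinely
#' repeat, as with per-drug signature features — and otherwise coalesces
#' to \code{ceiling(sqrt(p))}.
#'
#' Majority ties inside an interval go to the globally rarer class
#' (smaller \code{class_counts}), then to the lower class code, so stump
#' fitting is deterministic and minority-friendly.
#'
#' @param values length-p numeric feature vector (finite).
#' @param labels length-p integer class codes in 1..n_classes.
#' @param n_classes number of classes in the code space.
#' @param class_counts global per-class sample counts used for the
#'   tie-break; defaults to the counts within \code{labels}.
#' @param feature_index column id stored on the stump (bookkeeping).
#' @param min_interval minimum samples per initial interval before
#'   majority labeling; \code{NULL} (default) selects adaptively as
#'   described above, \code{1} forces the per-value partition.
#' @return A \code{decision_stump}: \code{breaks} (u-1 increasing
#'   cut-points), \code{distribution} (u x n_classes row-stochastic
#'   matrix), \code{majority} (per-group class codes, adjacent entries
#'   distinct), \code{counts} (per-group sample counts), \code{u},
#'   \code{feature_index}.
#' @examples
#' s <- build_stump(c(1, 2, 3, 4), c(1L, 1L, 2L, 2L), n_classes = 2L,
#'                  min_interval = 1L)
#' s$breaks      # 2.5
#' s$majority    # 1 2
#' @export
build_stump <- function(values, labels, n_classes,
                        class_counts = NULL, feature_index = NA_integer_,
                        min_interval = NULL) {
  p <- length(values)
  if (p == 0L) stop("cannot build a stump on zero samples")
  if (length(labels) != p) stop("values/labels length mismatch")
  if (any(!is.finite(values))) stop("non-finite feature values")
  if (is.null(class_counts)) class_counts <- tabulate(labels, nbins = n_classes)

  ord <- order(values)
  vs <- values[ord]
  ls <- labels[ord]

  # runs of equal feature value
  r <- rle(vs)
  nrun <- length(r$values)
  if (is.null(min_interval)) {
    min_interval <- if (p / nrun >= 3) 1L else ceiling(sqrt(p))
  }
  min_interval <- max(1L, as.integer(min_interval))

  if (min_interval > 1L && nrun > 1L) {
    start0 <- cumsum(c(0L, r$lengths[-nrun]))   # 0-based run starts
    bin <- start0 %/% min_interval + 1L
    bin <- match(bin, unique(bin))              # dense bin ids
    nbin <- bin[nrun]
    if (nbin > 1L && sum(r$lengths[bin == nbin]) < min_interval) {
      bin[bin == nbin] <- nbin - 1L             # underfull trailing bin
      nbin <- nbin - 1L
    }
  } else {
    bin <- seq_len(nrun)
    nbin <- nrun
  }

  # per-bin class counts and majority label
  samp_bin <- rep.int(bin, r$lengths)
  cnt <- matrix(tabulate(samp_bin + nbin * (ls - 1L),
                         nbins = nbin * n_classes),
                nrow = nbin, ncol = n_classes)
  maj <- majority_codes(cnt, class_counts)

  # merge adjacent same-label bins into groups
  g <- rle(maj)
  ngrp <- length(g$values)
  grp_of_bin <- rep.int(seq_len(ngrp), g$lengths)
  gcnt <- rowsum(cnt, group = grp_of_bin, reorder = TRUE)
  dimnames(gcnt) <- NULL

  breaks <- if (ngrp > 1L) {
    last_run_of_bin <- which(c(bin[-1L] != bin[-nrun], TRUE))
    last_bin_of_grp <- cumsum(g$lengths)
    lr <- last_run_of_bin[last_bin_of_grp[-ngrp]]
    (r$values[lr] + r$values[lr + 1L]) / 2
  } else numeric(0L)

  gsz <- rowSums(gcnt)
  structure(
    list(feature_index = as.integer(feature_index),
         breaks = breaks,
         distribution = gcnt / gsz,
         majority = g$values,
         counts = as.integer(gsz),
         u = ngrp),
    class = "decision_stump"
  )
}

# Vectorized per-row argmax with tie-break: rarer global class first, then
# lower code. Returns integer codes.
majority_codes <- function(cnt, class_counts) {
  n_classes <- ncol(cnt)
  pref <- order(order(class_counts, seq_len(n_classes)))  # rank; 1 = rarest
  mx <- do.call(pmax, lapply(seq_len(n_classes), function(j) cnt[, j]))
  rk <- matrix(rep(pref, each = nrow(cnt)), nrow(cnt), n_classes)
  rk[cnt < mx] <- Inf
  max.col(-rk, ties.method = "first")
}

#' Size-unweighted Gini impurity of a stump
#'
#' Sums \eqn{1 - \sum_j p_{j,z}^2} over the stump's u groups. Unlike the
#' classical criterion, each group contributes equally regardless of how
#' many samples it holds — leaf size carries no penalty — so the score
#' reflects how cleanly the feature's intervals separate classes across
#' the whole axis. Lower is better; 0 iff every group is pure.
#'
#' @param stump a fitted \code{decision_stump}.
#' @return A non-negative number in \code{[0, u * (1 - 1/c)]}.
#' @export
modified_gini <- function(stump) {
  stopifnot(inherits(stump, "decision_stump"))
  sum(1 - rowSums(stump$distribution^2))
}

# Same impurity from a raw group-count matrix (rows = groups); empty
# groups contribute 0.
gini_from_counts <- function(cnt) {
  sz <- rowSums(cnt)
  keep <- sz > 0
  if (!any(keep)) return(0)
  p <- cnt[keep, , drop = FALSE] / sz[keep]
  sum(1 - rowSums(p^2))
}

#' Route values through a stump
#'
#' Interval membership follows the half-open convention \code{lo < x <= hi}
#' used when rules are printed: a value equal to a cut-point belongs to the
#' left group.
#'
#' @param stump a fitted \code{decision_stump}.
#' @param values numeric vector (no NAs).
#' @return Integer vector of group indices in \code{1..u}.
#' @export
stump_group <- function(stump, values) {
  stopifnot(inherits(stump, "decision_stump"))
  if (anyNA(values)) stop("cannot route NA values through a stump")
  findInterval(values, stump$breaks, left.open = TRUE) + 1L
}

#' @rdname stump_group
#' @param value a single value.
#' @return \code{stump_predict}: a list with the containing
#'   \code{group_index} and that group's \code{class_distribution}.
#' @export
stump_predict <- function(stump, value) {
  g <- stump_group(stump, value)
  list(group_index = g, class_distribution = stump$distribution[g, ])
}

#' @export
print.decision_stump <- function(x, ...) {
  cat("<decision_stump> feature ", x$feature_index, ", ", x$u, " group(s)",
      if (x$u > 1L) paste0(", cuts at ",
                           paste(signif(x$breaks, 4L), collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}
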