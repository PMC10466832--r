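#' Class-balanced sampling plan
#'
#' Per-class sampling probabilities inversely proportional to class size,
#' \eqn{\alpha_j = (1/N_j) / \sum_{j'} 1/N_{j'}}: every sample of class j
#' is drawn with probability proportional to \eqn{\alpha_j}, i.e. to
#' \eqn{1/N_j}, so each class contributes equal total probability mass.
#' Minority classes are thus over-sampled and the expected class shares of
#' a bootstrap subset are equal (1/C each).
#'
#' @param ds a \code{\link{labeled_dataset}}.
#' @param subset_size number of draws per subset (default n, the standard
#'   bootstrap size).
#' @return A \code{sampling_plan}: \code{alphas} (length-C, sums to 1),
#'   \code{weights} (length-n per-sample probabilities, sum to 1),
#'   \code{subset_size}.
#' @examples
#' ds <- generate_synthetic(synth_config(n_samples = 60, seed = 1))
#' sampling_plan(ds)$alphas
#' @export
sampling_plan <- function(ds, subset_size = NULL) {
  stopifnot(inherits(ds, "labeled_dataset"))
  N <- ds$class_counts
  inv <- ifelse(N > 0L, 1 / N, 0)          # empty classes leave the sum
  alphas <- inv / sum(inv)
  w <- alphas[ds$labels]
  structure(list(alphas = alphas, weights = w / sum(w),
                 subset_size = if (is.null(subset_size)) nrow(ds$features)
                               else as.integer(subset_size)),
            class = "sampling_plan")
}

#' Draw one balanced bootstrap subset
#'
#' Samples \code{plan$subset_size} rows with replacement under the plan's
#' per-sample weights.
#'
#' @param ds a \code{\link{labeled_dataset}}.
#' @param plan a \code{\link{sampling_plan}} derived from \code{ds}
#'   (computed when omitted).
#' @return A \code{labeled_dataset} of the drawn rows.
#' @export
balanced_sample <- function(ds, plan = NULL) {
  if (is.null(plan)) plan <- sampling_plan(ds)
  idx <- sample.int(nrow(ds$features), size = plan$subset_size,
                    replace = TRUE, prob = plan$weights)
  subset_dataset(ds, idx)
}

#' EDST configuration
#'
#' Defaults follow the method's published hyperparameters: 100 retained
#' trees, 10\% stump exchange, tree depth capped at 10 stump layers,
#' branches below 10\% of a task's samples become leaves, and 300
#' chi-square-selected features.
#'
#' @param m number of retained DSTs (2m candidates are trained).
#' @param exchange_prop fraction of each subset's stumps that may be
#'   exchanged.
#' @param max_depth stump-layer cap per tree.
#' @param leaf_frac minimum branch size as a fraction of each binary
#'   task's root sample count.
#' @param k number of features kept by chi-square selection.
#' @param scale apply min-max scaling before selection (recommended;
#'   chi-square needs non-negative features).
#' @param sampling \code{"balanced"} (inverse-class-size weights) or
#'   \code{"uniform"} (plain bootstrap; for ablation).
#' @param score candidate ranking criterion on the full training set.
#' @param seed integer seed making the whole fit reproducible.
#' @return A list of class \code{edst_config}.
#' @export
edst_config <- function(m = 100L, exchange_prop = 0.1, max_depth = 10L,
                        leaf_frac = 0.1, k = 300L, scale = TRUE,
                        sampling = c("balanced", "uniform"),
                        score = c("macro_f1", "accuracy"), seed = 1L) {
  stopifnot(m >= 1L, exchange_prop >= 0, exchange_prop <= 1,
            max_depth >= 1L, leaf_frac > 0, leaf_frac <= 1, k >= 1L)
  structure(list(m = as.integer(m), exchange_prop = exchange_prop,
                 max_depth = as.integer(max_depth), leaf_frac = leaf_frac,
                 k = as.integer(k), scale = isTRUE(scale),
                 sampling = match.arg(sampling), score = match.arg(score),
                 seed = as.integer(seed)),
            class = "edst_config")
}

#' Fit an EDST ensemble
#'
#' Pipeline: min-max scale (optional), chi-square feature selection, 2m
#' balanced bootstrap subsets, one stump set per subset, cross-subset
#' exchange of low-information stumps, one DST per subset, then the m
#' candidates scoring best on the full training set are retained. A drawn
#' subset containing a single class is redrawn (up to 5 retries).
#'
#' @param ds training \code{\link{labeled_dataset}}.
#' @param config an \code{\link{edst_config}}.
#' @return An \code{edst_model}: \code{dsts} (m retained classifiers),
#'   \code{selection_scores} (all 2m candidate scores, training set),
#'   \code{retained} (indices of the kept candidates), \code{scaler},
#'   \code{selection}, \code{config}, \code{class_names},
#'   \code{class_counts}, \code{feature_names}.
#' @export
edst_fit <- function(ds, config = edst_config()) {
  stopifnot(inherits(ds, "labeled_dataset"), inherits(config, "edst_config"))
  set.seed(config$seed)
  scaler <- NULL
  work <- ds
  if (config$scale) {
    scaler <- fit_minmax(work)
    work <- apply_minmax(work, scaler)
  }
  sel <- chi2_select(work, k = min(config$k, ncol(work$features)))
  work <- apply_selection(work, sel)

  plan <- sampling_plan(work)
  if (config$sampling == "uniform") {
    plan$weights <- rep(1 / nrow(work$features), nrow(work$features))
  }
  n_cand <- 2L * config$m
  subsets <- vector("list", n_cand)
  for (b in seq_len(n_cand)) {
    for (try in seq_len(5L)) {
      sub <- balanced_sample(work, plan)
      if (sum(sub$class_counts > 0L) >= 2L) break
      if (try == 5L) stop("degenerate single-class subsets after 5 retries")
    }
    subsets[[b]] <- sub
  }
  sets <- lapply(seq_len(n_cand), function(b) {
    build_stump_set(subsets[[b]], work$features, subset_id = b)
  })
  if (config$exchange_prop > 0 && n_cand >= 2L) {
    sets <- exchange_stumps(sets, proportion = config$exchange_prop)
  }
  dsts <- lapply(seq_len(n_cand), function(b) {
    dst_fit(subsets[[b]], sets[[b]], max_depth = config$max_depth,
            leaf_frac = config$leaf_frac)
  })

  scores <- vapply(dsts, function(d) {
    pr <- dst_predict_proba(d, work$features)
    yhat <- argmax_rare(pr, work$class_counts)
    if (config$score == "macro_f1") macro_f1(work$labels, yhat,
                                             length(work$class_names))
    else mean(yhat == work$labels)
  }, numeric(1L))
  keep <- order(-scores, seq_len(n_cand))[seq_len(config$m)]

  structure(
    list(dsts = dsts[keep], selection_scores = scores, retained = keep,
         scaler = scaler, selection = sel, config = config,
         class_names = ds$class_names, class_counts = ds$class_counts,
         feature_names = ds$feature_names),
    class = "edst_model"
  )
}

# argmax per row; ties go to the rarer training class, then lower code
argmax_rare <- function(prob, class_counts) {
  pref <- order(order(class_counts, seq_along(class_counts)))
  mx <- do.call(pmax, lapply(seq_len(ncol(prob)), function(j) prob[, j]))
  rk <- matrix(rep(pref, each = nrow(prob)), nrow(prob))
  rk[prob < mx - 1e-12] <- Inf
  max.col(-rk, ties.method = "first")
}

macro_f1 <- function(y, yhat, C) {
  f1 <- vapply(seq_len(C), function(j) {
    tp <- sum(y == j & yhat == j)
    fp <- sum(y != j & yhat == j)
    fn <- sum(y == j & yhat != j)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1L))
  mean(f1)
}

# push new data through the model's stored scaler + feature selection
model_transform <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != length(model$feature_names)) {
    stop("expected ", length(model$feature_names), " features, got ", ncol(X))
  }
  if (!is.null(model$scaler)) {
    rng <- model$scaler$max - model$scaler$min
    rng[rng <= 0] <- Inf
    X <- sweep(sweep(X, 2L, model$scaler$min, "-"), 2L, rng, "/")
  }
  X[, model$selection$selected, drop = FALSE]
}

#' Predict with an EDST ensemble
#'
#' The m retained DSTs vote probabilistically: their per-class probability
#' rows are averaged and renormalized. \code{edst_predict} takes the
#' arg-max, breaking ties toward the rarer training class.
#'
#' @param model a fitted \code{edst_model}.
#' @param X feature matrix in the training schema (untransformed; the
#'   model's scaler and selection are applied internally), or a
#'   \code{labeled_dataset}.
#' @return \code{edst_predict_proba}: n x C row-stochastic matrix;
#'   \code{edst_predict}: character class labels.
#' @export
edst_predict_proba <- function(model, X) {
  stopifnot(inherits(model, "edst_model"))
  if (inherits(X, "labeled_dataset")) X <- X$features
  Xt <- model_transform(model, X)
  acc <- matrix(0, nrow(Xt), length(model$class_names))
  for (d in model$dsts) acc <- acc + dst_predict_proba(d, Xt)
  acc / rowSums(acc)
}

#' @rdname edst_predict_proba
#' @export
edst_predict <- function(model, X) {
  pr <- edst_predict_proba(model, X)
  model$class_names[argmax_rare(pr, model$class_counts)]
}

#' Node-frequency feature importance
#'
#' A feature's importance is the frequency with which the ensemble's tree
#' nodes (all retained DSTs, all pairwise trees, all depths) split on it,
#' normalized to sum to 1. Also returns the smallest feature set whose
#' cumulative importance reaches \code{threshold} (the "about 90\%
#' contribution" convention).
#'
#' @param model a fitted \code{edst_model}.
#' @param threshold cumulative-contribution cutoff in (0, 1].
#' @return A list: \code{importance} (named numeric, descending, original
#'   feature names; only used features appear) and \code{top_set}
#'   (feature names reaching the threshold).
#' @export
feature_importance <- function(model, threshold = 0.9) {
  stopifnot(inherits(model, "edst_model"), threshold > 0, threshold <= 1)
  counts <- numeric(length(model$selection$selected))
  visit <- function(node) {
    if (node$type == "leaf") return(invisible())
    counts[node$feature] <<- counts[node$feature] + 1
    for (ch in node$children) visit(ch)
  }
  for (d in model$dsts) for (tr in d$trees) visit(tr$root)
  if (sum(counts) == 0) {
    return(list(importance = setNames(numeric(0L), character(0L)),
                top_set = character(0L)))
  }
  imp <- counts / sum(counts)
  names(imp) <- model$feature_names[model$selection$selected]
  imp <- imp[imp > 0]
  imp <- imp[order(-imp, match(names(imp), model$feature_names))]
  cum <- cumsum(imp)
  top_n <- which(cum >= threshold - 1e-12)[1L]
  list(importance = imp, top_set = names(imp)[seq_len(top_n)])
}

#' Ensemble tree-complexity statistics
#'
#' Mean maximum depth (stump layers; a lone root stump counts 1, a bare
#' leaf 0) and mean leaf count over all pairwise trees of all retained
#' DSTs, recomputed by recursive traversal.
#'
#' @param model a fitted \code{edst_model} (or a single
#'   \code{dst_classifier}).
#' @return A list: \code{mean_max_depth}, \code{mean_leaf_count},
#'   \code{per_tree} (data frame with one row per pairwise tree).
#' @export
complexity_stats <- function(model) {
  dsts <- if (inherits(model, "dst_classifier")) list(model)
          else { stopifnot(inherits(model, "edst_model")); model$dsts }
  rows <- list()
  for (d in dsts) {
    for (tr in d$trees) {
      st <- tree_stats_node(tr$root)
      rows[[length(rows) + 1L]] <-
        data.frame(depth = st[["depth"]], leaves = st[["leaves"]])
    }
  }
  per_tree <- do.call(rbind, rows)
  list(mean_max_depth = mean(per_tree$depth),
       mean_leaf_count = mean(per_tree$leaves),
       per_tree = per_tree)
}

#' @export
print.edst_model <- function(x, ...) {
  cat("<edst_model> ", length(x$dsts), " DSTs over ",
      length(x$class_names), " classes (",
      paste(x$class_names, collapse = ", "), ")\n", sep = "")
  cat("  features kept: ", length(x$selection$selected), " of ",
      length(x$feature_names), "; seed ", x$config$seed, "\n", sep = "")
  cs <- complexity_stats(x)
  cat(sprintf("  mean max depth %.2f, mean leaf count %.2f\n",
              cs$mean_max_depth, cs$mean_leaf_count))
  invisible(x)
}
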