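#' Classification metrics for imbalanced multiclass problems
#'
#' Per-class one-vs-rest confusion counts, precision = TP/(TP+FP),
#' recall = TP/(TP+FN), F1 = their harmonic mean (any 0/0 yields 0 with a
#' warning), macro-F1 over all classes, rank-based AUC (macro one-vs-rest
#' when probabilities are supplied), and F1* — the unweighted mean of the
#' designated minority classes' F1 scores, summarizing how well the rare
#' classes are recovered.
#'
#' @param y_true integer codes or class-name labels.
#' @param y_pred same coding as \code{y_true}.
#' @param y_proba optional n x C row-stochastic matrix (needed for AUC).
#' @param class_names the class inventory (required when labels are codes).
#' @param minority_classes class names treated as minorities for F1*;
#'   default: every class except the largest in \code{y_true}.
#' @return A \code{class_metrics} list: \code{per_class} data frame (TP,
#'   FP, TN, FN, precision, recall, f1, auc), \code{macro_f1},
#'   \code{f1_star}, \code{auc}, \code{accuracy}.
#' @export
compute_metrics <- function(y_true, y_pred, y_proba = NULL,
                            class_names = NULL, minority_classes = NULL) {
  if (is.null(class_names)) {
    class_names <- sort(unique(as.character(y_true)))
  }
  C <- length(class_names)
  to_code <- function(y) {
    if (is.numeric(y)) {
      if (any(y < 1 | y > C)) stop("label code outside inventory 1..", C)
      as.integer(y)
    } else {
      cd <- match(as.character(y), class_names)
      if (anyNA(cd)) stop("label outside inventory: ",
                          paste(unique(y[is.na(cd)]), collapse = ", "))
      cd
    }
  }
  yt <- to_code(y_true); yp <- to_code(y_pred)
  if (length(yt) != length(yp)) stop("y_true / y_pred length mismatch")
  n <- length(yt)
  tab <- data.frame(class = class_names, TP = NA_real_, FP = NA_real_,
                    TN = NA_real_, FN = NA_real_, precision = NA_real_,
                    recall = NA_real_, f1 = NA_real_, auc = NA_real_)
  zdiv <- FALSE
  for (j in seq_len(C)) {
    tp <- sum(yt == j & yp == j); fp <- sum(yt != j & yp == j)
    fn <- sum(yt == j & yp != j); tn <- n - tp - fp - fn
    pr <- if (tp + fp == 0) { zdiv <- TRUE; 0 } else tp / (tp + fp)
    rc <- if (tp + fn == 0) { zdiv <- TRUE; 0 } else tp / (tp + fn)
    f1 <- if (pr + rc == 0) 0 else 2 * pr * rc / (pr + rc)
    tab[j, 2:8] <- c(tp, fp, tn, fn, pr, rc, f1)
    if (!is.null(y_proba) && length(unique(yt == j)) == 2L) {
      tab$auc[j] <- auc_rank(as.integer(yt == j), y_proba[, j])
    }
  }
  if (zdiv) warning("zero-division in precision/recall set to 0")
  if (is.null(minority_classes)) {
    cnt <- tabulate(yt, nbins = C)
    minority_classes <- class_names[-which.max(cnt)]
  }
  mi <- match(minority_classes, class_names)
  if (anyNA(mi)) stop("unknown minority class name(s)")
  structure(
    list(per_class = tab,
         macro_f1 = mean(tab$f1),
         f1_star = mean(tab$f1[mi]),
         auc = if (all(is.na(tab$auc))) NA_real_
               else mean(tab$auc, na.rm = TRUE),
         accuracy = mean(yt == yp),
         minority_classes = minority_classes),
    class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("macro-F1 %.4f | F1* %.4f | AUC %s | accuracy %.4f\n",
              x$macro_f1, x$f1_star,
              if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc),
              x$accuracy))
  print(x$per_class, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Samples are ranked by score from smallest to largest (midranks for
#' ties); AUC is the rank-sum statistic
#' \eqn{(\sum_{i \in pos} rank_i - n_+(n_+ + 1)/2) / (n_+ n_-)},
#' the probability a random positive outranks a random negative.
#'
#' @param y_bin 0/1 vector (both classes present).
#' @param scores predicted probabilities (or any monotone score).
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(y_bin, scores) {
  if (length(y_bin) != length(scores)) stop("length mismatch")
  if (!all(y_bin %in% c(0L, 1L))) stop("y_bin must be 0/1")
  npos <- sum(y_bin == 1L); nneg <- sum(y_bin == 0L)
  if (npos == 0L || nneg == 0L) {
    stop("AUC undefined: only one class present")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y_bin == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# stratified fold assignment: within each class, shuffled round-robin
stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (j in unique(labels)) {
    idx <- which(labels == j)
    if (length(idx) < k) {
      warning("class ", j, " has fewer than ", k,
              " members; folds will miss it")
    }
    fold[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(k), length(idx))
  }
  fold
}

# fit on train rows, score on test rows; shared by both CV drivers
eval_fold <- function(ds, train_idx, test_idx, config) {
  model <- edst_fit(subset_dataset(ds, train_idx), config)
  test <- subset_dataset(ds, test_idx)
  proba <- edst_predict_proba(model, test$features)
  pred <- model$class_names[argmax_rare(proba, model$class_counts)]
  cs <- complexity_stats(model)
  m <- compute_metrics(ds$class_names[test$labels], pred, proba,
                       class_names = ds$class_names)
  m$mean_max_depth <- cs$mean_max_depth
  m$mean_leaf_count <- cs$mean_leaf_count
  m
}

summarize_folds <- function(per_fold) {
  pick <- function(f) vapply(per_fold, function(m) {
    x <- m[[f]]; if (is.null(x) || is.na(x)) NA_real_ else x
  }, numeric(1L))
  fields <- c("macro_f1", "f1_star", "auc", "accuracy",
              "mean_max_depth", "mean_leaf_count")
  means <- vapply(fields, function(f) mean(pick(f), na.rm = TRUE),
                  numeric(1L))
  sds <- vapply(fields, function(f) stats::sd(pick(f), na.rm = TRUE),
                numeric(1L))
  list(mean = as.list(means), sd = as.list(sds), folds = per_fold)
}

#' Stratified k-fold cross-validation of EDST
#'
#' Folds preserve class ratios; the scaler and chi-square selection are
#' refit inside every training fold (no leakage). Defaults to the
#' five-fold protocol (80/20 splits).
#'
#' @param ds a \code{\link{labeled_dataset}}.
#' @param config an \code{\link{edst_config}} (its seed offsets per-fold
#'   fitting; the CV seed controls fold assignment).
#' @param k number of folds.
#' @param seed fold-assignment seed.
#' @return A list: \code{mean}, \code{sd} (over folds, for macro-F1, F1*,
#'   AUC, accuracy and complexity), \code{folds} (per-fold
#'   \code{class_metrics}).
#' @export
kfold_cv <- function(ds, config = edst_config(), k = 5L, seed = 1L) {
  stopifnot(inherits(ds, "labeled_dataset"), k >= 2L)
  set.seed(seed)
  fold <- stratified_folds(ds$labels, k)
  per_fold <- lapply(seq_len(k), function(f) {
    cfg <- config
    cfg$seed <- config$seed + f
    eval_fold(ds, which(fold != f), which(fold == f), cfg)
  })
  summarize_folds(per_fold)
}

#' Leave-drug-combinations-out split plan
#'
#' Distinct drug identifiers are randomly partitioned into t groups; fold
#' g tests every sample containing any drug of group g and trains on the
#' rest, so performance is measured on combinations of entirely unseen
#' drugs. A sample pairing drugs from two different groups is tested in
#' both corresponding folds and trains in neither.
#'
#' @param ds a \code{\link{labeled_dataset}} with \code{drug_pairs}.
#' @param t number of drug groups (default 6).
#' @param seed partition seed.
#' @return A \code{split_plan}: \code{strategy}, \code{groups} (named list
#'   drug-ID vectors), \code{folds} (per fold: \code{train}, \code{test}
#'   row indices), \code{seed}.
#' @export
leave_drug_combinations_out <- function(ds, t = 6L, seed = 1L) {
  stopifnot(inherits(ds, "labeled_dataset"))
  if (is.null(ds$drug_pairs)) stop("dataset has no drug_pairs")
  stopifnot(t >= 2L)
  set.seed(seed)
  drugs <- sort(unique(as.vector(ds$drug_pairs)))
  if (length(drugs) < t) stop("fewer distinct drugs (", length(drugs),
                              ") than groups (", t, ")")
  grp <- rep_len(seq_len(t), length(drugs))[sample.int(length(drugs))]
  groups <- split(drugs, grp)
  names(groups) <- paste0("group", seq_len(t))
  folds <- lapply(groups, function(g) {
    in_test <- ds$drug_pairs[, 1L] %in% g | ds$drug_pairs[, 2L] %in% g
    list(train = which(!in_test), test = which(in_test))
  })
  structure(list(strategy = "leave_drug_out", groups = groups,
                 folds = folds, seed = seed),
            class = "split_plan")
}

#' Leave-drug-combinations-out cross-validation of EDST
#'
#' Runs \code{\link{edst_fit}} over the folds of
#' \code{\link{leave_drug_combinations_out}}. Folds whose training or test
#' part misses a second class are skipped with a warning.
#'
#' @inheritParams kfold_cv
#' @param t number of drug groups.
#' @return As \code{\link{kfold_cv}}.
#' @export
leave_drug_out_cv <- function(ds, config = edst_config(), t = 6L,
                              seed = 1L) {
  plan <- leave_drug_combinations_out(ds, t = t, seed = seed)
  per_fold <- list()
  for (f in seq_along(plan$folds)) {
    tr <- plan$folds[[f]]$train; te <- plan$folds[[f]]$test
    if (length(unique(ds$labels[tr])) < 2L || length(te) == 0L) {
      warning("fold ", f, " skipped (degenerate split)")
      next
    }
    cfg <- config
    cfg$seed <- config$seed + f
    per_fold[[length(per_fold) + 1L]] <- eval_fold(ds, tr, te, cfg)
  }
  summarize_folds(per_fold)
}
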