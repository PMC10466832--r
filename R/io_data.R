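#' Construct a labeled dataset
#'
#' The universal input container: a numeric feature matrix, one categorical
#' label per row, and optionally the two drug identifiers that formed each
#' sample (needed for leave-drug-combinations-out splitting). Class labels
#' are mapped to integer codes \code{1..C} in stable sorted order of the
#' distinct labels; the original strings are kept in \code{class_names}.
#'
#' @param features numeric matrix or data frame, n samples x v features.
#'   No missing values are allowed (samples with missing features must be
#'   removed upstream).
#' @param labels length-n vector of class labels (character, factor or
#'   integer); at least two distinct classes.
#' @param drug_pairs optional n x 2 matrix/data frame of drug identifiers.
#' @param feature_names optional length-v character vector; defaults to
#'   \code{"feature i"} with 1-based i, the convention used when printing
#'   rules.
#' @param class_names optional explicit class inventory (sorted order is
#'   used when omitted).
#' @return An object of class \code{labeled_dataset}: a list with
#'   \code{features} (matrix), \code{labels} (integer codes 1..C),
#'   \code{class_names}, \code{class_counts}, \code{drug_pairs} (or NULL)
#'   and \code{feature_names}.
#' @examples
#' ds <- labeled_dataset(matrix(runif(12), 4, 3), c("A", "A", "B", "C"))
#' ds$class_counts
#' @export
labeled_dataset <- function(features, labels, drug_pairs = NULL,
                            feature_names = NULL, class_names = NULL) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  n <- nrow(features)
  v <- ncol(features)
  if (length(labels) != n) {
    stop("labels length (", length(labels), ") != number of rows (", n, ")")
  }
  if (anyNA(features) || any(!is.finite(features))) {
    bad <- which(!is.finite(features), arr.ind = TRUE)[1L, ]
    stop("non-finite feature value at row ", bad[1L], ", column ", bad[2L])
  }
  lab_chr <- as.character(labels)
  if (anyNA(lab_chr)) stop("missing labels at rows: ",
                           paste(which(is.na(lab_chr)), collapse = ", "))
  if (is.null(class_names)) {
    class_names <- sort(unique(lab_chr))
  } else if (!all(lab_chr %in% class_names)) {
    stop("labels outside the declared class inventory: ",
         paste(setdiff(lab_chr, class_names), collapse = ", "))
  }
  C <- length(class_names)
  if (C < 2L) stop("need at least 2 classes, got ", C)
  if (n < C) stop("need n >= C (", n, " samples for ", C, " classes)")
  codes <- match(lab_chr, class_names)
  counts <- tabulate(codes, nbins = C)
  if (any(counts < 1L)) {
    stop("empty class(es): ", paste(class_names[counts < 1L], collapse = ", "))
  }
  if (!is.null(drug_pairs)) {
    drug_pairs <- as.matrix(drug_pairs)
    if (nrow(drug_pairs) != n || ncol(drug_pairs) != 2L) {
      stop("drug_pairs must be an n x 2 matrix of drug identifiers")
    }
    storage.mode(drug_pairs) <- "character"
  }
  if (is.null(feature_names)) {
    feature_names <- paste("feature", seq_len(v))
  } else if (length(feature_names) != v) {
    stop("feature_names length != number of features")
  }
  structure(
    list(features = features, labels = codes, class_names = class_names,
         class_counts = counts, drug_pairs = drug_pairs,
         feature_names = feature_names),
    class = "labeled_dataset"
  )
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> ", nrow(x$features), " samples x ",
      ncol(x$features), " features, ", length(x$class_names), " classes\n",
      sep = "")
  cat("  classes: ",
      paste0(x$class_names, " (", x$class_counts, ")", collapse = ", "),
      "\n", sep = "")
  if (!is.null(x$drug_pairs)) {
    cat("  drug pairs over", length(unique(as.vector(x$drug_pairs))),
        "distinct drugs\n")
  }
  invisible(x)
}

# Row subset keeping metadata; class inventory is preserved (codes stay
# comparable across subsets) even if a class drops out of the rows.
subset_dataset <- function(ds, idx) {
  structure(
    list(features = ds$features[idx, , drop = FALSE],
         labels = ds$labels[idx],
         class_names = ds$class_names,
         class_counts = tabulate(ds$labels[idx],
                                 nbins = length(ds$class_names)),
         drug_pairs = if (is.null(ds$drug_pairs)) NULL
                      else ds$drug_pairs[idx, , drop = FALSE],
         feature_names = ds$feature_names),
    class = "labeled_dataset"
  )
}

#' Load a labeled dataset from delimited text
#'
#' Reads a CSV/TSV file with a header row, one label column, optionally two
#' drug-identifier columns, and numeric feature columns for everything else.
#'
#' @param path file path; comma- or tab-delimited (inferred from the
#'   extension, override with \code{sep}).
#' @param label_column name of the label column.
#' @param drug_columns optional character vector of the two drug-ID column
#'   names.
#' @param sep field separator; default "," unless the path ends in
#'   \code{.tsv}/\code{.txt} (then tab).
#' @return A \code{\link{labeled_dataset}}.
#' @export
load_dataset <- function(path, label_column = "label", drug_columns = NULL,
                         sep = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(sep)) sep <- if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  raw <- read.csv(path, sep = sep, check.names = FALSE,
                  colClasses = "character")
  if (!label_column %in% names(raw)) {
    stop("label column '", label_column, "' not found; columns are: ",
         paste(names(raw), collapse = ", "))
  }
  if (!is.null(drug_columns)) {
    if (length(drug_columns) != 2L || !all(drug_columns %in% names(raw))) {
      stop("drug_columns must name two existing columns")
    }
  }
  feat_cols <- setdiff(names(raw), c(label_column, drug_columns))
  if (length(feat_cols) == 0L) stop("no feature columns in ", path)
  feats <- matrix(NA_real_, nrow(raw), length(feat_cols),
                  dimnames = list(NULL, feat_cols))
  for (j in seq_along(feat_cols)) {
    cell <- raw[[feat_cols[j]]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(is.na(num) | !nzchar(trimws(cell)))
    if (length(bad)) {
      stop("non-numeric or missing value in column '", feat_cols[j],
           "', row ", bad[1L])
    }
    feats[, j] <- num
  }
  labeled_dataset(
    feats, raw[[label_column]],
    drug_pairs = if (is.null(drug_columns)) NULL
                 else as.matrix(raw[drug_columns]),
    feature_names = feat_cols
  )
}

#' Fit / apply per-feature min-max scaling
#'
#' Learns per-feature (min, max) on a training split and maps training
#' values into [0, 1]. Applied to new data the transform extrapolates: test
#' values outside the training range fall outside [0, 1] and are not
#' clipped, so rules such as "1.0 < feature i" remain meaningful. A
#' constant feature (max == min) maps to 0 with a warning.
#'
#' @param train a \code{\link{labeled_dataset}} (training split only).
#' @return \code{fit_minmax}: a \code{scaler_params} object (lists
#'   \code{min}, \code{max} per feature). \code{apply_minmax}: the dataset
#'   with transformed features.
#' @export
fit_minmax <- function(train) {
  stopifnot(inherits(train, "labeled_dataset"))
  mins <- apply(train$features, 2L, min)
  maxs <- apply(train$features, 2L, max)
  if (any(maxs <= mins)) {
    warning("constant feature(s) map to 0: ",
            paste(head(which(maxs <= mins), 5L), collapse = ", "))
  }
  structure(list(min = mins, max = maxs), class = "scaler_params")
}

#' @rdname fit_minmax
#' @param ds dataset to transform.
#' @param params a fitted \code{scaler_params}.
#' @export
apply_minmax <- function(ds, params) {
  stopifnot(inherits(ds, "labeled_dataset"), inherits(params, "scaler_params"))
  if (ncol(ds$features) != length(params$min)) {
    stop("feature count mismatch: dataset has ", ncol(ds$features),
         ", scaler was fit on ", length(params$min))
  }
  rng <- params$max - params$min
  rng[rng <= 0] <- Inf  # constant feature -> 0
  ds$features <- sweep(sweep(ds$features, 2L, params$min, "-"), 2L, rng, "/")
  ds
}

#' Chi-square feature selection
#'
#' Ranks features by the chi-square statistic of per-class feature mass
#' against class totals: each non-negative feature is treated as a count
#' distributed across classes, observed class sums are compared to
#' expectations proportional to class frequencies. Top-k features are kept;
#' ties break toward the lower feature index.
#'
#' @param train a \code{\link{labeled_dataset}} with non-negative features
#'   (apply \code{\link{fit_minmax}} first).
#' @param k number of features to keep (default 300). If \code{k > v} all
#'   features are returned with a warning.
#' @return A \code{feature_selection} object: \code{selected} (original
#'   indices, descending score order) and \code{scores} (per-feature
#'   statistic).
#' @export
chi2_select <- function(train, k = 300L) {
  stopifnot(inherits(train, "labeled_dataset"), k >= 1L)
  X <- train$features
  if (any(X < 0)) stop("chi2_select needs non-negative features; scale first")
  v <- ncol(X)
  C <- length(train$class_names)
  # observed: per-class column sums (C x v)
  obs <- rowsum(X, group = train$labels, reorder = TRUE)
  if (nrow(obs) < C) {  # classes absent from this split contribute 0 rows
    full <- matrix(0, C, v)
    full[as.integer(rownames(obs)), ] <- obs
    obs <- full
  }
  prior <- tabulate(train$labels, nbins = C) / nrow(X)
  tot <- colSums(obs)
  exp_ <- outer(prior, tot)                       # C x v expected mass
  chi2 <- colSums((obs - exp_)^2 / ifelse(exp_ > 0, exp_, Inf))
  chi2[tot == 0] <- 0
  if (k > v) {
    warning("k = ", k, " > ", v, " features; returning all")
    k <- v
  }
  ord <- order(-chi2, seq_len(v))
  structure(list(selected = ord[seq_len(k)], scores = chi2),
            class = "feature_selection")
}

# Restrict a dataset to selected feature columns (original order of the
# selection, i.e. descending score).
apply_selection <- function(ds, sel) {
  stopifnot(inherits(sel, "feature_selection"))
  ds$features <- ds$features[, sel$selected, drop = FALSE]
  ds$feature_names <- ds$feature_names[sel$selected]
  ds
}
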