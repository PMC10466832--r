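#' Extract IF-THEN rules from fitted trees
#'
#' One rule per leaf per pairwise tree: the conjunction of half-open
#' interval conditions along the leaf's root-to-leaf decision path, with
#' the pairwise verdict "PREDICT X THAN Y" — X the leaf's majority class
#' within the task pair, Y the other class. Since a feature is never
#' reused along a path, each rule has at most one condition per feature
#' (asserted; repeated conditions would intersect).
#'
#' @param model a fitted \code{edst_model} or a single
#'   \code{dst_classifier}.
#' @return A list of \code{rule} objects; each holds \code{conditions}
#'   (data frame: \code{feature} original index, \code{name}, \code{lo},
#'   \code{hi}), \code{predict_class} / \code{against_class} (names),
#'   \code{provenance} (dst, tree, leaf), and NA metric slots until
#'   \code{\link{rule_metrics}} fills them.
#' @export
extract_rules <- function(model) {
  if (inherits(model, "dst_classifier")) {
    dsts <- list(model)
    fmap <- seq_len(10^6)  # identity: columns are original indices
    fnames <- NULL
    cn <- model$class_names
  } else {
    stopifnot(inherits(model, "edst_model"))
    dsts <- model$dsts
    fmap <- model$selection$selected
    fnames <- model$feature_names
    cn <- model$class_names
  }
  rules <- list()
  for (di in seq_along(dsts)) {
    d <- dsts[[di]]
    for (ti in seq_along(d$trees)) {
      pair <- d$pairs[, ti]
      leaf_id <- 0L
      walk <- function(node, conds) {
        if (node$type == "leaf") {
          leaf_id <<- leaf_id + 1L
          pred <- pair[node$majority]
          agst <- pair[3L - node$majority]
          rules[[length(rules) + 1L]] <<- structure(
            list(conditions = conds,
                 predict_class = cn[pred], against_class = cn[agst],
                 provenance = c(dst = di, tree = ti, leaf = leaf_id),
                 coverage = NA_real_, accuracy = NA_real_,
                 score = NA_real_),
            class = "rule")
          return(invisible())
        }
        feat <- fmap[node$feature]
        stopifnot(!feat %in% conds$feature)  # no feature reuse on a path
        bounds <- c(-Inf, node$breaks, Inf)
        for (gz in seq_along(node$children)) {
          cc <- rbind(conds, data.frame(
            feature = feat,
            name = if (is.null(fnames)) paste("feature", feat)
                   else fnames[feat],
            lo = bounds[gz], hi = bounds[gz + 1L]))
          walk(node$children[[gz]], cc)
        }
      }
      walk(d$trees[[ti]]$root,
           data.frame(feature = integer(0L), name = character(0L),
                      lo = numeric(0L), hi = numeric(0L)))
    }
  }
  rules
}

# rows of X (original schema or already-transformed) matched by the rule
rule_matches <- function(rule, X) {
  ok <- rep(TRUE, nrow(X))
  for (i in seq_len(nrow(rule$conditions))) {
    x <- X[, rule$conditions$feature[i]]
    ok <- ok & x > rule$conditions$lo[i] & x <= rule$conditions$hi[i]
  }
  ok
}

#' Coverage and accuracy of a rule
#'
#' Evaluated on the rule's pairwise population — the dataset restricted to
#' its two verdict classes. Coverage is the fraction of those samples
#' satisfying all conditions; accuracy the fraction of satisfying samples
#' whose label equals the predicted class. A rule matching nothing scores
#' (0, 0). Set \code{pair_population = FALSE} to use the whole dataset as
#' denominator instead.
#'
#' @param rule a \code{rule}.
#' @param ds a \code{\link{labeled_dataset}} in the rule's feature space
#'   (i.e. already scaled if the model scaled; conditions reference
#'   original feature indices).
#' @param pair_population restrict to the two verdict classes (default).
#' @return The rule with \code{coverage}, \code{accuracy}, \code{score}
#'   filled in.
#' @export
rule_metrics <- function(rule, ds, pair_population = TRUE) {
  stopifnot(inherits(rule, "rule"), inherits(ds, "labeled_dataset"))
  pred <- match(rule$predict_class, ds$class_names)
  agst <- match(rule$against_class, ds$class_names)
  idx <- if (pair_population) which(ds$labels %in% c(pred, agst))
         else seq_along(ds$labels)
  if (length(idx) == 0L) {
    rule$coverage <- 0; rule$accuracy <- 0; rule$score <- 0
    return(rule)
  }
  hit <- rule_matches(rule, ds$features[idx, , drop = FALSE])
  rule$coverage <- mean(hit)
  rule$accuracy <- if (!any(hit)) 0 else mean(ds$labels[idx][hit] == pred)
  rule$score <- rule_score(rule$coverage, rule$accuracy)
  rule
}

#' Harmonic-mean rule score
#'
#' \code{2 * coverage * accuracy / (coverage + accuracy)}, with the limit
#' convention 0 when both are 0. Symmetric in its arguments.
#'
#' @param coverage,accuracy numbers in [0, 1].
#' @return The score in [0, 1].
#' @examples
#' rule_score(0.5, 1.0)  # 2/3
#' @export
rule_score <- function(coverage, accuracy) {
  stopifnot(all(coverage >= 0 & coverage <= 1),
            all(accuracy >= 0 & accuracy <= 1))
  s <- coverage + accuracy
  ifelse(s == 0, 0, 2 * coverage * accuracy / s)
}

#' Extract, score and rank all rules of a model
#'
#' Convenience wrapper: extracts every leaf rule, evaluates coverage /
#' accuracy / score against a dataset, and sorts by score (descending;
#' ties by lower dst index then leaf id, keeping the ranking stable).
#'
#' @param model a fitted \code{edst_model}.
#' @param ds dataset to score against, in the original (untransformed)
#'   schema; the model's scaler is applied before matching.
#' @param pair_population see \code{\link{rule_metrics}}.
#' @return A list of scored \code{rule} objects, best first.
#' @export
rank_rules <- function(model, ds, pair_population = TRUE) {
  stopifnot(inherits(model, "edst_model"))
  work <- ds
  if (!is.null(model$scaler)) work <- apply_minmax(work, model$scaler)
  rules <- extract_rules(model)
  rules <- lapply(rules, rule_metrics, ds = work,
                  pair_population = pair_population)
  sc <- vapply(rules, `[[`, numeric(1L), "score")
  dsti <- vapply(rules, function(r) r$provenance[["dst"]], numeric(1L))
  leafi <- vapply(rules, function(r) r$provenance[["leaf"]], numeric(1L))
  rules[order(-sc, dsti, leafi)]
}

fmt_num <- function(x) {
  if (is.finite(x) && x == round(x)) sprintf("%.1f", x) else as.character(x)
}

#' Render / parse the rule text dialect
#'
#' \code{render_rule} prints a rule as
#' \code{IF <lo> < <name> ≤ <hi> [AND ...] THEN PREDICT <X> THAN <Y>}.
#' An infinite lower bound drops the lower clause (\code{IF feature 1604
#' ≤ 0.37}); an infinite upper bound drops the upper (\code{IF 1.0 <
#' feature 1850}). \code{parse_rule} is its exact inverse.
#'
#' @param rule a \code{rule}.
#' @return \code{render_rule}: a single string; \code{parse_rule}: a
#'   \code{rule} (metric slots NA).
#' @export
render_rule <- function(rule) {
  stopifnot(inherits(rule, "rule"))
  cl <- vapply(seq_len(nrow(rule$conditions)), function(i) {
    lo <- rule$conditions$lo[i]; hi <- rule$conditions$hi[i]
    nm <- rule$conditions$name[i]
    if (lo >= hi) stop("contradictory condition on ", nm)
    if (is.infinite(lo) && is.infinite(hi)) nm
    else if (is.infinite(lo)) paste0(nm, " \u2264 ", fmt_num(hi))
    else if (is.infinite(hi)) paste0(fmt_num(lo), " < ", nm)
    else paste0(fmt_num(lo), " < ", nm, " \u2264 ", fmt_num(hi))
  }, character(1L))
  paste0("IF ", paste(cl, collapse = " AND "),
         " THEN PREDICT ", rule$predict_class, " THAN ", rule$against_class)
}

#' @rdname render_rule
#' @param text a rendered rule string.
#' @export
parse_rule <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regexec("^IF (.+) THEN PREDICT (\\S+) THAN (\\S+)$", text)[[1L]]
  if (m[1L] == -1L) {
    pos <- if (!startsWith(text, "IF ")) 1L
           else attr(regexpr("^IF .*", text), "match.length") + 1L
    stop("rule syntax error near position ", pos,
         ": expected 'IF <conditions> THEN PREDICT <X> THAN <Y>'")
  }
  parts <- regmatches(text, list(m))[[1L]]
  conds_txt <- strsplit(parts[2L], " AND ", fixed = TRUE)[[1L]]
  num <- "[-+]?[0-9]*\\.?[0-9]+(?:[eE][-+]?[0-9]+)?"
  both <- paste0("^(", num, ") < (.+) \u2264 (", num, ")$")
  up   <- paste0("^(.+) \u2264 (", num, ")$")
  low  <- paste0("^(", num, ") < (.+)$")
  rows <- lapply(seq_along(conds_txt), function(i) {
    ct <- conds_txt[i]
    if (grepl(both, ct)) {
      g <- regmatches(ct, regexec(both, ct))[[1L]]
      data.frame(name = g[3L], lo = as.numeric(g[2L]), hi = as.numeric(g[4L]))
    } else if (grepl(up, ct)) {
      g <- regmatches(ct, regexec(up, ct))[[1L]]
      data.frame(name = g[2L], lo = -Inf, hi = as.numeric(g[3L]))
    } else if (grepl(low, ct)) {
      g <- regmatches(ct, regexec(low, ct))[[1L]]
      data.frame(name = g[3L], lo = as.numeric(g[2L]), hi = Inf)
    } else {
      stop("rule syntax error in condition ", i, ": '", ct, "'")
    }
  })
  conds <- do.call(rbind, rows)
  if (anyDuplicated(conds$name)) stop("repeated feature in conditions")
  if (any(conds$lo >= conds$hi)) stop("contradictory interval bounds")
  fid <- suppressWarnings(as.integer(sub("^feature ", "", conds$name)))
  structure(
    list(conditions = data.frame(feature = fid, name = conds$name,
                                 lo = conds$lo, hi = conds$hi),
         predict_class = parts[3L], against_class = parts[4L],
         provenance = c(dst = NA, tree = NA, leaf = NA),
         coverage = NA_real_, accuracy = NA_real_, score = NA_real_),
    class = "rule")
}

#' @export
print.rule <- function(x, ...) {
  cat(render_rule(x), "\n")
  if (!is.na(x$score)) {
    cat(sprintf("  coverage %.3f, accuracy %.3f, score %.3f\n",
                x$coverage, x$accuracy, x$score))
  }
  invisible(x)
}
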