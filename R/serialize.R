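# Versioned JSON persistence for fitted models: stumps stored as
# cut-point lists plus distributions, fully portable text, no binary
# serialization.

node_to_list <- function(node) {
  if (node$type == "leaf") {
    list(type = "leaf", prob = node$prob, majority = node$majority,
         n = node$n)
  } else {
    list(type = "node", feature = node$feature, breaks = node$breaks,
         n = node$n, dist = node$dist,
         children = lapply(node$children, node_to_list))
  }
}

node_from_list <- function(x) {
  if (x$type == "leaf") {
    list(type = "leaf", prob = as.numeric(x$prob),
         majority = as.integer(x$majority), n = as.integer(x$n))
  } else {
    list(type = "node", feature = as.integer(x$feature),
         breaks = as.numeric(x$breaks), n = as.integer(x$n),
         dist = as.numeric(x$dist),
         children = lapply(x$children, node_from_list))
  }
}

#' Serialize / restore an EDST model as JSON
#'
#' The whole fitted ensemble — configuration, scaler, feature selection
#' and every tree down to its cut-points and leaf distributions — is
#' written as versioned JSON text, so models are portable and two
#' identically seeded fits serialize to identical bytes.
#'
#' @param model a fitted \code{edst_model}.
#' @param path optional file; when omitted the JSON string is returned.
#' @return \code{edst_to_json}: the JSON string (invisibly when written
#'   to a file); \code{edst_from_json}: the restored \code{edst_model}.
#' @export
edst_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "edst_model"))
  obj <- list(
    format = "edst-model", version = 1L,
    config = unclass(model$config),
    class_names = model$class_names,
    class_counts = model$class_counts,
    feature_names = model$feature_names,
    scaler = if (is.null(model$scaler)) NULL
             else list(min = unname(model$scaler$min),
                       max = unname(model$scaler$max)),
    selection = list(selected = model$selection$selected,
                     scores = unname(model$selection$scores)),
    selection_scores = model$selection_scores,
    retained = model$retained,
    dsts = lapply(model$dsts, function(d) {
      list(pairs = d$pairs, subset_id = d$subset_id,
           trees = lapply(d$trees, function(tr) {
             list(theta = tr$theta, max_depth = tr$max_depth,
                  n_leaves = tr$n_leaves, depth = tr$depth,
                  root = node_to_list(tr$root))
           }))
    })
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                         null = "null")
  if (!is.null(path)) {
    writeLines(js, path, useBytes = TRUE)
    return(invisible(js))
  }
  js
}

#' @rdname edst_to_json
#' @param json a JSON string or file path produced by
#'   \code{edst_to_json}.
#' @export
edst_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) {
    json <- paste(readLines(json, warn = FALSE), collapse = "\n")
  }
  x <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (!identical(x$format, "edst-model")) stop("not an edst model file")
  cfg <- do.call(edst_config, x$config[setdiff(names(x$config), NULL)])
  dsts <- lapply(x$dsts, function(d) {
    pairs <- matrix(unlist(d$pairs), nrow = 2L, byrow = TRUE)
    structure(list(
      trees = lapply(d$trees, function(tr) {
        structure(list(root = node_from_list(tr$root),
                       theta = as.integer(tr$theta),
                       max_depth = as.integer(tr$max_depth),
                       n_leaves = as.integer(tr$n_leaves),
                       depth = as.integer(tr$depth)),
                  class = "stump_tree")
      }),
      pairs = pairs,
      class_names = unlist(x$class_names),
      subset_id = if (is.null(d$subset_id)) NA_integer_
                  else as.integer(d$subset_id)),
      class = "dst_classifier")
  })
  structure(
    list(dsts = dsts,
         selection_scores = as.numeric(unlist(x$selection_scores)),
         retained = as.integer(unlist(x$retained)),
         scaler = if (is.null(x$scaler)) NULL
                  else structure(list(min = as.numeric(unlist(x$scaler$min)),
                                      max = as.numeric(unlist(x$scaler$max))),
                                 class = "scaler_params"),
         selection = structure(
           list(selected = as.integer(unlist(x$selection$selected)),
                scores = as.numeric(unlist(x$selection$scores))),
           class = "feature_selection"),
         config = cfg,
         class_names = unlist(x$class_names),
         class_counts = as.integer(unlist(x$class_counts)),
         feature_names = unlist(x$feature_names)),
    class = "edst_model")
}
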