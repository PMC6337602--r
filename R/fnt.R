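#' Flexible neural tree nodes
#'
#' A flexible neural tree (FNT) is a typed tree. Leaves reference a feature
#' index and emit the raw feature value. A function node with children
#' `y_1..y_r` and edge weights `w_1..w_r` computes the weighted sum
#' `net = sum_j w_j * y_j` and emits the flexible Gaussian activation
#' `exp(-((net - m) / n_act)^2)`, where `m` (center) and `n_act` (width) are
#' per-node parameters. Every function-node output — in particular the root
#' score — therefore lies in `(0, 1]`.
#'
#' @param feature Positive integer feature index.
#' @return An `fnt_node`.
#' @rdname fnt_node
#' @export
fnt_leaf <- function(feature) {
  stopifnot(length(feature) == 1L, feature >= 1, feature == round(feature))
  structure(list(kind = "leaf", feature = as.integer(feature)),
            class = "fnt_node")
}

#' @param children List of `fnt_node` children (length >= 2).
#' @param weights Numeric edge weights, one per child.
#' @param m Activation center.
#' @param n_act Activation width; `abs(n_act)` is clamped to at least 1e-6
#'   during evaluation.
#' @rdname fnt_node
#' @export
fnt_function_node <- function(children, weights, m, n_act) {
  stopifnot(is.list(children), length(children) >= 2L,
            length(weights) == length(children),
            is.finite(m), is.finite(n_act))
  structure(list(kind = "function", children = children,
                 weights = as.numeric(weights),
                 m = as.numeric(m), n_act = as.numeric(n_act)),
            class = "fnt_node")
}

is_function_node <- function(node) identical(node$kind, "function")

#' Depth of an FNT (root at depth 1)
#' @param node An `fnt_node`.
#' @return Integer depth.
#' @export
tree_depth <- function(node) {
  if (!is_function_node(node)) return(1L)
  1L + max(vapply(node$children, tree_depth, integer(1)))
}

#' Number of nodes in an FNT
#' @param node An `fnt_node`.
#' @return Integer count of all nodes (function + leaf).
#' @export
tree_size <- function(node) {
  if (!is_function_node(node)) return(1L)
  1L + sum(vapply(node$children, tree_size, integer(1)))
}

# Structural validity: arities, weight counts, leaf indices, depth cap.
validate_tree <- function(node, feature_dim, max_depth = Inf, depth = 1L) {
  if (depth > max_depth) return(FALSE)
  if (!is_function_node(node)) {
    return(node$feature >= 1L && node$feature <= feature_dim)
  }
  if (length(node$children) < 2L ||
      length(node$weights) != length(node$children)) return(FALSE)
  all(vapply(node$children, validate_tree, logical(1),
             feature_dim = feature_dim, max_depth = max_depth,
             depth = depth + 1L))
}

FNT_EPS <- 1e-6

#' Evaluate a flexible neural tree
#'
#' Vectorized over samples: each node is evaluated once against the whole
#' feature matrix. Leaves return their feature column; function nodes return
#' `exp(-((sum_j w_j y_j - m) / n_act)^2)`. The root of a model is a
#' function node, so model scores lie in `(0, 1]`.
#'
#' @param node An `fnt_node` or `fnt_model`.
#' @param features Numeric matrix (samples x features) or a single feature
#'   vector.
#' @return Numeric vector of length `nrow(features)`.
#' @examples
#' tr <- fnt_function_node(list(fnt_leaf(1), fnt_leaf(2)),
#'                         weights = c(1, 1), m = 1, n_act = 1)
#' eval_tree(tr, matrix(c(0.5, 0.5), nrow = 1))
#' @export
eval_tree <- function(node, features) {
  if (inherits(node, "fnt_model")) {
    if (NCOL(features) != node$feature_dim &&
        !(is.null(dim(features)) && length(features) == node$feature_dim)) {
      stop(sprintf("feature dimension mismatch: model expects %d, got %d",
                   node$feature_dim, NCOL(features)))
    }
    node <- node$root
  }
  if (is.null(dim(features))) features <- matrix(features, nrow = 1L)
  if (any(!is.finite(features))) stop("non-finite feature values")
  eval_node(node, features)
}

eval_node <- function(node, X) {
  if (!is_function_node(node)) {
    if (node$feature > ncol(X)) {
      stop(sprintf("leaf references feature %d but only %d features supplied",
                   node$feature, ncol(X)))
    }
    return(X[, node$feature])
  }
  net <- 0
  for (j in seq_along(node$children)) {
    net <- net + node$weights[j] * eval_node(node$children[[j]], X)
  }
  width <- max(abs(node$n_act), FNT_EPS)
  out <- exp(-((net - node$m) / width)^2)
  if (any(!is.finite(out))) {
    stop(sprintf("non-finite activation at function node (m=%g, n_act=%g)",
                 node$m, node$n_act))
  }
  out
}

#' @export
print.fnt_node <- function(x, ...) {
  cat(format_node(x), sep = "\n")
  invisible(x)
}

format_node <- function(node, indent = 0L) {
  pad <- strrep("  ", indent)
  if (!is_function_node(node)) {
    return(sprintf("%sleaf x%d", pad, node$feature))
  }
  head <- sprintf("%s+(m=%.3g, n=%.3g; w=%s)", pad, node$m, node$n_act,
                  paste(sprintf("%.3g", node$weights), collapse = ","))
  c(head, unlist(lapply(node$children, format_node, indent = indent + 1L)))
}

#' @export
print.fnt_model <- function(x, ...) {
  cat(sprintf("<fnt_model> %d features, depth %d, %d nodes, threshold %.2f\n",
              x$feature_dim, tree_depth(x$root), tree_size(x$root),
              x$threshold))
  if (!is.null(x$fitness)) {
    cat(sprintf("  training fitness (%s): %.5f\n",
                x$config$fitness, x$fitness))
  }
  invisible(x)
}

node_to_list <- function(node) {
  if (!is_function_node(node)) {
    return(list(kind = "leaf", feature = node$feature))
  }
  list(kind = "function", weights = node$weights, m = node$m,
       n_act = node$n_act, children = lapply(node$children, node_to_list))
}

node_from_list <- function(lst) {
  if (identical(lst$kind, "leaf")) return(fnt_leaf(lst$feature))
  fnt_function_node(lapply(lst$children, node_from_list),
                    weights = unlist(lst$weights), m = lst$m,
                    n_act = lst$n_act)
}

#' Serialize an FNT model to JSON
#'
#' Full-precision, round-trip-safe JSON (nested node objects). Models
#' trained with the same data, config and seed serialize identically.
#'
#' @param model An `fnt_model`.
#' @param path Optional file path; if given the JSON is written there.
#' @return The JSON string, invisibly if `path` is given.
#' @export
fnt_to_json <- function(model, path = NULL) {
  payload <- list(root = node_to_list(model$root),
                  feature_dim = model$feature_dim,
                  threshold = model$threshold,
                  config = unclass(model$config),
                  seed = model$seed,
                  fitness = model$fitness,
                  scaling = model$scaling)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Restore an FNT model from JSON
#'
#' @param x JSON string or path to a file written by [fnt_to_json()].
#' @return An `fnt_model`.
#' @export
fnt_from_json <- function(x) {
  lst <- jsonlite::fromJSON(x, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  cfg <- lst$config
  cfg$function_arities <- as.integer(unlist(cfg$function_arities))
  structure(list(root = node_from_list(lst$root),
                 feature_dim = as.integer(lst$feature_dim),
                 threshold = lst$threshold,
                 config = do.call(train_config, cfg),
                 seed = lst$seed,
                 fitness = lst$fitness,
                 scaling = lst$scaling),
            class = "fnt_model")
}
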