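#' Serialize / restore a tree model as JSON
#'
#' Trees are stored as JSON with explicit node ids and left/right child
#' ids; the serialized convention is that a linear combination less
#' than or equal to its threshold routes to the left child.  The
#' round trip preserves topology, coefficients, thresholds and leaf
#' labels exactly (doubles are written at full precision).
#'
#' @param model A `seldi_tree`.
#' @param path JSON file path.
#' @return `write_tree_model()` returns `path` invisibly;
#'   `read_tree_model()` returns the restored `seldi_tree`.
#' @export
write_tree_model <- function(model, path) {
  stopifnot(inherits(model, "seldi_tree"))
  validate_tree(model)
  nodes <- lapply(model$nodes, function(nd) {
    if (nd$type == "split") {
      list(node_id = nd$node_id, type = "split",
           features = as.numeric(names(nd$coefficients)),
           coefficients = unname(as.numeric(nd$coefficients)),
           threshold = nd$threshold,
           left_child = nd$left_child, right_child = nd$right_child,
           n = nd$n, counts = as.list(nd$counts),
           decrease = nd$decrease)
    } else {
      list(node_id = nd$node_id, type = "leaf", label = nd$label,
           counts = as.list(nd$counts))
    }
  })
  obj <- list(schema_version = 1L, model = "seldi_tree",
              classes = model$classes, root_id = model$root_id,
              nodes = nodes, meta = model$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

#' @rdname write_tree_model
#' @export
read_tree_model <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse tree model JSON ",
                                           path, ": ", conditionMessage(e)))
  if (is.null(obj$schema_version) || obj$schema_version != 1L)
    stop("unsupported tree model schema version: ",
         obj$schema_version %||% "<missing>")
  nodes <- lapply(obj$nodes, function(nd) {
    counts <- if (!is.null(nd$counts))
      stats::setNames(as.numeric(unlist(nd$counts)), names(nd$counts))
    if (nd$type == "split") {
      list(node_id = as.integer(nd$node_id), type = "split",
           coefficients = stats::setNames(as.numeric(unlist(nd$coefficients)),
                                          as.character(unlist(nd$features))),
           threshold = as.numeric(nd$threshold),
           decrease = if (is.null(nd$decrease)) NA_real_
                      else as.numeric(nd$decrease),
           n = if (is.null(nd$n)) NA_integer_ else as.integer(nd$n),
           counts = counts,
           left_child = as.integer(nd$left_child),
           right_child = as.integer(nd$right_child))
    } else if (nd$type == "leaf") {
      list(node_id = as.integer(nd$node_id), type = "leaf",
           label = as.character(nd$label), counts = counts)
    } else stop("unknown node type '", nd$type, "' in ", path)
  })
  nodes <- nodes[order(vapply(nodes, `[[`, integer(1), "node_id"))]
  meta <- obj$meta
  if (!is.null(meta$class_weights))
    meta$class_weights <- stats::setNames(as.numeric(unlist(meta$class_weights)),
                                          names(meta$class_weights))
  tree <- structure(list(nodes = nodes, root_id = as.integer(obj$root_id),
                         classes = as.character(unlist(obj$classes)),
                         params = NULL, meta = meta),
                    class = "seldi_tree")
  validate_tree(tree)
  tree
}

# Structural validation: connected binary tree, no cycles, every split
# has two children, ids consistent.
validate_tree <- function(tree) {
  n <- length(tree$nodes)
  ids <- vapply(tree$nodes, `[[`, integer(1), "node_id")
  if (!identical(sort(ids), seq_len(n)))
    stop("tree node ids must be 1..", n)
  seen <- logical(n)
  walk <- function(id) {
    if (id < 1L || id > n) stop("child id ", id, " out of range")
    if (seen[id]) stop("cycle or shared child detected at node ", id)
    seen[id] <<- TRUE
    nd <- tree$nodes[[id]]
    if (nd$type == "split") {
      if (is.na(nd$left_child) || is.na(nd$right_child))
        stop("split node ", id, " lacks two children")
      if (length(nd$coefficients) < 1L || all(nd$coefficients == 0))
        stop("split node ", id, " has no nonzero coefficient")
      walk(nd$left_child)
      walk(nd$right_child)
    }
  }
  walk(tree$root_id)
  if (!all(seen)) stop("disconnected node(s): ",
                       paste(which(!seen), collapse = ", "))
  invisible(tree)
}
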