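# Minimal cost-complexity pruning and cross-validated penalty
# selection for seldi_tree objects.

node_weighted_counts <- function(tree, id) {
  nd <- tree$nodes[[id]]
  wk <- tree$meta$class_weights %||%
    stats::setNames(rep(1, length(tree$classes)), tree$classes)
  as.numeric(nd$counts[tree$classes]) * as.numeric(wk[tree$classes])
}

# Resubstitution error (weighted, as a rate of the root total) of node
# `id` treated as a leaf.
node_leaf_error <- function(tree, id, total) {
  w <- node_weighted_counts(tree, id)
  (sum(w) - max(w)) / total
}

subtree_stats <- function(tree, id, total) {
  nd <- tree$nodes[[id]]
  if (nd$type == "leaf")
    return(list(error = node_leaf_error(tree, id, total), leaves = 1L))
  l <- subtree_stats(tree, nd$left_child, total)
  r <- subtree_stats(tree, nd$right_child, total)
  list(error = l$error + r$error, leaves = l$leaves + r$leaves)
}

collapse_to_leaf <- function(tree, ids) {
  wk <- tree$meta$class_weights %||%
    stats::setNames(rep(1, length(tree$classes)), tree$classes)
  for (id in ids) {
    nd <- tree$nodes[[id]]
    w <- as.numeric(nd$counts[tree$classes]) * as.numeric(wk[tree$classes])
    tree$nodes[[id]] <- list(node_id = id, type = "leaf",
                             label = tree$classes[which.max(w)],
                             counts = nd$counts)
  }
  # drop unreachable nodes and reindex breadth-first
  old <- integer(0)
  queue <- tree$root_id
  while (length(queue)) {
    id <- queue[1L]; queue <- queue[-1L]
    old <- c(old, id)
    nd <- tree$nodes[[id]]
    if (nd$type == "split") queue <- c(queue, nd$left_child, nd$right_child)
  }
  remap <- stats::setNames(seq_along(old), old)
  nodes <- vector("list", length(old))
  for (i in seq_along(old)) {
    nd <- tree$nodes[[old[i]]]
    nd$node_id <- i
    if (nd$type == "split") {
      nd$left_child <- unname(remap[as.character(nd$left_child)])
      nd$right_child <- unname(remap[as.character(nd$right_child)])
    }
    nodes[[i]] <- nd
  }
  tree$nodes <- nodes
  tree$root_id <- 1L
  tree
}

# Weakest-link pruning sequence: list of (alpha, tree), nested, ending
# at the root leaf.
prune_sequence <- function(tree) {
  total <- sum(node_weighted_counts(tree, tree$root_id))
  out <- list()
  cur <- tree
  repeat {
    internal <- which(vapply(cur$nodes, `[[`, character(1), "type") == "split")
    if (!length(internal)) {
      if (!length(out)) out <- list(list(alpha = 0, tree = cur))
      break
    }
    g <- vapply(internal, function(id) {
      st <- subtree_stats(cur, id, total)
      (node_leaf_error(cur, id, total) - st$error) / (st$leaves - 1L)
    }, numeric(1))
    gmin <- min(g)
    if (!length(out) && gmin > 1e-12) {
      out[[1L]] <- list(alpha = 0, tree = cur)
    }
    cur <- collapse_to_leaf(cur, internal[g <= gmin + 1e-12])
    out[[length(out) + 1L]] <- list(alpha = max(gmin, 0), tree = cur)
  }
  out
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

prune_tree_cv <- function(tree, ft, enc, params) {
  main_seq <- prune_sequence(tree)
  if (length(main_seq) <= 1L) return(main_seq[[1L]]$tree)
  alphas <- vapply(main_seq, `[[`, numeric(1), "alpha")
  K <- length(alphas)
  cand <- c(sqrt(alphas[-K] * alphas[-1L]), Inf)   # geometric-mean midpoints
  k <- min(params$cv_folds, min(table(enc$y)))
  if (k < 2L) return(main_seq[[1L]]$tree)
  fold <- stratified_folds(enc$y, k)
  err <- numeric(K)
  for (f in seq_len(k)) {
    tr <- fold != f
    ft_f <- list(values = ft$values[tr, , drop = FALSE], mz = ft$mz)
    enc_f <- list(y = enc$y[tr], classes = enc$classes)
    tree_f <- grow_tree(ft_f, enc_f, params)
    seq_f <- prune_sequence(tree_f)
    af <- vapply(seq_f, `[[`, numeric(1), "alpha")
    test_vals <- ft$values[!tr, , drop = FALSE]
    truth <- enc$classes[enc$y[!tr]]
    for (ki in seq_len(K)) {
      pick <- max(which(af <= cand[ki]))
      pred <- predict(seq_f[[pick]]$tree, test_vals)
      err[ki] <- err[ki] + sum(pred != truth)
    }
  }
  n <- length(enc$y)
  rate <- err / n
  best <- min(rate)
  se <- sqrt(best * (1 - best) / n)
  kstar <- max(which(rate <= best + se))    # 1-SE rule: smallest such tree
  main_seq[[kstar]]$tree
}

#' Cross-validated performance of the tree pipeline
#'
#' Stratified k-fold cross-validation: for each fold a tree is fitted
#' on the remaining folds with the same parameters (including its own
#' internal pruning) and evaluated on the held-out fold; confusion
#' counts are pooled.
#'
#' @param x A [peak_matrix()] or numeric matrix with `mz_*` columns.
#' @param labels Class labels (from the matrix if omitted).
#' @param params A [tree_params()]; `cv_folds` must not exceed the
#'   smaller class count.
#' @param seed Integer seed (folds and fold-tree fits).
#' @return A list with `report` (pooled [compute_metrics()] in mode
#'   `"cv"`), `folds` (per-fold reports) and `predictions`.
#' @export
cross_validate <- function(x, labels = NULL, params = tree_params(),
                           seed = 1L) {
  ft <- feature_table(x)
  if (is.null(labels)) {
    if (!inherits(x, "peak_matrix")) stop("labels must be supplied")
    labels <- x$labels
  }
  enc <- encode_labels(labels)
  k <- params$cv_folds
  if (k < 2L || k > min(table(enc$y)))
    stop("cv_folds must be between 2 and the smaller class count ",
         "(stratification error otherwise)")
  with_seed(seed, {
    fold <- stratified_folds(enc$y, k)
    pred <- character(length(enc$y))
    fold_reports <- vector("list", k)
    for (f in seq_len(k)) {
      tr <- fold != f
      if (length(unique(enc$y[tr])) < 2L)
        stop("training fold with a single class (stratification error)")
      tree_f <- with_seed(derive_seed(seed, f),
                          fit_tree(ft$values[tr, , drop = FALSE],
                                   labels[tr], params,
                                   seed = derive_seed(seed, f)))
      pred[!tr] <- predict(tree_f, ft$values[!tr, , drop = FALSE])
      fold_reports[[f]] <- compute_metrics(pred[!tr], labels[!tr], mode = "cv")
    }
    list(report = compute_metrics(pred, labels, mode = "cv"),
         folds = fold_reports,
         predictions = data.frame(
           sample_id = rownames(ft$values) %||% seq_along(pred),
           truth = labels, predicted = pred, fold = fold,
           stringsAsFactors = FALSE))
  })
}
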