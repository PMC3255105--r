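#' Gini impurity of a node
#'
#' `1 - sum(p_k^2)` over the class proportions, optionally reweighting
#' counts (priors/misclassification costs enter the tree as per-class
#' weights).
#'
#' @param class_counts Nonnegative counts, not all zero.
#' @param weights Optional per-class weights.
#' @return The impurity in `[0, 0.5]` for two classes.
#' @export
gini_impurity <- function(class_counts, weights = NULL) {
  if (any(class_counts < 0) || sum(class_counts) == 0)
    stop("class counts must be nonnegative and not all zero")
  w <- if (is.null(weights)) rep(1, length(class_counts)) else weights
  p <- class_counts * w / sum(class_counts * w)
  1 - sum(p^2)
}

# Best threshold on a single numeric projection: weighted Gini decrease,
# candidate thresholds at midpoints of consecutive distinct values,
# ties broken toward the smaller threshold.  y is integer 1/2.
split_eval <- function(z, y, wt = NULL, min_bucket = 1L) {
  n <- length(z)
  if (is.null(wt)) wt <- rep(1, n)
  ord <- order(z, method = "radix")
  zs <- z[ord]; ys <- y[ord]; ws <- wt[ord]
  W <- cumsum(ws)
  W1 <- cumsum(ws * (ys == 1L))
  Tw <- W[n]; T1 <- W1[n]
  i <- seq_len(n - 1L)
  valid <- (zs[i] < zs[i + 1L]) & (i >= min_bucket) & ((n - i) >= min_bucket)
  if (!any(valid))
    return(list(threshold = NA_real_, decrease = 0))
  i <- i[valid]
  wl <- W[i]; w1l <- W1[i]
  wr <- Tw - wl; w1r <- T1 - w1l
  gl <- 1 - (w1l / wl)^2 - ((wl - w1l) / wl)^2
  gr <- 1 - (w1r / wr)^2 - ((wr - w1r) / wr)^2
  gp <- 1 - (T1 / Tw)^2 - ((Tw - T1) / Tw)^2
  dec <- gp - (wl / Tw) * gl - (wr / Tw) * gr
  b <- which.max(dec)                       # first max => smallest threshold
  list(threshold = (zs[i[b]] + zs[i[b] + 1L]) / 2, decrease = dec[b])
}

#' Best axis-parallel split on one feature
#'
#' Exhaustive search over the midpoints between consecutive distinct
#' values, maximizing the (weighted) Gini impurity decrease; ties are
#' broken toward the smaller threshold.  A constant feature yields zero
#' decrease and an `NA` threshold.
#'
#' @param x Numeric feature vector.
#' @param labels Class labels (two classes).
#' @param weights Optional per-sample weights.
#' @param min_bucket Minimum child size.
#' @return A list with `threshold` and `decrease`.
#' @export
best_axis_split <- function(x, labels, weights = NULL, min_bucket = 1L) {
  y <- encode_labels(labels)
  split_eval(x, y$y, weights, min_bucket)
}

encode_labels <- function(labels) {
  labels <- as.character(labels)
  classes <- intersect(c("node_positive", "node_negative"), unique(labels))
  if (length(classes) < length(unique(labels)))
    classes <- sort(unique(labels))
  if (length(classes) > 2L) stop("only two-class problems are supported")
  list(y = match(labels, classes), classes = classes)
}

#' Oblique-tree fitting parameters
#'
#' @param max_depth Maximum tree depth (root = depth 0).
#' @param min_node_size Minimum samples in a leaf (>= 1).
#' @param allow_oblique Search linear-combination splits in addition to
#'   axis-parallel ones.
#' @param n_restarts Seeded random restarts of the oblique coordinate
#'   descent (>= 1).
#' @param max_oblique_features Number of top axis-ranked features fed to
#'   the oblique search at each node.
#' @param class_priors Named per-class priors (default equal).
#' @param misclassification_costs Named per-class costs (default unit).
#' @param cv_folds Folds used for cost-complexity pruning and
#'   [cross_validate()].
#' @param prune Apply minimal cost-complexity pruning selected by
#'   cross-validation with the 1-SE rule.
#' @return A list of class `tree_params`.
#' @export
tree_params <- function(max_depth = 30L, min_node_size = 5L,
                        allow_oblique = TRUE, n_restarts = 20L,
                        max_oblique_features = 8L, class_priors = NULL,
                        misclassification_costs = NULL, cv_folds = 10L,
                        prune = TRUE) {
  stopifnot(min_node_size >= 1, n_restarts >= 1, max_depth >= 1)
  structure(list(max_depth = as.integer(max_depth),
                 min_node_size = as.integer(min_node_size),
                 allow_oblique = isTRUE(allow_oblique),
                 n_restarts = as.integer(n_restarts),
                 max_oblique_features = as.integer(max_oblique_features),
                 class_priors = class_priors,
                 misclassification_costs = misclassification_costs,
                 cv_folds = as.integer(cv_folds), prune = isTRUE(prune)),
            class = "tree_params")
}

#' Best oblique (linear-combination) split
#'
#' Searches coefficient vectors `w` and thresholds `t` for the split
#' `w . x <= t` maximizing the Gini decrease.  With exactly two
#' candidate features and a small node the search is exact (every
#' distinct ordering of the projections is enumerated via the critical
#' direction angles defined by sample pairs); otherwise cyclic
#' coordinate descent is run from the best axis split plus seeded
#' random restarts, followed by backward deletion of near-zero
#' coefficients.  The best axis-parallel split is always in the search
#' space, so the returned decrease never falls below it.  Coefficients
#' are scaled to unit maximum magnitude.
#'
#' @param x Numeric matrix of candidate features (columns named by
#'   m/z).
#' @param labels Class labels.
#' @param params A [tree_params()].
#' @param weights Optional per-sample weights.
#' @param min_bucket Minimum child size.
#' @return A list with `coefficients` (named), `threshold`, `decrease`
#'   and `no_split` (TRUE when no impurity-decreasing split exists).
#'   Uses the current RNG stream for restarts; seed it for
#'   reproducibility.
#' @export
best_oblique_split <- function(x, labels, params = tree_params(),
                               weights = NULL, min_bucket = 1L) {
  x <- as.matrix(x)
  enc <- encode_labels(labels)
  y <- enc$y
  d <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(d))
  axis <- lapply(seq_len(d), function(j) split_eval(x[, j], y, weights, min_bucket))
  adec <- vapply(axis, `[[`, numeric(1), "decrease")
  jbest <- which.max(adec)
  best <- list(w = as.numeric(seq_len(d) == jbest),
               threshold = axis[[jbest]]$threshold, decrease = adec[jbest])
  consider <- function(w, ev) {
    if (!is.na(ev$threshold) && ev$decrease > best$decrease + 1e-12)
      best <<- list(w = w, threshold = ev$threshold, decrease = ev$decrease)
  }
  if (d == 2L && nrow(x) <= 64L) {
    # exact: enumerate all distinct projection orderings
    pairs <- utils::combn(nrow(x), 2L)
    dx <- x[pairs[1L, ], 1L] - x[pairs[2L, ], 1L]
    dy <- x[pairs[1L, ], 2L] - x[pairs[2L, ], 2L]
    crit <- sort(unique(c(0, pi / 2, atan2(-dx, dy) %% pi)))
    mids <- (crit + c(crit[-1L], crit[1L] + pi)) / 2
    for (theta in sort(unique(c(crit, mids %% pi)))) {
      w <- c(cos(theta), sin(theta))
      consider(w, split_eval(drop(x %*% w), y, weights, min_bucket))
    }
  } else if (d >= 2L) {
    starts <- list(best$w)
    for (r in seq_len(max(params$n_restarts - 1L, 0L))) {
      w <- stats::rnorm(d)
      starts[[r + 1L]] <- w / max(abs(w))
    }
    grid <- c(-2, -1, -0.5, -0.25, -0.1, 0.1, 0.25, 0.5, 1, 2)
    for (w0 in starts) {
      w <- w0
      cur <- split_eval(drop(x %*% w), y, weights, min_bucket)
      for (sweep in 1:8) {
        improved <- FALSE
        for (j in seq_len(d)) {
          zo <- drop(x %*% w) - w[j] * x[, j]
          sj <- (stats::sd(zo) + 1e-12) / (stats::sd(x[, j]) + 1e-12)
          for (cj in unique(c(0, w[j], grid * sj))) {
            ev <- split_eval(zo + cj * x[, j], y, weights, min_bucket)
            if (!is.na(ev$threshold) && ev$decrease > cur$decrease + 1e-12) {
              w[j] <- cj
              cur <- ev
              improved <- TRUE
            }
          }
        }
        if (!improved) break
      }
      consider(w, cur)
    }
    # backward deletion of small coefficients
    repeat {
      nz <- which(best$w != 0)
      if (length(nz) <= 1L) break
      ord <- nz[order(abs(best$w[nz]))]
      dropped <- FALSE
      for (j in ord) {
        w <- best$w
        w[j] <- 0
        ev <- split_eval(drop(x %*% w), y, weights, min_bucket)
        if (!is.na(ev$threshold) && ev$decrease >= best$decrease - 1e-12) {
          best <- list(w = w, threshold = ev$threshold, decrease = ev$decrease)
          dropped <- TRUE
          break
        }
      }
      if (!dropped) break
    }
  }
  if (is.na(best$threshold) || best$decrease <= 1e-12)
    return(list(coefficients = stats::setNames(best$w, colnames(x)),
                threshold = NA_real_, decrease = 0, no_split = TRUE))
  scale <- max(abs(best$w))
  w <- best$w / scale
  list(coefficients = stats::setNames(w, colnames(x))[w != 0],
       threshold = best$threshold / scale, decrease = best$decrease,
       no_split = FALSE)
}

feature_table <- function(x) {
  # Accepts peak_matrix, matrix or data.frame; returns values + numeric m/z
  if (inherits(x, "peak_matrix"))
    return(list(values = x$values, mz = matrix_mz(x)))
  v <- as.matrix(x)
  cn <- colnames(v)
  if (is.null(cn)) stop("feature matrix must have m/z column names")
  mz <- suppressWarnings(as.numeric(sub("^mz_", "", cn)))
  if (any(is.na(mz))) stop("cannot parse m/z from column names")
  list(values = v, mz = mz)
}

class_weights <- function(labels, classes, params) {
  n_k <- table(factor(labels, levels = classes))
  priors <- params$class_priors
  if (is.null(priors)) priors <- stats::setNames(rep(1, length(classes)), classes)
  costs <- params$misclassification_costs
  if (is.null(costs)) costs <- stats::setNames(rep(1, length(classes)), classes)
  wk <- priors[classes] * costs[classes] / pmax(as.numeric(n_k), 1)
  wk <- wk / sum(wk * as.numeric(n_k)) * length(labels)   # mean weight 1
  stats::setNames(as.numeric(wk), classes)
}

#' Fit an oblique classification tree
#'
#' Recursive partitioning with Gini impurity and linear-combination
#' splits (`sum_i w_i x_i <= t` routes left), grown until node purity,
#' `min_node_size` or `max_depth`, then (optionally) pruned by minimal
#' cost-complexity pruning with the penalty chosen by stratified
#' k-fold cross-validation under the 1-SE rule.  Fully deterministic
#' given `seed`.
#'
#' @param x A [peak_matrix()] or numeric matrix with `mz_*` column
#'   names.
#' @param labels Class labels (ignored when `x` is a [peak_matrix()]
#'   unless supplied).
#' @param params A [tree_params()].
#' @param seed Integer seed driving the oblique restarts and the
#'   pruning folds.
#' @return An object of class `seldi_tree`.
#' @export
fit_tree <- function(x, labels = NULL, params = tree_params(), seed = 1L) {
  ft <- feature_table(x)
  if (is.null(labels)) {
    if (!inherits(x, "peak_matrix"))
      stop("labels must be supplied for a plain matrix")
    labels <- x$labels
  }
  enc <- encode_labels(labels)
  with_seed(seed, {
    tree <- grow_tree(ft, enc, params)
    if (params$prune && length(tree$nodes) > 1L)
      tree <- prune_tree_cv(tree, ft, enc, params)
    tree$meta$seed <- as.integer(seed)
    tree
  })
}

grow_tree <- function(ft, enc, params) {
  X <- ft$values
  y <- enc$y
  classes <- enc$classes
  wk <- if (length(classes) == 2L) class_weights(classes[y], classes, params)
        else stats::setNames(1, classes)
  wt <- wk[y]
  nodes <- list()
  new_id <- function() length(nodes) + 1L
  make_leaf <- function(idx) {
    cnt <- tabulate(y[idx], nbins = length(classes))
    wcnt <- cnt * wk
    id <- new_id()
    nodes[[id]] <<- list(node_id = id, type = "leaf",
                         label = classes[which.max(wcnt)],
                         counts = stats::setNames(cnt, classes))
    id
  }
  grow <- function(idx, depth) {
    cnt <- tabulate(y[idx], nbins = length(classes))
    pure <- sum(cnt > 0) <= 1L
    if (pure || depth >= params$max_depth ||
        length(idx) < 2L * params$min_node_size || length(classes) < 2L)
      return(make_leaf(idx))
    Xi <- X[idx, , drop = FALSE]
    yi <- y[idx]
    wi <- wt[idx]
    d <- ncol(Xi)
    axis <- lapply(seq_len(d), function(j)
      split_eval(Xi[, j], yi, wi, params$min_node_size))
    adec <- vapply(axis, `[[`, numeric(1), "decrease")
    jb <- which.max(adec)
    chosen <- list(coefficients = stats::setNames(1, as.character(ft$mz[jb])),
                   threshold = axis[[jb]]$threshold, decrease = adec[jb])
    if (params$allow_oblique && d >= 2L) {
      top <- order(-adec, seq_len(d))[seq_len(min(params$max_oblique_features, d))]
      sub <- Xi[, top, drop = FALSE]
      colnames(sub) <- as.character(ft$mz[top])
      ob <- best_oblique_split(sub, classes[yi], params, wi,
                               params$min_node_size)
      if (!ob$no_split && ob$decrease > chosen$decrease + 1e-12)
        chosen <- ob[c("coefficients", "threshold", "decrease")]
    }
    if (is.na(chosen$threshold) || chosen$decrease <= 1e-12)
      return(make_leaf(idx))
    fmz <- as.numeric(names(chosen$coefficients))
    cols <- match(fmz, ft$mz)
    z <- drop(X[idx, cols, drop = FALSE] %*% chosen$coefficients)
    go_left <- z <= chosen$threshold
    if (!any(go_left) || all(go_left)) return(make_leaf(idx))
    id <- new_id()
    nodes[[id]] <<- list(node_id = id, type = "split",
                         coefficients = chosen$coefficients,
                         threshold = chosen$threshold,
                         decrease = chosen$decrease,
                         n = length(idx),
                         counts = stats::setNames(cnt, classes),
                         left_child = NA_integer_, right_child = NA_integer_)
    l <- grow(idx[go_left], depth + 1L)
    r <- grow(idx[!go_left], depth + 1L)
    nodes[[id]]$left_child <<- l
    nodes[[id]]$right_child <<- r
    id
  }
  root <- grow(seq_along(y), 0L)
  structure(list(nodes = nodes, root_id = root, classes = classes,
                 params = params,
                 meta = list(n_train = length(y),
                             class_weights = wk)),
            class = "seldi_tree")
}

#' @export
print.seldi_tree <- function(x, ...) {
  types <- vapply(x$nodes, `[[`, character(1), "type")
  cat(sprintf("<seldi_tree> %d node(s): %d split(s), %d leaf/leaves\n",
              length(x$nodes), sum(types == "split"), sum(types == "leaf")))
  invisible(x)
}

# m/z features referenced by a tree's splitters
tree_features <- function(tree) {
  f <- unlist(lapply(tree$nodes, function(nd)
    if (nd$type == "split") as.numeric(names(nd$coefficients))))
  sort(unique(f))
}

#' Predict classes with a fitted or published tree
#'
#' Samples are routed by the serialized convention that a linear
#' combination less than or equal to its threshold goes to the left
#' child.  Model features are matched to matrix columns by nearest m/z
#' within a relative tolerance; a feature with no matching column is an
#' error naming the m/z.
#'
#' @param object A `seldi_tree`.
#' @param newdata A [peak_matrix()] or numeric matrix with `mz_*`
#'   column names.
#' @param type `"class"` for a label vector, `"node"` for a
#'   `data.frame` with the terminal node and the visited node path.
#' @param match_tolerance Relative m/z matching tolerance (0.005 =
#'   one cluster window).
#' @param ... Unused.
#' @return Character vector of labels, or a `data.frame` when
#'   `type = "node"`.
#' @export
predict.seldi_tree <- function(object, newdata, type = c("class", "node"),
                               match_tolerance = 0.005, ...) {
  type <- match.arg(type)
  ft <- feature_table(newdata)
  need <- tree_features(object)
  col_of <- vapply(need, function(mz) {
    j <- which.min(abs(ft$mz - mz))
    if (abs(ft$mz[j] - mz) > match_tolerance * mz)
      stop("no matrix column matches model feature m/z ", mz)
    j
  }, integer(1))
  names(col_of) <- as.character(need)
  n <- nrow(ft$values)
  out_label <- character(n)
  out_node <- integer(n)
  out_path <- character(n)
  for (i in seq_len(n)) {
    id <- object$root_id
    path <- id
    repeat {
      nd <- object$nodes[[id]]
      if (nd$type == "leaf") break
      fmz <- names(nd$coefficients)
      v <- ft$values[i, col_of[fmz]]
      id <- if (sum(v * nd$coefficients) <= nd$threshold) nd$left_child
            else nd$right_child
      path <- c(path, id)
    }
    out_label[i] <- nd$label
    out_node[i] <- id
    out_path[i] <- paste(path, collapse = ">")
  }
  if (type == "class") return(out_label)
  data.frame(sample_id = rownames(ft$values) %||% seq_len(n),
             label = out_label, terminal_node = out_node, path = out_path,
             stringsAsFactors = FALSE)
}

#' The published fixed classification tree
#'
#' The two-splitter, three-leaf tree reported for the training cohort:
#' the root combines the five panel peaks m/z 3,104, 3,781, 5,867,
#' 7,970 and 9,290 (threshold 1.122, combination <= threshold routes
#' left); its left child combines m/z 3,781 and 5,867 (threshold
#' 0.248).  Terminal nodes 1 and 3 are node-positive, terminal node 2
#' node-negative.  Coefficients are stored verbatim as printed, with
#' no renormalization.  The topology (the second splitter is the left
#' child of the root) is the one consistent with the published
#' class-conditional mean vectors landing on their own class's
#' terminals.
#'
#' @return A `seldi_tree`.
#' @export
published_tree <- function() {
  n1 <- list(node_id = 1L, type = "split",
             coefficients = c(`3104` = -0.075, `3781` = -0.231,
                              `5867` = 0.157, `7970` = 0.086, `9290` = 0.953),
             threshold = 1.122, decrease = NA_real_, n = 145L,
             counts = c(node_positive = 70L, node_negative = 75L),
             left_child = 2L, right_child = 5L)
  n2 <- list(node_id = 2L, type = "split",
             coefficients = c(`3781` = 0.410, `5867` = -0.912),
             threshold = 0.248, decrease = NA_real_, n = NA_integer_,
             counts = NULL, left_child = 3L, right_child = 4L)
  leaf <- function(id, label)
    list(node_id = id, type = "leaf", label = label, counts = NULL)
  structure(list(nodes = list(n1, n2, leaf(3L, "node_positive"),
                              leaf(4L, "node_negative"),
                              leaf(5L, "node_positive")),
                 root_id = 1L,
                 classes = c("node_positive", "node_negative"),
                 params = NULL,
                 meta = list(source = "published_fixed_tree",
                             terminal_names = c(`3` = "Terminal 1",
                                                `4` = "Terminal 2",
                                                `5` = "Terminal 3"))),
            class = "seldi_tree")
}

# Best axis split on feature f predicting a binary left/right
# assignment; returns the adjusted agreement lambda in [0, 1].
surrogate_association <- function(f, go_left) {
  n <- length(f)
  ord <- order(f, method = "radix")
  gl <- go_left[ord]
  cl <- cumsum(gl)
  tot <- cl[n]
  i <- seq_len(n - 1L)
  fs <- f[ord]
  valid <- fs[i] < fs[i + 1L]
  if (!any(valid)) return(0)
  i <- i[valid]
  # send <= threshold left (or right): take the better orientation
  match_left <- cl[i] + ((n - i) - (tot - cl[i]))
  agree <- max(match_left, n - match_left) / n
  maj <- max(tot, n - tot) / n
  if (agree <= maj) 0 else (agree - maj) / (1 - maj)
}

#' Variable importance of a tree
#'
#' Per-feature importance is the impurity decrease attributable to the
#' feature summed over the tree's splits: oblique splits share their
#' decrease across features in proportion to absolute coefficients,
#' and every feature additionally credits each node with its surrogate
#' association (how well its best axis split reproduces the primary
#' left/right assignment) times the node's decrease.  Scores are
#' scaled so the top feature is exactly 100.
#'
#' @param model A `seldi_tree`.
#' @param x Training [peak_matrix()] (or matrix) used to route samples
#'   and realize decreases.
#' @param labels Class labels (taken from the matrix if omitted).
#' @param surrogates Include surrogate-split credit.
#' @return Named numeric vector (names = `mz_*`), decreasing, top =
#'   100.
#' @export
variable_importance <- function(model, x, labels = NULL, surrogates = TRUE) {
  ft <- feature_table(x)
  if (is.null(labels)) {
    if (!inherits(x, "peak_matrix")) stop("labels must be supplied")
    labels <- x$labels
  }
  enc <- encode_labels(labels)
  need <- tree_features(model)
  col_of <- vapply(need, function(mz) which.min(abs(ft$mz - mz)), integer(1))
  names(col_of) <- as.character(need)
  imp <- stats::setNames(numeric(length(ft$mz)), paste0("mz_", round(ft$mz)))
  recurse <- function(id, idx) {
    nd <- model$nodes[[id]]
    if (nd$type == "leaf" || length(idx) < 2L) return(invisible())
    fmz <- names(nd$coefficients)
    z <- drop(ft$values[idx, col_of[fmz], drop = FALSE] %*% nd$coefficients)
    go_left <- z <= nd$threshold
    cnt <- tabulate(enc$y[idx], nbins = length(enc$classes))
    dec <- 0
    if (any(go_left) && !all(go_left)) {
      gp <- gini_impurity(cnt)
      cl <- tabulate(enc$y[idx][go_left], nbins = length(enc$classes))
      cr <- cnt - cl
      dec <- gp - sum(go_left) / length(idx) * gini_impurity(cl) -
        sum(!go_left) / length(idx) * gini_impurity(cr)
      share <- abs(nd$coefficients) / sum(abs(nd$coefficients))
      pcols <- col_of[fmz]
      imp[pcols] <<- imp[pcols] + dec * share
      if (surrogates && dec > 0) {
        for (j in setdiff(seq_along(ft$mz), pcols)) {
          lam <- surrogate_association(ft$values[idx, j], go_left)
          imp[j] <<- imp[j] + lam * dec
        }
      }
    }
    recurse(nd$left_child, idx[go_left])
    recurse(nd$right_child, idx[!go_left])
  }
  recurse(model$root_id, seq_len(nrow(ft$values)))
  if (max(imp) > 0) imp <- 100 * imp / max(imp)
  sort(imp, decreasing = TRUE)
}
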