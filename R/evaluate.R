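#' Confusion-matrix performance metrics
#'
#' Counts true/false positives and negatives (positive class =
#' `node_positive`) and derives sensitivity, specificity, accuracy and
#' positive predictive value as percentages.  Values are carried at
#' full precision; rounding to two decimals happens only in the print
#' method, so 32/35 prints as 91.43.
#'
#' @param predictions,truth Equal-length label vectors.
#' @param mode One of `"learning"`, `"cv"`, `"blind_test"`.
#' @return A list of class `performance_report` with counts `tp`,
#'   `fp`, `tn`, `fn` and percentage metrics `sensitivity`,
#'   `specificity`, `accuracy`, `ppv` (`NA` when no positives are
#'   predicted).
#' @export
compute_metrics <- function(predictions, truth,
                            mode = c("learning", "cv", "blind_test")) {
  mode <- match.arg(mode)
  if (length(predictions) != length(truth))
    stop("predictions and truth must have equal length")
  pos <- "node_positive"
  tp <- sum(predictions == pos & truth == pos)
  fp <- sum(predictions == pos & truth != pos)
  tn <- sum(predictions != pos & truth != pos)
  fn <- sum(predictions != pos & truth == pos)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, mode = mode,
                 sensitivity = pct(tp, tp + fn),
                 specificity = pct(tn, tn + fp),
                 accuracy = pct(tp + tn, length(truth)),
                 ppv = pct(tp, tp + fp)),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  f <- function(v) if (is.na(v)) "n/a" else sprintf("%.2f%%", v)
  cat(sprintf(paste0("<performance_report> mode=%s\n",
                     "  sensitivity %s (%d/%d)  specificity %s (%d/%d)\n",
                     "  accuracy    %s (%d/%d)  PPV         %s (%d/%d)\n"),
              x$mode, f(x$sensitivity), x$tp, x$tp + x$fn,
              f(x$specificity), x$tn, x$tn + x$fp,
              f(x$accuracy), x$tp + x$tn, x$tp + x$fp + x$tn + x$fn,
              f(x$ppv), x$tp, x$tp + x$fp))
  invisible(x)
}

#' Run the full simulated experiment
#'
#' Simulates a training cohort (default 70 node-positive / 75
#' node-negative) and a blind-test cohort (35/30), preprocesses and
#' peak-detects them (or samples peak matrices directly when
#' `matrix_only = TRUE`), screens clusters univariately, fits the
#' oblique tree, and reports learning-mode, cross-validated and
#' blind-test performance for both the freshly trained tree and the
#' published fixed tree.
#'
#' @param gen_config A [generator_config()].
#' @param config A [pipeline_config()].
#' @param params A [tree_params()].
#' @param seed Integer master seed; every stage derives its own stream
#'   from it.
#' @param n_train,n_test Length-2 vectors `c(n_pos, n_neg)`.
#' @param matrix_only Skip spectrum rendering and sample feature
#'   matrices directly (fast classifier-level path).
#' @return A list of class `seldi_experiment` with the matrices, the
#'   screen, the fitted tree and a `reports` list (`learning`, `cv`,
#'   `blind_test`, `published_training`, `published_blind`), plus
#'   provenance.
#' @export
run_experiment <- function(gen_config = generator_config(),
                           config = pipeline_config(),
                           params = tree_params(), seed = 1L,
                           n_train = c(70L, 75L), n_test = c(35L, 30L),
                           matrix_only = FALSE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("experiment stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (matrix_only) {
    train_pm <- stage("simulate", generate_feature_matrix(
      gen_config, n_train[1], n_train[2], seed = derive_seed(seed, 1)))
    test_pm <- stage("simulate", generate_feature_matrix(
      gen_config, n_test[1], n_test[2], seed = derive_seed(seed, 2)))
  } else {
    train <- stage("simulate", generate_cohort(
      gen_config, n_train[1], n_train[2], role = "training",
      seed = derive_seed(seed, 1)))
    test <- stage("simulate", generate_cohort(
      gen_config, n_test[1], n_test[2], role = "test",
      seed = derive_seed(seed, 2)))
    train <- stage("preprocess", preprocess_cohort(train, config))
    test <- stage("preprocess", preprocess_cohort(test, config))
    train_pm <- stage("detect", build_peak_matrix(train, config))
    test_pm <- stage("detect", build_peak_matrix(test, config))
  }
  screen <- stage("t_screen", t_test_peaks(train_pm, alpha = config$alpha_report))
  selected <- screen_differential(screen, config$alpha_strict,
                                  config$alpha_report)
  tree <- stage("train", fit_tree(train_pm, params = params,
                                  seed = derive_seed(seed, 3)))
  unpruned <- stage("train", fit_tree(
    train_pm,
    params = tree_params(max_depth = params$max_depth, min_node_size = 1L,
                         allow_oblique = params$allow_oblique,
                         n_restarts = params$n_restarts,
                         cv_folds = params$cv_folds, prune = FALSE),
    seed = derive_seed(seed, 3)))
  cv <- stage("cross_validate", cross_validate(train_pm, params = params,
                                               seed = derive_seed(seed, 4)))
  pub <- published_tree()
  reports <- list(
    learning = compute_metrics(predict(unpruned, train_pm), train_pm$labels,
                               mode = "learning"),
    cv = cv$report,
    blind_test = compute_metrics(predict(tree, test_pm), test_pm$labels,
                                 mode = "blind_test"),
    published_training = compute_metrics(predict(pub, train_pm),
                                         train_pm$labels, mode = "learning"),
    published_blind = compute_metrics(predict(pub, test_pm), test_pm$labels,
                                      mode = "blind_test"))
  structure(list(train_matrix = train_pm, test_matrix = test_pm,
                 screen = screen, selected = selected, tree = tree,
                 unpruned_tree = unpruned, cv = cv, reports = reports,
                 provenance = list(seed = as.integer(seed),
                                   matrix_only = matrix_only,
                                   n_train = n_train, n_test = n_test,
                                   package_version =
                                     as.character(utils::packageVersion("selditree")))),
            class = "seldi_experiment")
}

#' @export
print.seldi_experiment <- function(x, ...) {
  cat("<seldi_experiment>\n")
  for (nm in names(x$reports)) {
    cat("--", nm, "\n")
    print(x$reports[[nm]])
  }
  invisible(x)
}
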