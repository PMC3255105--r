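test_that("gini impurity: pure, maximal, arithmetic", {
  expect_equal(gini_impurity(c(10, 0)), 0)
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(66, 4)), 1 - (66 / 70)^2 - (4 / 70)^2)
  expect_error(gini_impurity(c(0, 0)), "not all zero")
})

test_that("axis splits match exhaustive enumeration", {
  y <- c("node_positive", "node_positive", "node_negative",
         "node_positive", "node_negative", "node_negative")
  x <- c(1.0, 2.0, 3.0, 4.0, 5.0, 6.0)
  got <- best_axis_split(x, y)
  oracle <- enum_axis_oracle(x, y)
  expect_equal(got$decrease, oracle$decrease, tolerance = 1e-12)
  expect_equal(got$threshold, oracle$threshold)

  # random parameterized instances
  for (seed in 1:20) {
    withr::with_seed(seed, {
      n <- sample(4:12, 1)
      x <- round(rnorm(n), 2)
      y <- sample(c("node_positive", "node_negative"), n, replace = TRUE)
    })
    if (length(unique(y)) < 2) next
    expect_equal(best_axis_split(x, y)$decrease,
                 enum_axis_oracle(x, y)$decrease, tolerance = 1e-12)
  }

  # perfectly separated data: decrease equals parent impurity
  sep <- best_axis_split(c(1, 2, 3, 10, 11), rep(c("node_positive",
                                                   "node_negative"), c(3, 2)))
  expect_equal(sep$decrease, gini_impurity(c(3, 2)))

  # relabelling classes leaves the chosen threshold unchanged
  y2 <- ifelse(y == "node_positive", "node_negative", "node_positive")
  expect_equal(best_axis_split(x, y)$threshold, best_axis_split(x, y2)$threshold)

  # constant feature
  const <- best_axis_split(rep(1, 5), rep(c("node_positive", "node_negative"),
                                          c(2, 3)))
  expect_true(is.na(const$threshold))
  expect_equal(const$decrease, 0)
})

test_that("oblique search: oracle equivalence and dominance", {
  # classes separable only by x1 + x2
  x <- cbind(mz_3000 = c(0, 1, 2, 3, 1.5, 2.5, 3.5, 4.5),
             mz_5000 = c(3, 2, 1, 0, 4.5, 3.5, 2.5, 1.5))
  y <- rep(c("node_positive", "node_negative"), each = 4)
  ob <- withr::with_seed(1, best_oblique_split(x, y))
  ax <- max(best_axis_split(x[, 1], y)$decrease,
            best_axis_split(x[, 2], y)$decrease)
  expect_gt(ob$decrease, ax)
  expect_equal(ob$decrease, gini_impurity(c(4, 4)), tolerance = 1e-9)

  # 8-sample 2-feature instances vs dense angle-grid oracle
  for (seed in 1:15) {
    withr::with_seed(seed, {
      xi <- matrix(rnorm(16), 8, 2,
                   dimnames = list(NULL, c("mz_3000", "mz_5000")))
      yi <- sample(rep(c("node_positive", "node_negative"), each = 4))
    })
    got <- withr::with_seed(seed + 100, best_oblique_split(xi, yi))
    oracle <- grid_oblique_oracle(xi, yi)
    expect_gte(got$decrease + 1e-6, oracle)
  }

  # dominance in higher dimension
  for (seed in 1:5) {
    withr::with_seed(seed, {
      xi <- matrix(rnorm(150), 30, 5,
                   dimnames = list(NULL, paste0("mz_", 3:7 * 1000)))
      yi <- sample(rep(c("node_positive", "node_negative"), each = 15))
    })
    adec <- max(vapply(1:5, function(j)
      best_axis_split(xi[, j], yi)$decrease, 1))
    ob <- withr::with_seed(seed, best_oblique_split(xi, yi))
    expect_gte(ob$decrease + 1e-12, adec)
  }

  # single candidate feature reduces to the axis split
  one <- best_oblique_split(x[, 1, drop = FALSE], y)
  expect_equal(one$decrease, best_axis_split(x[, 1], y)$decrease)
})

test_that("published tree: structure, routing oracle, boundary convention", {
  pub <- published_tree()
  expect_equal(length(tree_features <- selditree:::tree_features(pub)), 5)
  expect_equal(tree_features, c(3104, 3781, 5867, 7970, 9290))
  types <- vapply(pub$nodes, `[[`, "", "type")
  expect_equal(sum(types == "leaf"), 3)

  # hand arithmetic on the printed coefficients and panel means
  p <- differential_peak_panel()
  mean_of <- function(mz, cls) p[p$mz == mz, paste0("mean_", cls)]
  co <- c(-0.075, -0.231, 0.157, 0.086, 0.953)
  s1_pos <- sum(co * vapply(c(3104, 3781, 5867, 7970, 9290),
                            mean_of, 1, cls = "pos"))
  s1_neg <- sum(co * vapply(c(3104, 3781, 5867, 7970, 9290),
                            mean_of, 1, cls = "neg"))
  expect_equal(s1_pos, 3.395572, tolerance = 1e-9)
  expect_equal(s1_neg, 0.024288, tolerance = 1e-9)
  expect_gt(s1_pos, 1.122)   # positives exit right at the root
  expect_lt(s1_neg, 1.122)   # negatives go left into splitter 2
  s2_neg <- 0.410 * mean_of(3781, "neg") - 0.912 * mean_of(5867, "neg")
  expect_gt(s2_neg, 0.248)   # ... and exit at the node-negative terminal

  expect_equal(predict(pub, panel_mean_vector("node_positive")),
               "node_positive")
  expect_equal(predict(pub, panel_mean_vector("node_negative")),
               "node_negative")
  routed <- predict(pub, panel_mean_vector("node_negative"), type = "node")
  expect_equal(routed$terminal_node, 4)        # Terminal Node 2

  # the alternative topology (splitter 2 as the right child) is
  # inconsistent with the class means landing on their own terminals
  alt <- pub
  alt$nodes[[1]]$left_child <- 5L
  alt$nodes[[1]]$right_child <- 2L
  expect_false(predict(alt, panel_mean_vector("node_positive")) ==
                 "node_positive" &&
               predict(alt, panel_mean_vector("node_negative")) ==
                 "node_negative")

  # a sample exactly on the root threshold routes LEFT
  x <- panel_mean_vector("node_negative")
  co_named <- pub$nodes[[1]]$coefficients
  j <- match(paste0("mz_", names(co_named)), colnames(x))
  x[1, j[5]] <- (1.122 - sum(co_named[-5] * x[1, j[-5]])) / co_named[5]
  expect_equal(predict(pub, x, type = "node")$path[1], "1>2>4")

  # missing feature is an explicit error naming the m/z
  no9290 <- panel_mean_vector("node_positive")
  no9290 <- no9290[, colnames(no9290) != "mz_9290", drop = FALSE]
  expect_error(predict(pub, no9290), "9290")
})

test_that("published tree separates the panel distributions (< 1% error/class)", {
  cfg <- generator_config()
  pub <- published_tree()
  pos <- generate_feature_matrix(cfg, 10000, 0, seed = 31,
                                 differential_only = TRUE)
  neg <- generate_feature_matrix(cfg, 0, 10000, seed = 32,
                                 differential_only = TRUE)
  err_pos <- mean(predict(pub, pos) != "node_positive")
  err_neg <- mean(predict(pub, neg) != "node_negative")
  expect_lt(err_pos, 0.01)
  expect_lt(err_neg, 0.01)
})

test_that("fit_tree: purity growth, determinism, degenerate input", {
  cfg <- generator_config()
  pm <- generate_feature_matrix(cfg, 40, 40, seed = 8)
  unpruned <- fit_tree(pm, params = tree_params(min_node_size = 1,
                                                prune = FALSE), seed = 2)
  expect_equal(predict(unpruned, pm), pm$labels)   # zero resubstitution error

  # pruned trees stay small across seeds at these effect sizes
  for (seed in 1:5) {
    pmi <- generate_feature_matrix(cfg, 70, 75, seed = seed + 50)
    tr <- fit_tree(pmi, params = tree_params(cv_folds = 5), seed = seed)
    n_internal <- sum(vapply(tr$nodes, `[[`, "", "type") == "split")
    expect_lte(n_internal, 5)
  }

  # same seed twice: identical serialized models
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_tree_model(fit_tree(pm, seed = 4), f1)
  write_tree_model(fit_tree(pm, seed = 4), f2)
  expect_identical(readLines(f1), readLines(f2))

  # single-class input collapses to a single leaf
  solo <- fit_tree(pm$values[pm$labels == "node_positive", ],
                   rep("node_positive", 40), seed = 1)
  expect_length(solo$nodes, 1)
  expect_equal(solo$nodes[[1]]$label, "node_positive")
})

test_that("variable importance: scaling contract", {
  cfg <- generator_config()
  pm <- generate_feature_matrix(cfg, 50, 50, seed = 13)
  tr <- fit_tree(pm, params = tree_params(prune = FALSE), seed = 3)
  imp <- variable_importance(tr, pm)
  expect_equal(max(imp), 100)
  expect_true(all(imp >= 0 & imp <= 100))
  # without surrogate credit, features absent from every split score 0
  imp0 <- variable_importance(tr, pm, surrogates = FALSE)
  used <- paste0("mz_", selditree:::tree_features(tr))
  expect_true(all(imp0[setdiff(names(imp0), used)] == 0))
  expect_true(all(imp0[used] > 0))
})

test_that("cross-validation: separability, null labels, stratification guard", {
  # one feature separates the classes with a wide margin, the rest are
  # pure noise, so every fold tree must learn the same boundary
  labels <- rep(c("node_positive", "node_negative"), each = 30)
  vals <- withr::with_seed(14, cbind(
    mz_5867 = ifelse(labels == "node_positive", 3.5, 0.2) + rnorm(60, 0, 0.1),
    mz_4000 = rnorm(60, 5, 1), mz_8000 = rnorm(60, 2, 0.5)))
  rownames(vals) <- sprintf("S%03d", 1:60)
  mz <- c(5867, 4000, 8000)[order(c(5867, 4000, 8000))]
  pm <- peak_matrix(pmax(vals[, order(c(5867, 4000, 8000))], 0),
                    data.frame(cluster_id = 1:3, mz_center = mz,
                               window_lo = mz * 0.9975,
                               window_hi = mz * 1.0025, prevalence = 1),
                    labels)
  fast <- tree_params(cv_folds = 5, prune = FALSE)
  cv <- cross_validate(pm, params = fast, seed = 6)
  expect_equal(cv$report$accuracy, 100)
  expect_identical(cross_validate(pm, params = fast, seed = 6)$report,
                   cv$report)

  # permuted labels: accuracy within binomial noise of the majority rate
  pm_null <- pm
  pm_null$labels <- withr::with_seed(7, sample(pm$labels))
  cv0 <- cross_validate(pm_null, params = fast, seed = 6)
  expect_lt(cv0$report$accuracy, 75)

  expect_error(cross_validate(pm, params = tree_params(cv_folds = 40),
                              seed = 1), "cv_folds")
})
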