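test_that("gini impurity matches its closed form and validates input", {
  expect_equal(gini_impurity(c(1, 0, 0)), 0)
  expect_equal(gini_impurity(rep(1 / 8, 8)), 0.875)
  expect_equal(gini_impurity(c(0.5, 0.5)), 0.5)
  expect_error(gini_impurity(c(0.5, 0.4)), "sum to 1")
  expect_error(gini_impurity(c(1.2, -0.2)), "nonnegative")
})

test_that("node importance is the weighted Gini reduction", {
  # pure 50/50 split of a balanced two-class parent
  expect_equal(node_importance(0.5, c(0, 0), c(1, 0.5, 0.5)), 0.5)
  # children identical in composition to the parent: no reduction
  expect_equal(node_importance(0.5, c(0.5, 0.5), c(1, 0.5, 0.5)), 0)
  expect_error(node_importance(0.5, c(0, 0), c(1, 0.3, 0.5)), "sum")
  # nonnegativity over random valid splits (Gini concavity)
  withr::with_seed(4, {
    for (i in 1:50) {
      na <- rmultinom(1, 40, c(0.3, 0.3, 0.4))[, 1]
      nb <- rmultinom(1, 60, c(0.2, 0.5, 0.3))[, 1]
      np <- na + nb
      g <- function(n) if (sum(n) == 0) 0 else sum(n / sum(n) * (1 - n / sum(n)))
      I <- node_importance(g(np), c(g(na), g(nb)),
                           c(1, sum(na) / 100, sum(nb) / 100))
      expect_gte(I, -1e-12)
    }
  })
})

test_that("decision_tree rejects counts that do not partition", {
  nodes <- data.frame(node_id = 1:3, left = c(2L, NA, NA),
                      right = c(3L, NA, NA), feature = c(1L, NA, NA))
  bad <- rbind(c(10, 10), c(5, 5), c(4, 5))
  expect_error(decision_tree(nodes, bad), "partition")
})

test_that("tree importances match exhaustive enumeration oracles on a depth-3 tree", {
  tree <- build_depth3_tree()
  expect_equal(tree_feature_importance(tree, 5),
               oracle_tree_importance(tree, 5))
  for (cl in 1:3) {
    expect_equal(tree_category_importance(tree, cl, 5),
                 oracle_category_importance(tree, cl, 5))
  }
  # support union of category maps equals global support
  cat_sum <- Reduce("+", lapply(1:3, tree_category_importance, tree = tree,
                                n_features = 5))
  expect_equal(cat_sum > 0, tree_feature_importance(tree, 5) > 0)
})

test_that("a stump attributes mass only to its split feature and class", {
  nodes <- data.frame(node_id = 1:3, left = c(2L, NA, NA),
                      right = c(3L, NA, NA), feature = c(4L, NA, NA))
  counts <- rbind(c(10, 10, 0), c(9, 1, 0), c(1, 9, 0))
  stump <- decision_tree(nodes, counts)
  a_map <- tree_category_importance(stump, 1, 6)
  expect_true(a_map[4] > 0 && all(a_map[-4] == 0))
  expect_equal(tree_category_importance(stump, 3, 6), rep(0, 6))
})

test_that("leaf feature sets propagate to the right category maps", {
  # class-A leaves sit under features {1, 2}; class-B leaves under {1, 3}
  nodes <- data.frame(node_id = 1:7,
                      left = c(2L, 4L, 6L, NA, NA, NA, NA),
                      right = c(3L, 5L, 7L, NA, NA, NA, NA),
                      feature = c(1L, 2L, 3L, NA, NA, NA, NA))
  counts <- rbind(c(20, 20), c(18, 4), c(2, 16),
                  c(14, 1), c(4, 3), c(1, 11), c(1, 5))
  tree <- decision_tree(nodes, counts)
  a <- tree_category_importance(tree, 1, 3)
  b <- tree_category_importance(tree, 2, 3)
  expect_true(all(a[1:2] > 0) && a[3] == 0)
  expect_true(all(b[c(1, 3)] > 0) && b[2] == 0)
})

test_that("forest attribution agrees with ranger's own impurity importance", {
  fx <- make_separable_features(15, 12, n_classes = 4, margin = 3,
                                noise = 1, seed = 9)
  fit <- ranger::ranger(x = fx$x, y = fx$y, num.trees = 40, seed = 1,
                        keep.inbag = TRUE, importance = "impurity",
                        num.threads = 1)
  maps <- importance_maps(fit, fx$x, fx$y, n_freq = 3, n_bin = 4)
  mine <- as.vector(t(unclass(maps$global)))
  ref <- unname(fit$variable.importance)
  expect_gt(cor(mine, ref), 0.999)
  expect_equal(mine, ref / sum(ref), tolerance = 1e-6)
  # category maps are nonnegative and their support matches the global map
  cat_sum <- Reduce("+", lapply(maps$category, function(m)
    as.vector(t(unclass(m)))))
  expect_true(all(cat_sum >= 0))
  expect_equal(cat_sum > 0, mine > 0)
})

test_that("a single informative feature dominates global importance", {
  withr::with_seed(12, {
    y <- factor(rep(c("a", "b"), each = 100))
    x <- matrix(rnorm(200 * 20), 200, 20)
    x[, 7] <- ifelse(y == "a", 2, -2) + rnorm(200, sd = 0.3)
    colnames(x) <- paste0("x", 1:20)
  })
  fit <- fit_probe_forest(x, y, n_trees = 50, seed = 2)
  gm <- importance_maps(fit, x, y, n_freq = 4, n_bin = 5)$global
  v <- as.vector(t(unclass(gm)))
  expect_gt(v[7], 0.5)
  expect_equal(sum(v), 1)
})

test_that("averaging importance maps is cell-wise and normalization-aware", {
  m1 <- matrix(c(2, 0, 0, 0), 2, 2)
  m2 <- matrix(c(0, 0, 0, 6), 2, 2)
  avg <- average_importance(list(m1, m2))
  expect_equal(unclass(avg), matrix(c(0.5, 0, 0, 0.5), 2, 2),
               ignore_attr = TRUE)
  expect_equal(unclass(average_importance(list(m1, m1), normalize = FALSE)),
               m1, ignore_attr = TRUE)
  withr::with_seed(5, maps <- lapply(1:10, function(i) matrix(runif(24), 4, 6)))
  avg2 <- average_importance(maps, normalize = FALSE)
  oracle <- matrix(colMeans(do.call(rbind, lapply(maps, as.vector))), 4, 6)
  expect_equal(unclass(avg2), oracle, ignore_attr = TRUE)
  expect_error(average_importance(list(m1, matrix(0, 3, 3))), "shape")
})

test_that("map comparison masks extreme cells and is antisymmetric", {
  withr::with_seed(6, {
    a <- matrix(rnorm(7008), 146, 48)
    b <- matrix(0, 146, 48)
  })
  same <- compare_maps(a, a, k = 4)
  expect_false(any(same$positive) || any(same$negative))
  d_sd <- sd(as.vector(a))
  a2 <- a; a2[100, 20] <- a[100, 20] + 10 * d_sd
  cmp <- compare_maps(a2, b, k = 4)
  expect_true(cmp$positive[100, 20])
  expect_lte(sum(cmp$positive), 3) # the spiked cell plus at most noise tail
  swapped <- compare_maps(b, a2, k = 4)
  expect_equal(swapped$negative, cmp$positive)
  expect_equal(swapped$positive, cmp$negative)
})

test_that("group contrasts label shared and dominant regions", {
  withr::with_seed(14, {
    base <- matrix(rexp(7008, 10), 146, 48)
    base[60:70, 20:25] <- base[60:70, 20:25] + 2 # shared important region
    ga <- list(base + matrix(rnorm(7008, sd = 0.01), 146, 48))
    gb <- list(base + matrix(rnorm(7008, sd = 0.01), 146, 48))
  })
  same <- group_importance_contrast(ga, ga)
  expect_true(any(same$labels == "both_important"))
  expect_false(any(same$labels %in% c("a_dominant", "b_dominant")))
  gb2 <- lapply(gb, function(m) { m[100:110, 30:35] <- m[100:110, 30:35] + 3; m })
  dom <- group_importance_contrast(ga, gb2)
  expect_true(all(dom$labels[100:110, 30:35] == "b_dominant"))
  expect_error(group_importance_contrast(list(), gb), "at least one")
})
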