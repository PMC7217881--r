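test_that("category mean activity is a cell-wise mean with linear structure", {
  withr::with_seed(2, f <- matrix(runif(16 * 7008, 0.5, 2), 16, 7008))
  y <- factor(rep(sf_categories(), each = 2))
  m <- category_mean_activity(f, y, "face")
  idx <- which(y == "face")
  expect_equal(m, unflatten_tf(colMeans(f[idx, ])), ignore_attr = TRUE)
  # identical trials: the map itself
  f2 <- f; f2[idx, ] <- rep(f[idx[1], ], each = 2)
  expect_equal(category_mean_activity(f2, y, "face"),
               unflatten_tf(f[idx[1], ]), ignore_attr = TRUE)
  # balanced design: mean of category means = grand mean
  all_means <- lapply(sf_categories(), category_mean_activity,
                      features = f, labels = y)
  expect_equal(Reduce("+", all_means) / 8, unflatten_tf(colMeans(f)),
               ignore_attr = TRUE)
  expect_error(category_mean_activity(f, factor(rep("house", 16)), "face"),
               "No trials")
})

test_that("the importance mask retains exactly the mu + sigma exceedances", {
  withr::with_seed(3, imp <- matrix(rexp(7008), 146, 48))
  mask <- importance_mask(imp)
  expect_equal(unclass(mask),
               imp > mean(imp) + sd(as.vector(imp)), ignore_attr = TRUE)
  expect_equal(sum(mask), sum(imp > attr(mask, "threshold")))
})

test_that("masking keeps retained cells in fixed order and drops the rest", {
  withr::with_seed(4, act <- matrix(runif(7008, 0.5, 3), 146, 48))
  full <- matrix(TRUE, 146, 48)
  expect_equal(unname(apply_mask(act, full)), unname(flatten_tf(act)))
  mask10 <- matrix(FALSE, 146, 48)
  cells <- cbind(c(2, 2, 5, 9, 30, 80, 100, 120, 140, 146),
                 c(1, 40, 12, 7, 25, 33, 48, 2, 44, 20))
  mask10[cells] <- TRUE
  v <- apply_mask(act, mask10)
  expect_length(v, 10)
  # row-major order: cells of earlier frequency rows come first
  expect_equal(unname(v[1]), act[2, 1])
  expect_equal(unname(v[2]), act[2, 40])
  expect_error(apply_mask(act, matrix(TRUE, 10, 10)), "Shapes")
})

test_that("cosine distance spans [0, 2] with the canonical anchors", {
  u <- c(1, 2, 3)
  expect_equal(cosine_distance(u, 5 * u), 0)
  expect_equal(cosine_distance(c(1, 0), c(0, 1)), 1)
  expect_equal(cosine_distance(u, -u), 2)
  expect_error(cosine_distance(u, c(0, 0, 0)), "zero vector")
  expect_error(cosine_distance(u, c(1, 2)), "length")
})

test_that("complete-linkage heights match the brute-force oracle", {
  withr::with_seed(7, x <- matrix(rnorm(6 * 10), 6, 10))
  cl <- cluster_probes(x, center = FALSE, h = 10)
  expect_equal(sort(cl$merge_heights),
               sort(oracle_complete_linkage_heights(x)), tolerance = 1e-12)
  expect_true(all(diff(cl$merge_heights) >= -1e-12))
})

test_that("direction bundles are recovered and opposite patterns separate", {
  withr::with_seed(9, {
    up <- rep(1, 30) + matrix(rnorm(20 * 30, sd = 0.05), 20, 30, byrow = TRUE)
    down <- -rep(1, 30) + matrix(rnorm(20 * 30, sd = 0.05), 20, 30,
                                 byrow = TRUE)
  })
  x <- rbind(up, down)
  rownames(x) <- sprintf("p%02d", 1:40)
  cl <- cluster_probes(x, center = FALSE, h = 0.7)
  truth <- rep(c("up", "down"), each = 20)
  expect_equal(ari(cl$assignment$cluster, truth), 1)
  # increase vs decrease patterns sit near the maximal cosine distance
  expect_gt(cosine_distance(up[1, ], down[1, ]), 1.9)
})

test_that("clustering is invariant to uniform positive rescaling", {
  withr::with_seed(10, x <- matrix(rnorm(8 * 12), 8, 12))
  rownames(x) <- paste0("p", 1:8)
  a <- cluster_probes(x, center = FALSE, h = 0.5)
  b <- cluster_probes(3 * x, center = FALSE, h = 0.5)
  expect_equal(a$assignment, b$assignment)
  expect_equal(a$merge_heights, b$merge_heights, tolerance = 1e-12)
})

test_that("degenerate clustering inputs are handled deterministically", {
  x <- matrix(rep(c(1, 2, 1.5), each = 4), 4, 3)
  rownames(x) <- paste0("p", 1:4)
  cl <- cluster_probes(x, center = FALSE)
  expect_equal(unique(cl$assignment$cluster), 1L)
  expect_true(all(cl$merge_heights < 1e-12))
  # all-zero centered vectors are excluded with a warning
  ones <- matrix(1, 3, 5)
  rownames(ones) <- paste0("z", 1:3)
  expect_warning(cl2 <- cluster_probes(ones, center = TRUE), "all-zero")
  expect_equal(nrow(cl2$assignment), 0)
})

test_that("cluster summaries aggregate F1 and polypredictive fractions", {
  x <- rbind(a = c(1, 1), b = c(1.1, 1), c = c(-1, -1))
  cl <- cluster_probes(x, center = FALSE, h = 0.5)
  f1 <- c(a = 0.4, b = 0.6, c = 0.8)
  status <- c(a = "monopredictive", b = "monopredictive",
              c = "polypredictive")
  s <- summarize_clusters(cl, x, f1, status, top_only = FALSE)
  big <- s[s$n == 2, ]
  expect_equal(big$mean_f1, 0.5)
  expect_equal(big$poly_fraction, 0)
  small <- s[s$n == 1, ]
  expect_equal(small$poly_fraction, 1)
  expect_equal(small$pattern[[1]], c(-1, -1), ignore_attr = TRUE)
})
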