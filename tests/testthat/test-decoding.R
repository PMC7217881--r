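test_that("per-class F1 follows the harmonic-mean definition", {
  expect_equal(f1_score(c("a", "b", "a"), c("a", "b", "a"), "a"), 1)
  # precision 0.5, recall 0.25 -> 1/3
  truth <- c("a", "a", "a", "a", "b", "b")
  pred <- c("a", "b", "b", "b", "a", "b")
  expect_equal(f1_score(truth, pred, "a"), 1 / 3)
  # precision = recall = p gives F1 = p
  expect_equal(2 * 0.125 * 0.125 / (0.125 + 0.125), 0.125)
  # class never predicted correctly -> 0
  expect_equal(f1_score(c("a", "b"), c("b", "a"), "a"), 0)
  expect_warning(out <- f1_score(c("b", "b"), c("a", "b"), "a"), "absent")
  expect_equal(out, 0)
  expect_error(f1_score("a", c("a", "b"), "a"), "length")
})

test_that("F1 is invariant to consistent relabeling", {
  withr::with_seed(3, {
    truth <- sample(letters[1:4], 60, replace = TRUE)
    pred <- sample(letters[1:4], 60, replace = TRUE)
  })
  map <- c(a = "w", b = "x", c = "y", d = "z")
  expect_equal(unname(per_class_f1(truth, pred, letters[1:4])),
               unname(per_class_f1(map[truth], map[pred], map[letters[1:4]])))
})

test_that("stratified folds balance classes and pooled predictions cover all trials", {
  y <- factor(rep(letters[1:8], each = 50))
  fold <- stratified_folds(y, 5, seed = 2)
  expect_true(all(table(fold, y) == 10))
  fx <- make_separable_features(10, 30, n_classes = 4, margin = 8, seed = 5)
  dec <- crossval_decode(fx$x, fx$y, n_trees = 60, folds = 5, seed = 1)
  expect_length(dec$predictions, length(fx$y))
  expect_false(anyNA(dec$predictions))
  expect_error(crossval_decode(fx$x[1:3, ], fx$y[1:3], folds = 5), "folds")
})

test_that("a separable fixture decodes perfectly, a permuted one at chance", {
  fx <- make_separable_features(50, 40, n_classes = 8, margin = 10,
                                noise = 0.5, seed = 7)
  dec <- crossval_decode(fx$x, fx$y, n_trees = 100, folds = 5, seed = 2)
  expect_true(all(dec$scores$f1 > 0.95))
  y_perm <- withr::with_seed(8, sample(fx$y))
  dec0 <- crossval_decode(fx$x, y_perm, n_trees = 100, folds = 5, seed = 2)
  expect_true(all(dec0$scores$f1 <= 0.39))
})

test_that("the empirical percentile matches an order-statistic oracle", {
  expect_equal(percentile_of(rep(0.125, 50), 99.9), 0.125)
  withr::with_seed(11, pool <- runif(1000))
  s <- sort(pool)
  for (p in c(50, 90, 99, 99.9)) {
    expect_equal(percentile_of(pool, p), s[ceiling(p / 100 * 1000)])
  }
  expect_error(percentile_of(numeric(0), 99), "Empty")
})

test_that("predictivity classification uses a strict threshold and counts", {
  mk <- function(f1) tibble::tibble(category = sf_categories(), f1 = f1)
  expect_equal(classify_predictivity(mk(rep(0.2, 8)))$status, "none")
  r <- classify_predictivity(mk(c(0.5, rep(0.1, 7))))
  expect_equal(r$status, "monopredictive")
  expect_equal(r$predictive_categories, "house")
  expect_equal(classify_predictivity(mk(c(0.45, 0.45, rep(0.1, 6))))$status,
               "polypredictive")
  # strict: exactly at threshold is not predictive
  expect_equal(classify_predictivity(mk(rep(0.390278, 8)))$status, "none")
})

test_that("band restriction selects the stated feature subsets", {
  expect_length(band_rows("full"), 146)
  expect_length(band_rows("low"), 46)   # 46 x 48 = 2208 features
  expect_length(band_rows("gamma"), 100)
  expect_equal(length(band_rows("low")) * 48, 2208)
  expect_error(band_rows("delta"), "Unknown band")
})

test_that("a gamma-band signature decodes better from gamma than from low features", {
  coh <- generate_cohort(
    probe_spec("g", signatures = signature_spec("face", 61, 120, 100, 500, 4)),
    trials_per_category = 10, seed = 23)
  f <- probe_features(coh$epochs[[1]])
  y <- coh$labels[[1]]
  dg <- band_restricted_f1(f, y, "gamma", n_trees = 150, folds = 5, seed = 3)
  dl <- band_restricted_f1(f, y, "low", n_trees = 150, folds = 5, seed = 3)
  f1g <- dg$scores$f1[dg$scores$category == "face"]
  f1l <- dl$scores$f1[dl$scores$category == "face"]
  expect_gte(f1g, f1l)
  expect_gt(f1g, 0.39)
})

test_that("band-group comparison reproduces exact Mann-Whitney results", {
  r <- compare_band_groups(c(1, 2, 3), c(4, 5, 6), c(1, 2, 3))
  full_low <- r[r$comparison == "full vs low", ]
  expect_equal(full_low$statistic, 0)
  expect_equal(full_low$p, 0.1) # exact two-sided: 2/choose(6,3)... = 2/20
  same <- compare_band_groups(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  expect_true(all(same$p_adj == 1))
  expect_error(compare_band_groups(1, c(1, 2), c(1, 2)), "2 probes")
})

test_that("a shifted band effect is detected with high power at the corrected level", {
  hits <- vapply(1:200, function(r) {
    withr::with_seed(1000 + r, {
      full <- rnorm(50, mean = 0.5, sd = 0.1)
      low <- rnorm(50, mean = 0.4, sd = 0.1)
    })
    suppressWarnings(wilcox.test(full, low)$p.value) < 0.001563
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
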