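#' Per-class F1 score
#'
#' `F1 = 2 * precision * recall / (precision + recall)` for one class;
#' 0 when `precision + recall = 0`. If the class is absent from `truths`,
#' recall is undefined and F1 is reported as 0 with a warning.
#'
#' @param truths,predictions Label vectors of equal length.
#' @param class The class to score.
#' @return F1 value in \[0, 1\].
#' @export
#' @examples
#' f1_score(c("a", "a", "b"), c("a", "b", "b"), "a")
f1_score <- function(truths, predictions, class) {
  if (length(truths) != length(predictions)) {
    abort("`truths` and `predictions` must have the same length.")
  }
  truths <- as.character(truths); predictions <- as.character(predictions)
  if (!class %in% truths) {
    warn(paste0("Class '", class, "' absent from truths; F1 reported as 0."))
    return(0)
  }
  tp <- sum(predictions == class & truths == class)
  fp <- sum(predictions == class & truths != class)
  fn <- sum(predictions != class & truths == class)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' @rdname f1_score
#' @param classes Classes to score (default: sorted unique truths).
#' @return `per_class_f1()`: named numeric vector of F1 per class.
#' @export
per_class_f1 <- function(truths, predictions, classes = NULL) {
  classes <- classes %||% sort(unique(as.character(truths)))
  vapply(classes, function(cl) f1_score(truths, predictions, cl), numeric(1))
}

#' Stratified cross-validation folds
#'
#' @param labels Factor of class labels.
#' @param k Number of folds.
#' @param seed Seed for the within-class shuffling.
#' @return Integer fold assignment (1..k), balanced within each class.
#' @export
stratified_folds <- function(labels, k, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  fold <- integer(length(labels))
  cls <- levels(factor(labels))
  for (ci in seq_along(cls)) {
    idx <- sample(which(labels == cls[ci]))
    # offset fold numbering per class so small classes still spread over folds
    fold[idx] <- ((seq_along(idx) - 1 + (ci - 1)) %% k) + 1
  }
  fold
}

#' Cross-validated random-forest decoding of one probe
#'
#' Trains a Gini random forest (bootstrap per tree, square-root feature
#' subsampling per split, unlimited depth) on the flattened 146 x 48 feature
#' maps under stratified k-fold cross-validation; out-of-fold predictions
#' are pooled into a single prediction per trial and scored with per-class
#' F1. Fold-wise F1 standard deviations are retained.
#'
#' @param features Trials x features numeric matrix.
#' @param labels Factor of trial categories (balanced 8-class design).
#' @param n_trees Trees per forest (default 3000).
#' @param folds Number of CV folds (default 5; 400 trials give 320 train /
#'   80 test per fold and 400 pooled predictions).
#' @param seed Seed controlling fold assignment and forest randomness.
#' @param mtry Features sampled per split (default `floor(sqrt(p))`).
#' @return A `probe_decoding` object: list with `scores` (tibble: category,
#'   f1, f1_sd), `predictions`, `truths`, `fold`, and the configuration.
#' @export
crossval_decode <- function(features, labels, n_trees = 3000, folds = 5,
                            seed = 1, mtry = NULL) {
  labels <- factor(labels)
  n <- nrow(features)
  if (n < folds) abort("Fewer trials than folds.")
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("x", seq_len(ncol(features)))
  }
  mtry <- mtry %||% floor(sqrt(ncol(features)))
  fold <- stratified_folds(labels, folds, seed = seed)
  pred <- factor(rep(NA_character_, n), levels = levels(labels))
  fold_f1 <- matrix(NA_real_, folds, nlevels(labels),
                    dimnames = list(NULL, levels(labels)))
  for (k in seq_len(folds)) {
    tr <- fold != k
    if (all(tr)) next
    fit <- ranger::ranger(
      x = features[tr, , drop = FALSE], y = labels[tr],
      num.trees = n_trees, mtry = mtry, splitrule = "gini",
      num.threads = 1, seed = seed + k
    )
    pk <- predict(fit, data = features[!tr, , drop = FALSE],
                  num.threads = 1, seed = seed + k)$predictions
    pred[!tr] <- pk
    fold_f1[k, ] <- suppressWarnings(
      per_class_f1(labels[!tr], pk, classes = levels(labels)))
  }
  f1 <- per_class_f1(labels, pred, classes = levels(labels))
  out <- list(
    scores = tibble::tibble(category = levels(labels), f1 = unname(f1),
                            f1_sd = apply(fold_f1, 2, sd)),
    predictions = pred, truths = labels, fold = fold,
    n_trees = n_trees, folds = folds, seed = seed, mtry = mtry
  )
  class(out) <- "probe_decoding"
  out
}

#' @export
print.probe_decoding <- function(x, ...) {
  cat("<probe_decoding> ", x$folds, "-fold CV, ", x$n_trees, " trees\n",
      sep = "")
  print(x$scores)
  invisible(x)
}

#' Permutation-derived F1 significance threshold
#'
#' Runs cross-validated decoding on null datasets with randomly permuted
#' class labels and pools the per-class F1 values of all classes across
#' permutations (and probes); returns the requested empirical percentile as
#' the chance-level F1 threshold. The reference full-scale protocol (100000
#' permutations, 99.999th percentile) yields 0.390278; reduced-scale runs
#' with a lower percentile are supported and labeled as such.
#'
#' @param feature_sets List of trials x features matrices (null probes).
#' @param labels Factor of trial labels (permuted independently per run).
#' @param n_permutations Number of permuted-label CV runs.
#' @param percentile Percentile of the pooled F1 values (default 99.9 for
#'   reduced-scale runs).
#' @param n_trees,folds Forest and CV parameters for the permutation runs.
#' @param seed Master seed.
#' @return List: `threshold`, `pool` (all per-class F1 values), `percentile`,
#'   `n_permutations`, and `full_scale` (TRUE when run at the reference
#'   protocol's scale).
#' @export
permutation_threshold <- function(feature_sets, labels, n_permutations,
                                  percentile = 99.9, n_trees = 200,
                                  folds = 5, seed = 1) {
  if (!is.list(feature_sets)) feature_sets <- list(feature_sets)
  if (n_permutations < 1) abort("`n_permutations` must be >= 1.")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "perm"))
  pool <- numeric(0)
  for (r in seq_len(n_permutations)) {
    x <- feature_sets[[(r - 1) %% length(feature_sets) + 1]]
    perm <- sample(factor(labels))
    dec <- crossval_decode(x, perm, n_trees = n_trees, folds = folds,
                           seed = derive_seed(seed, paste0("perm", r)))
    pool <- c(pool, dec$scores$f1)
  }
  list(threshold = percentile_of(pool, percentile), pool = pool,
       percentile = percentile, n_permutations = n_permutations,
       full_scale = n_permutations >= 1e5 && percentile >= 99.999)
}

#' Empirical percentile as an order statistic
#'
#' `percentile_of(x, p)` returns the smallest order statistic whose rank is
#' at least `p/100 * length(x)` (inverse empirical CDF).
#'
#' @param x Numeric pool.
#' @param p Percentile in (0, 100\].
#' @return The order-statistic percentile.
#' @export
percentile_of <- function(x, p) {
  if (length(x) == 0) abort("Empty pool.")
  s <- sort(x)
  s[max(1L, ceiling(p / 100 * length(s)))]
}

#' Label a probe's predictivity from its decoding scores
#'
#' A probe is predictive of a category when that category's cross-validated
#' F1 strictly exceeds the threshold (default: the full-scale
#' permutation-derived 0.390278). Exactly one predictive category makes the
#' probe monopredictive; two or more, polypredictive.
#'
#' @param decoding A `probe_decoding` (or its `scores` tibble).
#' @param threshold F1 threshold (default 0.390278).
#' @return List: `predictive_categories`, `status`
#'   (`"none"`, `"monopredictive"` or `"polypredictive"`).
#' @export
classify_predictivity <- function(decoding, threshold = 0.390278) {
  scores <- if (inherits(decoding, "probe_decoding")) decoding$scores
            else decoding
  cats <- scores$category[scores$f1 > threshold]
  status <- if (length(cats) == 0) "none"
            else if (length(cats) == 1) "monopredictive"
            else "polypredictive"
  list(predictive_categories = cats, status = status)
}

#' Frequency rows of a spectral band
#'
#' Bands follow the half-open grid (centers 4..149 Hz): `"full"` 4-150 Hz
#' (146 rows), `"low"` 4-50 Hz (46 rows), `"gamma"` broadband gamma
#' 50-150 Hz (100 rows).
#'
#' @param band One of `"full"`, `"low"`, `"gamma"`.
#' @return Integer vector of frequency-row indices (1-based on the 4..149
#'   grid).
#' @export
band_rows <- function(band) {
  f0 <- 4:149
  switch(band,
    full = seq_along(f0),
    low = which(f0 < 50),
    gamma = which(f0 >= 50),
    abort(paste0("Unknown band '", band,
                 "'; use \"full\", \"low\" or \"gamma\"."))
  )
}

#' Decoding restricted to one spectral band
#'
#' Runs the identical CV protocol on the feature columns whose frequency row
#' lies in the band.
#'
#' @inheritParams crossval_decode
#' @param band `"full"` (4-150 Hz), `"low"` (4-50 Hz) or `"gamma"`
#'   (50-150 Hz).
#' @param n_bins Time bins per frequency row (default 48).
#' @return A `probe_decoding` on the restricted features.
#' @export
band_restricted_f1 <- function(features, labels, band, n_trees = 3000,
                               folds = 5, seed = 1, n_bins = 48) {
  rows <- band_rows(band)
  cols <- as.vector(outer(seq_len(n_bins), (rows - 1L) * n_bins, "+"))
  crossval_decode(features[, cols, drop = FALSE], labels,
                  n_trees = n_trees, folds = folds, seed = seed)
}

#' Compare per-probe predictive power across spectral bands
#'
#' Two-sided Mann-Whitney U tests between each pair of band groups,
#' Bonferroni-corrected for the number of comparisons performed.
#'
#' @param f1_full,f1_low,f1_gamma Per-probe F1 values (e.g. each probe's
#'   best per-class F1) under the three band restrictions.
#' @return Tibble: comparison, statistic (U), p, p_adj.
#' @export
compare_band_groups <- function(f1_full, f1_low, f1_gamma) {
  groups <- list(full = f1_full, low = f1_low, gamma = f1_gamma)
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  res <- purrr::map_dfr(pairs, function(pr) {
    a <- groups[[pr[1]]]; b <- groups[[pr[2]]]
    if (length(a) < 2 || length(b) < 2) {
      abort("Each band group needs at least 2 probes.")
    }
    wt <- suppressWarnings(wilcox.test(a, b, exact = TRUE))
    tibble::tibble(comparison = paste(pr, collapse = " vs "),
                   statistic = unname(wt$statistic), p = wt$p.value)
  })
  res$p_adj <- pmin(res$p * nrow(res), 1)
  res
}

#' Decode every probe of a cohort
#'
#' @param features_by_probe Named list of trials x features matrices.
#' @param labels_by_probe List of matching label factors.
#' @param n_trees,folds Forest and CV parameters.
#' @param threshold Predictivity threshold on per-class F1.
#' @param seed Master seed; per-probe seeds are derived by stable hashing of
#'   the probe id.
#' @return Tibble: probe_id, decoding (list of `probe_decoding`), status,
#'   predictive_categories (list), max_f1.
#' @export
decode_cohort <- function(features_by_probe, labels_by_probe,
                          n_trees = 3000, folds = 5,
                          threshold = 0.390278, seed = 1) {
  ids <- names(features_by_probe) %||%
    paste0("probe", seq_along(features_by_probe))
  if (length(features_by_probe) == 0) {
    return(tibble::tibble(probe_id = character(0), decoding = list(),
                          status = character(0),
                          predictive_categories = list(),
                          max_f1 = numeric(0)))
  }
  purrr::map_dfr(seq_along(features_by_probe), function(p) {
    dec <- crossval_decode(features_by_probe[[p]], labels_by_probe[[p]],
                           n_trees = n_trees, folds = folds,
                           seed = derive_seed(seed, ids[p]))
    pred <- classify_predictivity(dec, threshold)
    tibble::tibble(probe_id = ids[p], decoding = list(dec),
                   status = pred$status,
                   predictive_categories = list(pred$predictive_categories),
                   max_f1 = max(dec$scores$f1))
  })
}
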