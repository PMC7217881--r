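# Independent oracles and shared fixtures. Oracles deliberately use a
# different code path (plain recursion / exhaustive enumeration) from the
# implementations they check.

# Mean binned ratio of a TF map inside a frequency x time rectangle.
region_ratio <- function(map, freq_lo, freq_hi, t_on, t_off) {
  f0 <- 4:149
  centers <- -500 + (seq_len(48) - 0.5) * 31.25
  mean(map[f0 >= freq_lo & f0 <= freq_hi, centers >= t_on & centers <= t_off])
}

# Fraction of top-decile importance mass inside the dilated rectangle
# (+/- 4 Hz, +/- 2 bins).
rect_top_decile_mass <- function(map, freq_lo, freq_hi, t_on, t_off) {
  map <- unclass(map)
  f0 <- 4:149
  centers <- -500 + (seq_len(48) - 0.5) * 31.25
  rect <- outer(f0 >= freq_lo - 4 & f0 <= freq_hi + 4,
                centers >= t_on - 62.5 & centers <= t_off + 62.5, "&")
  sel <- map > quantile(as.vector(map), 0.9)
  sum(map[sel & rect]) / sum(map[sel])
}

# Recursive per-feature Gini importance: enumerate every node from the
# root, computing impurities and fraction-weighted reductions directly.
oracle_tree_importance <- function(tree, n_features) {
  counts <- tree$counts
  n_tot <- sum(counts[1, ])
  g_of <- function(i) {
    n <- sum(counts[i, ])
    if (n == 0) return(0)
    p <- counts[i, ] / n
    sum(p * (1 - p))
  }
  out <- numeric(n_features)
  recurse <- function(i) {
    l <- tree$nodes$left[i]
    if (is.na(l)) return(invisible())
    r <- tree$nodes$right[i]
    imp <- (sum(counts[i, ]) * g_of(i) - sum(counts[l, ]) * g_of(l) -
              sum(counts[r, ]) * g_of(r)) / n_tot
    f <- tree$nodes$feature[i]
    out[f] <<- out[f] + imp
    recurse(l); recurse(r)
  }
  recurse(1)
  out
}

# Exhaustive path enumeration: collect every root-to-leaf path, keep the
# leaves whose majority class is `class_index`, and add each path node's
# importance to its feature.
oracle_category_importance <- function(tree, class_index, n_features) {
  counts <- tree$counts
  n_tot <- sum(counts[1, ])
  g_of <- function(i) {
    n <- sum(counts[i, ])
    if (n == 0) return(0)
    p <- counts[i, ] / n
    sum(p * (1 - p))
  }
  node_imp <- function(i) {
    l <- tree$nodes$left[i]; r <- tree$nodes$right[i]
    (sum(counts[i, ]) * g_of(i) - sum(counts[l, ]) * g_of(l) -
       sum(counts[r, ]) * g_of(r)) / n_tot
  }
  paths <- list()
  walk <- function(i, path) {
    if (is.na(tree$nodes$left[i])) {
      paths[[length(paths) + 1]] <<- list(leaf = i, path = path)
    } else {
      walk(tree$nodes$left[i], c(path, i))
      walk(tree$nodes$right[i], c(path, i))
    }
  }
  walk(1, integer(0))
  out <- numeric(n_features)
  for (pl in paths) {
    if (which.max(counts[pl$leaf, ]) != class_index) next
    for (i in pl$path) {
      f <- tree$nodes$feature[i]
      out[f] <- out[f] + node_imp(i)
    }
  }
  out
}

# Brute-force complete-linkage agglomeration on cosine distances: merge the
# closest pair of clusters under max-pairwise distance, recording heights.
oracle_complete_linkage_heights <- function(x) {
  d <- as.matrix(1 - (x %*% t(x)) /
                   outer(sqrt(rowSums(x^2)), sqrt(rowSums(x^2))))
  diag(d) <- 0
  clusters <- as.list(seq_len(nrow(x)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        dd <- max(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d) { best_d <- dd; best <- c(j, i) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# A hand-built depth-3 tree over 5 features and 3 classes, with counts that
# partition correctly at every split.
build_depth3_tree <- function() {
  nodes <- data.frame(
    node_id = 1:7,
    left = c(2L, 4L, 6L, NA, NA, NA, NA),
    right = c(3L, 5L, 7L, NA, NA, NA, NA),
    feature = c(2L, 4L, 2L, NA, NA, NA, NA)
  )
  counts <- rbind(
    c(40, 30, 30), # root
    c(35, 10, 5),  # node 2
    c(5, 20, 25),  # node 3
    c(30, 2, 3),   # leaf 4 -> class 1
    c(5, 8, 2),    # leaf 5 -> class 2
    c(1, 18, 4),   # leaf 6 -> class 2
    c(4, 2, 21)    # leaf 7 -> class 3
  )
  decision_tree(nodes, counts)
}

# Linearly separable synthetic feature fixture: each class has its own
# mean direction plus small isotropic noise.
make_separable_features <- function(n_per_class, n_features, n_classes = 8,
                                    margin = 6, noise = 1, seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(n_classes * n_features), n_classes)
    centers <- centers / sqrt(rowSums(centers^2)) * margin
    y <- factor(rep(paste0("c", seq_len(n_classes)), each = n_per_class))
    x <- centers[as.integer(y), ] +
      matrix(rnorm(length(y) * n_features, sd = noise), length(y))
    colnames(x) <- paste0("x", seq_len(n_features))
    list(x = x, y = y)
  })
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
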