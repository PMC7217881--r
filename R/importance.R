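#' Gini impurity of a class distribution
#'
#' `G = sum_i p_i (1 - p_i)` over class proportions; 0 for a pure node and
#' at most `1 - 1/n_c` for `n_c` balanced classes.
#'
#' @param class_proportions Nonnegative proportions summing to 1
#'   (tolerance 1e-9).
#' @return Gini impurity.
#' @export
#' @examples
#' gini_impurity(rep(1 / 8, 8)) # 0.875
gini_impurity <- function(class_proportions) {
  if (any(class_proportions < 0) ||
      abs(sum(class_proportions) - 1) > 1e-9) {
    abort("`class_proportions` must be nonnegative and sum to 1.")
  }
  sum(class_proportions * (1 - class_proportions))
}

#' Importance of one tree split
#'
#' Sample-fraction-weighted Gini reduction of a binary split:
#' `I = f_parent * G_parent - f_left * G_left - f_right * G_right`, where the
#' fractions are node sample counts over the tree's total. The weighting
#' makes `I >= 0` for every valid split (Gini is concave); the unweighted
#' difference of impurities would not be a reduction.
#'
#' @param parent_g Parent node Gini impurity.
#' @param child_g Numeric length 2: left and right child impurities.
#' @param fractions Numeric length 3: parent, left and right sample
#'   fractions; the children must partition the parent.
#' @return Node importance `I >= 0`.
#' @export
node_importance <- function(parent_g, child_g, fractions) {
  if (length(child_g) != 2 || length(fractions) != 3) {
    abort("`child_g` must have length 2 and `fractions` length 3.")
  }
  if (abs(fractions[1] - fractions[2] - fractions[3]) > 1e-9) {
    abort("Child sample fractions must sum to the parent fraction.")
  }
  if (any(fractions[2:3] > fractions[1] + 1e-12)) {
    abort("Each child fraction must not exceed the parent fraction.")
  }
  fractions[1] * parent_g - fractions[2] * child_g[1] -
    fractions[3] * child_g[2]
}

#' Explicit decision-tree representation
#'
#' A tree as a node table plus per-node class counts, the substrate for the
#' importance computations (and for building small trees by hand in tests).
#' Node 1 is the root; `left`/`right`/`feature` are `NA` for leaves.
#'
#' @param nodes Data frame with columns `node_id` (1..n), `left`, `right`,
#'   `feature` (integer feature index used at the split).
#' @param counts n_nodes x n_classes matrix of training-sample class counts
#'   per node; each internal node's counts must equal the sum of its
#'   children's.
#' @return A `decision_tree` object.
#' @export
decision_tree <- function(nodes, counts) {
  nodes <- as.data.frame(nodes)
  if (nrow(nodes) != nrow(counts)) {
    abort("`nodes` and `counts` must have one row per node.")
  }
  for (i in seq_len(nrow(nodes))) {
    if (!is.na(nodes$left[i])) {
      kid_sum <- counts[nodes$left[i], ] + counts[nodes$right[i], ]
      if (any(abs(kid_sum - counts[i, ]) > 1e-9)) {
        abort(sprintf("Children of node %d do not partition its samples.", i))
      }
    }
  }
  structure(list(nodes = nodes, counts = counts), class = "decision_tree")
}

# Per-node Gini, sample fractions and (for internal nodes) importances.
tree_node_stats <- function(tree) {
  counts <- tree$counts
  n_tot <- sum(counts[1, ])
  node_n <- rowSums(counts)
  g <- vapply(seq_len(nrow(counts)), function(i) {
    if (node_n[i] == 0) return(0)
    p <- counts[i, ] / node_n[i]
    sum(p * (1 - p))
  }, numeric(1))
  frac <- node_n / n_tot
  internal <- which(!is.na(tree$nodes$left))
  imp <- numeric(nrow(counts))
  for (i in internal) {
    l <- tree$nodes$left[i]; r <- tree$nodes$right[i]
    imp[i] <- node_importance(g[i], c(g[l], g[r]), c(frac[i], frac[l], frac[r]))
  }
  list(gini = g, fraction = frac, importance = imp, internal = internal)
}

#' Per-feature Gini importance of one tree
#'
#' Sums the sample-fraction-weighted Gini reductions of every node that
#' splits on each feature.
#'
#' @param tree A [decision_tree()].
#' @param n_features Length of the returned importance vector.
#' @return Numeric vector: summed node importance per feature (unnormalized).
#' @export
tree_feature_importance <- function(tree, n_features) {
  st <- tree_node_stats(tree)
  out <- numeric(n_features)
  for (i in st$internal) {
    f <- tree$nodes$feature[i]
    out[f] <- out[f] + st$importance[i]
  }
  out
}

# Majority training class of each leaf (ties broken toward the lowest class
# index, deterministically).
tree_leaf_classes <- function(tree) {
  leaves <- which(is.na(tree$nodes$left))
  cls <- apply(tree$counts[leaves, , drop = FALSE], 1, which.max)
  stats::setNames(cls, leaves)
}

tree_parents <- function(tree) {
  parent <- rep(NA_integer_, nrow(tree$nodes))
  for (i in which(!is.na(tree$nodes$left))) {
    parent[tree$nodes$left[i]] <- i
    parent[tree$nodes$right[i]] <- i
  }
  parent
}

#' Category-specific importance of one tree (leaf-to-root traversal)
#'
#' Every leaf whose majority training class equals `class_index` is traced
#' back to the root; each split node on the path contributes its full node
#' importance to that node's feature, once per leaf path (duplicate features
#' on one path accumulate).
#'
#' @param tree A [decision_tree()].
#' @param class_index Column index of the category in the counts matrix.
#' @param n_features Length of the returned vector.
#' @return Nonnegative per-feature importance vector for the category.
#' @export
tree_category_importance <- function(tree, class_index, n_features) {
  st <- tree_node_stats(tree)
  parent <- tree_parents(tree)
  leaf_cls <- tree_leaf_classes(tree)
  out <- numeric(n_features)
  for (leaf in as.integer(names(leaf_cls)[leaf_cls == class_index])) {
    node <- parent[leaf]
    while (!is.na(node)) {
      f <- tree$nodes$feature[node]
      out[f] <- out[f] + st$importance[node]
      node <- parent[node]
    }
  }
  out
}

# ---- extraction of decision_tree tables from a fitted ranger forest ------

# Route the in-bag training samples of tree `t` through the tree and return
# a decision_tree with in-bag class counts at every node. Requires a forest
# fitted with keep.inbag = TRUE.
ranger_tree_table <- function(fit, t, x, y) {
  ti <- ranger::treeInfo(fit, t)
  left <- ti$leftChild + 1L
  right <- ti$rightChild + 1L
  feat <- ti$splitvarID + 1L
  sv <- ti$splitval
  w <- fit$inbag.counts[[t]]
  n_nodes <- nrow(ti)
  y <- factor(y)
  node <- rep(1L, nrow(x))
  repeat {
    nt <- which(!is.na(left[node]) & w > 0)
    if (length(nt) == 0) break
    cur <- node[nt]
    go_left <- x[cbind(nt, feat[cur])] <= sv[cur]
    node[nt] <- ifelse(go_left, left[cur], right[cur])
    if (identical(node[nt], cur)) break
  }
  counts <- matrix(0, n_nodes, nlevels(y))
  at_leaf <- w > 0
  tab <- rowsum((diag(nlevels(y))[as.integer(y[at_leaf]), , drop = FALSE]) *
                  w[at_leaf], group = node[at_leaf])
  counts[as.integer(rownames(tab)), ] <- tab
  for (i in rev(seq_len(n_nodes))) {
    if (!is.na(left[i])) {
      counts[i, ] <- counts[left[i], ] + counts[right[i], ]
    }
  }
  decision_tree(
    nodes = data.frame(node_id = seq_len(n_nodes), left = left,
                       right = right, feature = feat),
    counts = counts
  )
}

new_importance_map <- function(values, scope, category = NA_character_) {
  structure(values, class = c("importance_map", "matrix"),
            scope = scope, category = category)
}

#' Importance maps of a fitted probe forest
#'
#' Extracts every tree of the forest as an explicit node table (in-bag
#' samples routed through the published split rules), then computes the
#' global Gini feature-importance map (normalized to sum 1) and the eight
#' category-specific maps via leaf-to-root traversal.
#'
#' @param fit A `ranger` classification forest fitted with
#'   `keep.inbag = TRUE` on the probe's feature matrix.
#' @param x The training feature matrix (trials x 7008).
#' @param y The training labels.
#' @param n_freq,n_bin Map dimensions (146 x 48).
#' @return List: `global` (an `importance_map` summing to 1) and `category`
#'   (named list of nonnegative `importance_map`s, one per class).
#' @export
importance_maps <- function(fit, x, y, n_freq = 146, n_bin = 48) {
  y <- factor(y)
  p <- ncol(x)
  glob <- numeric(p)
  cat_imp <- matrix(0, nlevels(y), p)
  n_splits <- 0
  for (t in seq_len(fit$num.trees)) {
    tree <- ranger_tree_table(fit, t, x, y)
    st <- tree_node_stats(tree)
    n_splits <- n_splits + length(st$internal)
    for (i in st$internal) {
      f <- tree$nodes$feature[i]
      glob[f] <- glob[f] + st$importance[i]
    }
    parent <- tree_parents(tree)
    leaf_cls <- tree_leaf_classes(tree)
    for (leaf in as.integer(names(leaf_cls))) {
      cl <- leaf_cls[[as.character(leaf)]]
      node <- parent[leaf]
      while (!is.na(node)) {
        f <- tree$nodes$feature[node]
        cat_imp[cl, f] <- cat_imp[cl, f] + st$importance[node]
        node <- parent[node]
      }
    }
  }
  if (n_splits == 0) {
    warn("Forest contains no splits; returning zero maps.")
    gm <- matrix(0, n_freq, n_bin)
  } else {
    gm <- unflatten_tf(glob / sum(glob), n_freq, n_bin)
  }
  cats <- levels(y)
  cat_maps <- lapply(seq_along(cats), function(ci) {
    if (all(cat_imp[ci, ] == 0)) {
      warn(paste0("No leaf predicts category '", cats[ci],
                  "'; zero importance map."))
    }
    new_importance_map(unflatten_tf(cat_imp[ci, ], n_freq, n_bin),
                       scope = "category", category = cats[ci])
  })
  names(cat_maps) <- cats
  list(global = new_importance_map(gm, scope = "global"),
       category = cat_maps)
}

#' @rdname importance_maps
#' @export
global_importance <- function(fit, x, y, n_freq = 146, n_bin = 48) {
  importance_maps(fit, x, y, n_freq, n_bin)$global
}

#' @rdname importance_maps
#' @param category Category label for the category-specific map.
#' @export
category_importance <- function(fit, x, y, category, n_freq = 146,
                                n_bin = 48) {
  importance_maps(fit, x, y, n_freq, n_bin)$category[[category]]
}

#' Fit the full-data forest used for importance attribution
#'
#' Predictive probes get one forest retrained on all trials (not the CV
#' splits); that forest feeds [importance_maps()].
#'
#' @param features Trials x features matrix.
#' @param labels Trial categories.
#' @param n_trees Trees (default 3000).
#' @param seed Seed.
#' @return A `ranger` forest with in-bag counts retained.
#' @export
fit_probe_forest <- function(features, labels, n_trees = 3000, seed = 1) {
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("x", seq_len(ncol(features)))
  }
  ranger::ranger(x = features, y = factor(labels), num.trees = n_trees,
                 mtry = floor(sqrt(ncol(features))), splitrule = "gini",
                 keep.inbag = TRUE, num.threads = 1, seed = seed)
}

#' Average importance maps across probes
#'
#' @param maps List of `importance_map`s of identical shape and scope.
#' @param normalize Normalize each map to sum 1 before averaging (default
#'   TRUE), so high-importance probes do not dominate the group mean.
#' @return The cell-wise mean `importance_map`.
#' @export
average_importance <- function(maps, normalize = TRUE) {
  if (length(maps) < 1) abort("Need at least one map.")
  dims <- dim(maps[[1]])
  acc <- matrix(0, dims[1], dims[2])
  for (m in maps) {
    if (!all(dim(m) == dims)) abort("Importance maps differ in shape.")
    mm <- unclass(m)
    if (normalize && sum(mm) > 0) mm <- mm / sum(mm)
    acc <- acc + mm
  }
  new_importance_map(acc / length(maps),
                     scope = attr(maps[[1]], "scope") %||% "average",
                     category = attr(maps[[1]], "category") %||% NA_character_)
}

#' Significance mask between two maps
#'
#' Fits a normal distribution to the cell-wise difference `D = A - B` and
#' masks cells where `D > mu + k*sigma` (`positive`); the symmetric lower
#' tail `D < mu - k*sigma` is reported separately (`negative`). With
#' `k = 4` on a 7008-cell map, about one false-positive cell is expected
#' under pure noise.
#'
#' @param map_a,map_b Matrices of identical shape.
#' @param k Threshold in SD units (default 4).
#' @return List: `positive`, `negative` (logical matrices), `mu`, `sigma`,
#'   `z` (the standardized difference field).
#' @export
compare_maps <- function(map_a, map_b, k = 4) {
  if (!all(dim(map_a) == dim(map_b))) abort("Maps differ in shape.")
  d <- unclass(map_a) - unclass(map_b)
  mu <- mean(d); sigma <- sd(as.vector(d))
  if (sigma == 0) {
    z <- matrix(0, nrow(d), ncol(d))
  } else {
    z <- (d - mu) / sigma
  }
  list(positive = z > k, negative = z < -k, mu = mu, sigma = sigma, z = z)
}

#' Contrast the mean importance maps of two probe groups
#'
#' Each group's mean map is z-scored against its own cell distribution;
#' cells with both z-scores `>= z_both` are "both-important", and cells
#' where the standardized difference of the group means exceeds `k` SD are
#' labeled group-dominant (dominance overlays both-importance).
#'
#' @param maps_a,maps_b Lists of `importance_map`s (e.g. monopredictive vs
#'   polypredictive probes).
#' @param z_both z threshold for within-group importance (default 2).
#' @param k SD threshold for the dominance contrast (default 4).
#' @return List: `labels` (matrix with values `"neither"`,
#'   `"both_important"`, `"a_dominant"`, `"b_dominant"`), `z_a`, `z_b`, and
#'   the underlying [compare_maps()] result.
#' @export
group_importance_contrast <- function(maps_a, maps_b, z_both = 2, k = 4) {
  if (length(maps_a) < 1 || length(maps_b) < 1) {
    abort("Both groups need at least one map.")
  }
  ma <- average_importance(maps_a)
  mb <- average_importance(maps_b)
  zs <- function(m) {
    v <- as.vector(unclass(m))
    if (sd(v) == 0) matrix(0, nrow(m), ncol(m))
    else (unclass(m) - mean(v)) / sd(v)
  }
  z_a <- zs(ma); z_b <- zs(mb)
  cmp <- compare_maps(ma, mb, k = k)
  labels <- matrix("neither", nrow(ma), ncol(ma))
  labels[z_a >= z_both & z_b >= z_both] <- "both_important"
  labels[cmp$positive] <- "a_dominant"
  labels[cmp$negative] <- "b_dominant"
  list(labels = labels, z_a = z_a, z_b = z_b, contrast = cmp)
}
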