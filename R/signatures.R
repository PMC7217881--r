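#' Mean spectrotemporal activity of one category
#'
#' Cell-wise mean of the baseline-normalized 146 x 48 maps over the trials
#' of one category.
#'
#' @param features Trials x 7008 feature matrix (flattened maps).
#' @param labels Trial categories.
#' @param category Category to average.
#' @param n_freq,n_bin Map dimensions.
#' @return 146 x 48 matrix of mean modulation ratios.
#' @export
category_mean_activity <- function(features, labels, category,
                                   n_freq = 146, n_bin = 48) {
  idx <- as.character(labels) == category
  if (!any(idx)) abort(paste0("No trials of category '", category, "'."))
  unflatten_tf(colMeans(features[idx, , drop = FALSE]), n_freq, n_bin)
}

#' Importance mask (mu + sigma rule)
#'
#' Cells retained are exactly those whose importance exceeds the map's mean
#' plus one standard deviation.
#'
#' @param importance An `importance_map` (or plain matrix).
#' @return Logical matrix of the same shape; attributes `mu`, `sigma` and
#'   `threshold` record the cut.
#' @export
importance_mask <- function(importance) {
  v <- as.vector(unclass(importance))
  mu <- mean(v); sigma <- sd(v)
  m <- unclass(importance) > mu + sigma
  attr(m, "mu") <- mu; attr(m, "sigma") <- sigma
  attr(m, "threshold") <- mu + sigma
  m
}

#' Filter activity by an importance mask
#'
#' Retained cells keep their baseline-normalized values; dropped cells are
#' excluded from the clustering vector (not zero-filled), in fixed row-major
#' (frequency-major) cell order.
#'
#' @param activity 146 x 48 activity matrix.
#' @param mask Logical matrix of the same shape.
#' @return Named numeric vector of the retained cells.
#' @export
apply_mask <- function(activity, mask) {
  if (!all(dim(activity) == dim(mask))) abort("Shapes differ.")
  v <- flatten_tf(activity)
  v[as.vector(t(mask))]
}

#' Cosine distance
#'
#' `d = 1 - u.v / (|u| |v|)`, in \[0, 2\]: 0 for identical direction, 1 for
#' orthogonal vectors, 2 for opposite patterns (e.g. a power increase vs the
#' matching decrease).
#'
#' @param u,v Nonzero numeric vectors of equal length.
#' @return The cosine distance.
#' @export
cosine_distance <- function(u, v) {
  if (length(u) != length(v)) abort("Vectors differ in length.")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("Cosine distance is undefined for a zero vector.")
  1 - sum(u * v) / (nu * nv)
}

cosine_distance_matrix <- function(x) {
  nrm <- sqrt(rowSums(x^2))
  if (any(nrm == 0)) abort("Zero vector in distance computation.")
  d <- 1 - (x %*% t(x)) / outer(nrm, nrm)
  d[d < 0] <- 0
  diag(d) <- 0
  as.dist(d)
}

#' Cluster probes by masked activity patterns
#'
#' Agglomerative complete-linkage clustering under cosine distance: the
#' distance between two clusters is the maximum pairwise cosine distance
#' between their members. Activity ratios are centered by -1 before the
#' distance (so increases are positive, decreases negative, and opposite
#' modulation patterns sit near distance 2); probes whose centered masked
#' vector is all zero are excluded and reported. The tree is cut at a
#' distance threshold and the most-populated clusters are reported first
#' (ties broken by lowest member probe id).
#'
#' @param vectors Probes x cells numeric matrix of masked activity (rows
#'   named by probe id), all rows masked by the same cell set.
#' @param h Distance threshold for the tree cut (default 0.7).
#' @param n_report Number of most-populated clusters to summarize (default 4).
#' @param center Subtract 1 from the ratio values before clustering
#'   (default TRUE).
#' @return A `probe_clustering`: list with `assignment` (tibble: probe_id,
#'   cluster), `merge_heights`, `hclust`, `excluded`, `top_clusters`.
#' @export
cluster_probes <- function(vectors, h = 0.7, n_report = 4, center = TRUE) {
  ids <- rownames(vectors) %||% paste0("probe", seq_len(nrow(vectors)))
  x <- if (center) vectors - 1 else vectors
  nz <- rowSums(x^2) > 0
  excluded <- ids[!nz]
  if (length(excluded) > 0) {
    warn(paste("Excluded all-zero masked vector(s):",
               paste(excluded, collapse = ", ")))
  }
  x <- x[nz, , drop = FALSE]; ids <- ids[nz]
  if (nrow(x) < 2) {
    assignment <- tibble::tibble(probe_id = ids, cluster = rep(1L, nrow(x)))
    out <- list(assignment = assignment, merge_heights = numeric(0),
                hclust = NULL, excluded = excluded,
                top_clusters = unique(assignment$cluster))
    class(out) <- "probe_clustering"
    return(out)
  }
  hc <- hclust(cosine_distance_matrix(x), method = "complete")
  raw <- cutree(hc, h = h)
  # deterministic cluster ids: by decreasing size, then lowest probe id
  size <- table(raw)
  first_id <- vapply(names(size), function(cl) min(ids[raw == as.integer(cl)]),
                     character(1))
  ord <- order(-as.integer(size), first_id)
  relabel <- stats::setNames(seq_along(ord), names(size)[ord])
  cluster <- unname(relabel[as.character(raw)])
  out <- list(
    assignment = tibble::tibble(probe_id = ids, cluster = as.integer(cluster)),
    merge_heights = hc$height, hclust = hc, excluded = excluded,
    top_clusters = seq_len(min(n_report, max(cluster)))
  )
  class(out) <- "probe_clustering"
  out
}

#' @export
print.probe_clustering <- function(x, ...) {
  cat("<probe_clustering> ", nrow(x$assignment), " probes, ",
      length(unique(x$assignment$cluster)), " clusters\n", sep = "")
  print(table(x$assignment$cluster))
  invisible(x)
}

#' Summarize activity-pattern clusters
#'
#' Per cluster: member count, mean per-member F1 for the clustered category,
#' fraction of polypredictive members, and the mean masked-activity pattern.
#'
#' @param clustering A `probe_clustering`.
#' @param vectors The probes x cells masked-activity matrix that was
#'   clustered (uncentered ratios; rows named by probe id).
#' @param f1 Named numeric: each member probe's F1 for the clustered
#'   category.
#' @param status Named character: each member's predictivity status.
#' @param top_only Summarize only the reported most-populated clusters.
#' @return Tibble: cluster, n, mean_f1, poly_fraction, pattern (list of mean
#'   masked vectors).
#' @export
summarize_clusters <- function(clustering, vectors, f1, status,
                               top_only = TRUE) {
  asg <- clustering$assignment
  cl_ids <- if (top_only) clustering$top_clusters else
    sort(unique(asg$cluster))
  purrr::map_dfr(cl_ids, function(cl) {
    members <- asg$probe_id[asg$cluster == cl]
    tibble::tibble(
      cluster = cl, n = length(members),
      mean_f1 = mean(f1[members]),
      poly_fraction = mean(status[members] == "polypredictive"),
      pattern = list(colMeans(vectors[members, , drop = FALSE]))
    )
  })
}
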