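#' Tidy a probe decoding result
#'
#' @param x A `probe_decoding`.
#' @param ... Unused.
#' @return Tibble: category, f1, f1_sd.
#' @export
tidy.probe_decoding <- function(x, ...) x$scores

#' @rdname tidy.probe_decoding
#' @return `glance()`: one-row tibble with max_f1, mean_f1, n_trees, folds,
#'   n_trials.
#' @export
glance.probe_decoding <- function(x, ...) {
  tibble::tibble(max_f1 = max(x$scores$f1), mean_f1 = mean(x$scores$f1),
                 n_trees = x$n_trees, folds = x$folds,
                 n_trials = length(x$truths))
}

#' Tidy a probe clustering
#'
#' @param x A `probe_clustering`.
#' @param ... Unused.
#' @return Tibble: probe_id, cluster.
#' @export
tidy.probe_clustering <- function(x, ...) x$assignment

#' @rdname tidy.probe_clustering
#' @export
glance.probe_clustering <- function(x, ...) {
  tibble::tibble(n_probes = nrow(x$assignment),
                 n_clusters = length(unique(x$assignment$cluster)),
                 n_excluded = length(x$excluded),
                 max_merge_height = if (length(x$merge_heights)) {
                   max(x$merge_heights)
                 } else NA_real_)
}

#' Tidy a pipeline result
#'
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @return Long tibble: probe_id, category, f1, f1_sd, status.
#' @export
tidy.pipeline_result <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x$decoding)), function(i) {
    sc <- x$decoding$decoding[[i]]$scores
    tibble::tibble(probe_id = x$decoding$probe_id[i],
                   category = sc$category, f1 = sc$f1, f1_sd = sc$f1_sd,
                   status = x$decoding$status[i])
  })
}

#' @rdname tidy.pipeline_result
#' @export
glance.pipeline_result <- function(x, ...) x$counts
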