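map_to_df <- function(map, freqs = NULL) {
  freqs <- freqs %||% (seq_len(nrow(map)) + 3)
  bins <- seq_len(ncol(map))
  tibble::tibble(
    frequency = rep(freqs, times = ncol(map)),
    time_ms = rep(-500 + (bins - 0.5) * 31.25, each = nrow(map)),
    value = as.vector(unclass(map))
  )
}

#' Plot a spectrotemporal map
#'
#' Raster of a 146 x 48 activity or importance map on the frequency x time
#' axes (bin centers; onset at 0 ms).
#'
#' @param map Matrix (activity ratio or importance).
#' @param freqs Row center frequencies (default 4..149 Hz).
#' @param title Optional title.
#' @return A ggplot object.
#' @export
plot_tf_map <- function(map, freqs = NULL, title = NULL) {
  df <- map_to_df(map, freqs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_ms, y = .data$frequency,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(name = NULL) +
    ggplot2::labs(x = "Time (ms)", y = "Frequency (Hz)", title = title) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.importance_map <- function(object, ...) {
  plot_tf_map(object, title = paste0(
    "Importance (", attr(object, "scope"),
    if (!is.na(attr(object, "category"))) {
      paste0(": ", attr(object, "category"))
    } else "", ")"))
}

#' Plot per-class decoding scores
#'
#' @param decoding A `probe_decoding`.
#' @param threshold Predictivity threshold drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_decoding <- function(decoding, threshold = 0.390278) {
  df <- decoding$scores
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$f1)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$f1 - .data$f1_sd,
                                        ymax = .data$f1 + .data$f1_sd),
                           width = 0.3) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = NULL, y = "Cross-validated F1") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.probe_decoding <- function(object, ...) plot_decoding(object, ...)

#' Plot mean masked-activity patterns of the reported clusters
#'
#' Cells outside the importance mask are blank; values are centered
#' modulation ratios (increase > 0, suppression < 0).
#'
#' @param result A `pipeline_result`.
#' @param category Clustered category to show.
#' @return A ggplot object.
#' @export
plot_cluster_patterns <- function(result, category) {
  cl <- result$clustering[[category]]
  if (is.null(cl)) abort(paste0("No clustering for category '", category, "'."))
  mask_cells <- as.vector(t(cl$mask))
  dfs <- purrr::map_dfr(seq_len(nrow(cl$summary)), function(i) {
    full <- rep(NA_real_, length(mask_cells))
    full[mask_cells] <- cl$summary$pattern[[i]] - 1
    df <- map_to_df(unflatten_tf(full, nrow(cl$mask), ncol(cl$mask)))
    df$cluster <- sprintf("cluster %d (n=%d)", cl$summary$cluster[i],
                          cl$summary$n[i])
    df
  })
  ggplot2::ggplot(dfs, ggplot2::aes(x = .data$time_ms, y = .data$frequency,
                                    fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::scale_fill_gradient2(name = "ratio - 1", na.value = "grey95") +
    ggplot2::labs(x = "Time (ms)", y = "Frequency (Hz)",
                  title = paste("Masked activity patterns:", category)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
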