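#' Printed functional-area bounding boxes
#'
#' MNI bounding boxes of the Fusiform Face Area (both hemispheres), Visual
#' Word Form Area (left) and Parahippocampal Place Area (both hemispheres).
#'
#' @return Tibble: name, hemisphere, x_lo, x_hi, y_lo, y_hi, z_lo, z_hi (mm).
#' @export
#' @examples
#' functional_area_boxes()
functional_area_boxes <- function() {
  tibble::tribble(
    ~name,  ~hemisphere, ~x_lo, ~x_hi, ~y_lo, ~y_hi, ~z_lo, ~z_hi,
    "FFA",  "left",        -44,   -38,   -61,   -50,   -24,   -15,
    "FFA",  "right",        36,    43,   -55,   -49,   -25,   -13,
    "VWFA", "left",        -50,   -38,   -61,   -50,   -30,   -16,
    "PPA",  "left",        -31,   -22,   -55,   -49,   -12,    -6,
    "PPA",  "right",        24,    32,   -54,   -45,   -12,    -6
  )
}

#' Functional-area membership of an MNI coordinate
#'
#' Box membership uses closed intervals (boundary points are inside).
#'
#' @param mni Numeric length 3 (x, y, z in mm).
#' @param boxes Area table, default [functional_area_boxes()].
#' @return Character vector of `"name (hemisphere)"` labels of the boxes
#'   containing the point (empty if none).
#' @export
#' @examples
#' in_functional_area(c(-40, -55, -20))
in_functional_area <- function(mni, boxes = functional_area_boxes()) {
  hit <- mni[1] >= boxes$x_lo & mni[1] <= boxes$x_hi &
    mni[2] >= boxes$y_lo & mni[2] <= boxes$y_hi &
    mni[3] >= boxes$z_lo & mni[3] <= boxes$z_hi
  if (!any(hit)) return(character(0))
  paste0(boxes$name[hit], " (", boxes$hemisphere[hit], ")")
}

#' Null Brodmann-area lookup
#'
#' Placeholder for the pluggable anatomical-atlas interface: any
#' single-argument function mapping MNI coordinates to an area label can be
#' supplied to [run_pipeline()] via the config; the default maps everything
#' to `"unmapped"` (no atlas is bundled).
#'
#' @param mni Numeric length 3.
#' @return `"unmapped"`.
#' @export
brodmann_null <- function(mni) "unmapped"

#' Per-category predictive-probe counts inside a functional area
#'
#' @param predictivity Tibble with columns `probe_id`, `mni_x`, `mni_y`,
#'   `mni_z` and a `predictive_categories` list-column.
#' @param area Area name (e.g. `"FFA"`).
#' @param boxes Area table.
#' @return Tibble: category, n_predictive (all 8 categories, zeros kept).
#' @export
area_predictivity_profile <- function(predictivity, area,
                                      boxes = functional_area_boxes()) {
  boxes <- boxes[boxes$name == area, , drop = FALSE]
  counts <- stats::setNames(integer(length(sf_categories())), sf_categories())
  for (i in seq_len(nrow(predictivity))) {
    mni <- c(predictivity$mni_x[i], predictivity$mni_y[i],
             predictivity$mni_z[i])
    if (length(in_functional_area(mni, boxes)) > 0) {
      for (cat in predictivity$predictive_categories[[i]]) {
        counts[cat] <- counts[cat] + 1L
      }
    }
  }
  tibble::tibble(category = names(counts), n_predictive = unname(counts))
}

#' Pipeline configuration
#'
#' All stage parameters in one serializable object. Defaults follow the
#' reference protocol: 10-sigma artifact rejection, bipolar re-referencing,
#' responsiveness alpha 0.005 with BH-FDR, 3000-tree forests under 5-fold
#' stratified CV, predictivity threshold 0.390278, category-scope importance
#' masks, complete-linkage cosine clustering cut at 0.7 with the 4 largest
#' clusters reported.
#'
#' @param artifact_k Artifact-rejection multiplier.
#' @param rereference Apply bipolar re-referencing.
#' @param alpha Responsiveness significance level (adjusted p).
#' @param n_trees Trees per forest.
#' @param folds CV folds.
#' @param threshold Predictivity F1 threshold.
#' @param mask_scope `"category"` (mask from the category's group-average
#'   importance) or `"probe"` (per-probe masks).
#' @param cluster_h Tree-cut distance threshold.
#' @param n_report Most-populated clusters to report.
#' @param seed Master seed (per-probe seeds are derived from it).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(artifact_k = 10, rereference = TRUE,
                            alpha = 0.005, n_trees = 3000, folds = 5,
                            threshold = 0.390278, mask_scope = "category",
                            cluster_h = 0.7, n_report = 4, seed = 1) {
  if (!mask_scope %in% c("category", "probe")) {
    abort("`mask_scope` must be \"category\" or \"probe\".")
  }
  cfg <- list(artifact_k = artifact_k, rereference = rereference,
              alpha = alpha, fdr = "BH", n_trees = n_trees, folds = folds,
              threshold = threshold, mask_scope = mask_scope,
              linkage = "complete", cluster_h = cluster_h,
              n_report = n_report, seed = seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Save / load a pipeline configuration
#'
#' JSON round trip is lossless: `read_config(write_config(cfg, path))`
#' equals `cfg`.
#'
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `write_config()` the path invisibly; `read_config()` the config.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Stable hash of a configuration
#'
#' Every output file of [run_pipeline()] embeds this hash and the master
#' seed, so artifacts can be matched to the configuration that produced
#' them.
#'
#' @param config A `pipeline_config`.
#' @return Character hash.
#' @export
config_hash <- function(config) {
  cfg <- unclass(config)[order(names(unclass(config)))]
  # canonicalize storage modes so a JSON round trip hashes identically
  cfg <- lapply(cfg, function(x) if (is.numeric(x)) as.numeric(x) else x)
  rlang::hash(cfg)
}

#' Run the full decoding pipeline on a cohort
#'
#' Executes preprocessing (detrend, artifact rejection, bipolar
#' re-referencing), spectral decomposition and responsiveness screening,
#' per-probe cross-validated forest decoding with predictivity
#' classification, importance attribution on full-data forests for the
#' predictive probes, and importance-masked complete-linkage clustering per
#' category.
#'
#' @param cohort An `lfp_cohort`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory for the CSV/JSON artifacts (see
#'   [write_results()]).
#' @param verbose Print stage progress.
#' @return A `pipeline_result` list: `config`, `hash`, `manifest`,
#'   `exclusions`, `responsiveness`, `decoding`, `importance`, `clustering`,
#'   `counts`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL,
                         verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- Sys.time()
  pre <- preprocess_cohort(cohort, k = config$artifact_k,
                           rereference = config$rereference)
  exclusions <- attr(pre, "exclusions") %||% tibble::tibble()
  pre <- pre[pre$usable, ]
  say("preprocess: %d usable probes", nrow(pre))
  if (nrow(pre) == 0) abort("Pipeline stage 'preprocess': no usable probes.")

  bank <- wavelet_bank()
  feats <- vector("list", nrow(pre)); names(feats) <- pre$probe_id
  resp <- vector("list", nrow(pre))
  for (p in seq_len(nrow(pre))) {
    tp <- tf_probe(pre$epochs[[p]], bank)
    feats[[p]] <- tp$features
    r <- responsiveness_test(tp$post, tp$base, alpha = config$alpha,
                             bank = bank)
    resp[[p]] <- tibble::tibble(probe_id = pre$probe_id[p],
                                n_significant_frequencies = r$n_significant,
                                responsive = r$responsive)
  }
  responsiveness <- dplyr::bind_rows(resp)
  keep <- responsiveness$responsive
  say("spectral: %d/%d responsive", sum(keep), nrow(pre))

  dec <- decode_cohort(feats[keep], pre$labels[keep],
                       n_trees = config$n_trees, folds = config$folds,
                       threshold = config$threshold, seed = config$seed)
  decoding <- dplyr::left_join(
    dec,
    cohort_manifest(pre)[, c("probe_id", "mni_x", "mni_y", "mni_z",
                             "truth_class")],
    by = "probe_id")
  say("decoding: %d predictive", sum(decoding$status != "none"))

  pred_idx <- which(decoding$status != "none")
  imp <- purrr::map(pred_idx, function(i) {
    pid <- decoding$probe_id[i]
    fit <- fit_probe_forest(feats[[pid]], pre$labels[[match(pid, pre$probe_id)]],
                            n_trees = config$n_trees,
                            seed = derive_seed(config$seed, paste0("imp/", pid)))
    importance_maps(fit, feats[[pid]],
                    pre$labels[[match(pid, pre$probe_id)]])
  })
  importance <- tibble::tibble(probe_id = decoding$probe_id[pred_idx],
                               maps = imp)
  say("importance: %d probes attributed", nrow(importance))

  clustering <- list()
  for (cat in sf_categories()) {
    pids <- decoding$probe_id[
      purrr::map_lgl(decoding$predictive_categories,
                     function(x) cat %in% x)]
    pids <- intersect(pids, importance$probe_id)
    if (length(pids) < 2) next
    cat_maps <- purrr::map(pids, function(pid) {
      importance$maps[[match(pid, importance$probe_id)]]$category[[cat]]
    })
    if (config$mask_scope == "category") {
      mask <- importance_mask(average_importance(cat_maps))
      masks <- rep(list(mask), length(pids))
    } else {
      masks <- purrr::map(cat_maps, importance_mask)
      mask <- importance_mask(average_importance(cat_maps))
      masks <- rep(list(mask), length(pids)) # common cell set for clustering
    }
    if (!any(mask)) next
    vectors <- t(vapply(seq_along(pids), function(j) {
      pid <- pids[j]
      act <- category_mean_activity(
        feats[[pid]], pre$labels[[match(pid, pre$probe_id)]], cat)
      apply_mask(act, masks[[j]])
    }, numeric(sum(mask))))
    rownames(vectors) <- pids
    cl <- cluster_probes(vectors, h = config$cluster_h,
                         n_report = config$n_report)
    f1 <- vapply(pids, function(pid) {
      sc <- decoding$decoding[[match(pid, decoding$probe_id)]]$scores
      sc$f1[sc$category == cat]
    }, numeric(1))
    status <- stats::setNames(
      decoding$status[match(pids, decoding$probe_id)], pids)
    clustering[[cat]] <- list(
      clustering = cl, vectors = vectors, mask = mask,
      summary = summarize_clusters(cl, vectors, f1, status))
  }
  say("signatures: %d categories clustered", length(clustering))

  counts <- tibble::tibble(
    n_probes = nrow(pre),
    n_responsive = sum(keep),
    responsive_fraction = mean(keep),
    n_predictive = sum(decoding$status != "none"),
    n_monopredictive = sum(decoding$status == "monopredictive"),
    n_polypredictive = sum(decoding$status == "polypredictive"),
    runtime_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  out <- list(config = config, hash = config_hash(config),
              manifest = cohort_manifest(pre),
              exclusions = exclusions,
              responsiveness = responsiveness, decoding = decoding,
              importance = importance, clustering = clustering,
              counts = counts)
  class(out) <- "pipeline_result"
  if (!is.null(out_dir)) write_results(out, out_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$counts)
  invisible(x)
}
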