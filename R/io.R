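# Plain-text persistence: every artifact is CSV or JSON so runs are
# portable and diffable. Result CSVs open with a comment line embedding the
# config hash and master seed.

stamped_csv <- function(df, path, hash, seed) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s seed=%d", hash, seed), con)
  writeLines(readr::format_csv(df), con, sep = "")
  invisible(path)
}

read_stamped_csv <- function(path) {
  readr::read_csv(path, comment = "#", show_col_types = FALSE)
}

#' Write pipeline artifacts
#'
#' Emits, under `dir`: `config.json`, `manifest.csv`, `exclusions.csv`,
#' `responsiveness.csv`, `decoding.csv` (per-probe F1 and fold SD per
#' category, status, predictive categories), and `clusters.csv`. All CSVs
#' carry the config hash and master seed in a leading comment line.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  write_config(cfg, file.path(dir, "config.json"))
  h <- result$hash; s <- cfg$seed
  stamped_csv(result$manifest, file.path(dir, "manifest.csv"), h, s)
  stamped_csv(result$exclusions, file.path(dir, "exclusions.csv"), h, s)
  stamped_csv(result$responsiveness, file.path(dir, "responsiveness.csv"),
              h, s)
  stamped_csv(tidy_decoding_table(result$decoding),
              file.path(dir, "decoding.csv"), h, s)
  stamped_csv(cluster_report(result), file.path(dir, "clusters.csv"), h, s)
  invisible(dir)
}

# Wide per-probe decoding table: f1_<cat>, sd_<cat>, status, categories.
tidy_decoding_table <- function(decoding) {
  purrr::map_dfr(seq_len(nrow(decoding)), function(i) {
    sc <- decoding$decoding[[i]]$scores
    row <- tibble::tibble(probe_id = decoding$probe_id[i])
    for (j in seq_len(nrow(sc))) {
      row[[paste0("f1_", sc$category[j])]] <- sc$f1[j]
      row[[paste0("sd_", sc$category[j])]] <- sc$f1_sd[j]
    }
    row$status <- decoding$status[i]
    row$predictive_categories <-
      paste(decoding$predictive_categories[[i]], collapse = ";")
    row
  })
}

cluster_report <- function(result) {
  if (length(result$clustering) == 0) {
    return(tibble::tibble(category = character(0), probe_id = character(0),
                          cluster = integer(0)))
  }
  purrr::map_dfr(names(result$clustering), function(cat) {
    asg <- result$clustering[[cat]]$clustering$assignment
    tibble::tibble(category = cat, probe_id = asg$probe_id,
                   cluster = asg$cluster)
  })
}

#' Write / read a synthetic cohort as plain text
#'
#' The cohort container is a directory: `manifest.csv`, `config.json` (the
#' generation snapshot), and one `epochs_<probe>.csv` per probe (columns:
#' trial, label, s1..s768).
#'
#' @param cohort An `lfp_cohort`.
#' @param dir Directory path.
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` an
#'   `lfp_cohort` (probe metadata, labels and epochs; implanted-signature
#'   specs are not round-tripped).
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort_manifest(cohort), file.path(dir, "manifest.csv"))
  jsonlite::write_json(attr(cohort, "cohort_config"),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  for (p in seq_len(nrow(cohort))) {
    em <- cohort$epochs[[p]]
    df <- as.data.frame(em)
    names(df) <- paste0("s", seq_len(ncol(em)))
    df <- cbind(trial = cohort$trials[[p]],
                label = as.character(cohort$labels[[p]]), df)
    readr::write_csv(df, file.path(dir, paste0("epochs_",
                                               cohort$probe_id[p], ".csv")))
  }
  invisible(dir)
}

#' @rdname write_cohort
#' @param dir Directory written by `write_cohort()`.
#' @export
read_cohort <- function(dir) {
  man <- readr::read_csv(file.path(dir, "manifest.csv"),
                         show_col_types = FALSE)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  cats <- cfg$categories
  rows <- purrr::map_dfr(seq_len(nrow(man)), function(p) {
    df <- readr::read_csv(
      file.path(dir, paste0("epochs_", man$probe_id[p], ".csv")),
      show_col_types = FALSE)
    em <- as.matrix(df[, -(1:2)])
    dimnames(em) <- NULL
    tibble::tibble(
      probe_id = man$probe_id[p], subject_id = man$subject_id[p],
      shaft_id = man$shaft_id[p], contact_index = man$contact_index[p],
      mni_x = man$mni_x[p], mni_y = man$mni_y[p], mni_z = man$mni_z[p],
      noise_exponent = NA_real_, trial_noise_sd = NA_real_,
      signatures = list(NULL), truth_class = man$truth_class[p],
      epochs = list(em), labels = list(factor(df$label, levels = cats)),
      trials = list(df$trial)
    )
  })
  attr(rows, "cohort_config") <- cfg
  class(rows) <- c("lfp_cohort", class(tibble::tibble()))
  rows
}
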