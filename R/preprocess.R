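#' Remove a least-squares linear trend from a trace
#'
#' @param x Numeric vector (>= 2 samples).
#' @return Detrended vector: the fitted line (intercept + slope) is removed,
#'   so the output has zero mean and zero residual slope. A constant input
#'   returns zeros.
#' @export
detrend_linear <- function(x) {
  n <- length(x)
  if (n < 2) abort("`detrend_linear()` needs at least 2 samples.")
  k <- seq_len(n) - (n + 1) / 2           # centered time index
  slope <- sum(k * x) / sum(k * k)
  x - mean(x) - slope * k
}

#' Linearly detrend every epoch of a cohort
#'
#' @param cohort An `lfp_cohort`.
#' @return The cohort with each epoch detrended.
#' @export
detrend_epochs <- function(cohort) {
  cohort$epochs <- lapply(cohort$epochs, function(em) {
    t(apply(em, 1, detrend_linear))
  })
  cohort
}

#' Exclude epochs containing extreme voltage values
#'
#' For each probe, `sigma_images` is the standard deviation of voltage over
#' *all* of that probe's epochs (-500..1000 ms), computed in a single pass;
#' any epoch containing a value with `|v| >= k * sigma_images` is excluded.
#' Probes with no retained epochs are flagged unusable and skipped by
#' downstream stages.
#'
#' @param cohort An `lfp_cohort`.
#' @param k Rejection multiplier (default 10).
#' @return The cohort with excluded epochs dropped, a logical `usable`
#'   column, and an `exclusions` attribute (tibble: probe_id, trial_index,
#'   reason) listing the dropped epochs.
#' @export
reject_artifacts <- function(cohort, k = 10) {
  reports <- vector("list", nrow(cohort))
  for (p in seq_len(nrow(cohort))) {
    em <- cohort$epochs[[p]]
    sigma <- sd(as.vector(em))
    bad <- apply(abs(em), 1, max) >= k * sigma
    if (any(bad)) {
      reports[[p]] <- tibble::tibble(
        probe_id = cohort$probe_id[p],
        trial_index = cohort$trials[[p]][bad],
        sigma_images = sigma,
        reason = sprintf("max |v| >= %g * sigma_images", k)
      )
      cohort$epochs[[p]] <- em[!bad, , drop = FALSE]
      cohort$labels[[p]] <- cohort$labels[[p]][!bad]
      cohort$trials[[p]] <- cohort$trials[[p]][!bad]
    }
  }
  cohort$usable <- vapply(cohort$epochs, nrow, integer(1)) > 0
  if (any(!cohort$usable)) {
    warn(paste("All epochs excluded for probe(s):",
               paste(cohort$probe_id[!cohort$usable], collapse = ", ")))
  }
  attr(cohort, "exclusions") <-
    dplyr::bind_rows(reports[!vapply(reports, is.null, logical(1))])
  cohort
}

#' Bipolar re-referencing of shaft contacts
#'
#' Within each (subject, shaft), contacts are ordered by `contact_index` and
#' each adjacent pair produces one derivation: `contact i - contact i+1`
#' (anode = lower index). A shaft with n contacts yields n-1 derived probes;
#' single-contact shafts yield none (with a warning). Derived probes inherit
#' the arithmetic MNI midpoint of their contact pair, the union of the
#' parents' implanted signatures (for ground-truth bookkeeping), and only
#' the trials retained on *both* contacts.
#'
#' @param cohort An `lfp_cohort` (monopolar contacts).
#' @return An `lfp_cohort` of derived probes.
#' @export
bipolar_rereference <- function(cohort) {
  key <- paste(cohort$subject_id, cohort$shaft_id, sep = "/")
  rows <- list()
  for (sk in unique(key)) {
    idx <- which(key == sk)
    idx <- idx[order(cohort$contact_index[idx])]
    if (length(idx) < 2) {
      warn(paste0("Shaft ", sk, " has a single contact; no derivation."))
      next
    }
    for (j in seq_len(length(idx) - 1)) {
      a <- idx[j]; b <- idx[j + 1]
      common <- intersect(cohort$trials[[a]], cohort$trials[[b]])
      ia <- match(common, cohort$trials[[a]])
      ib <- match(common, cohort$trials[[b]])
      sigs <- dplyr::bind_rows(cohort$signatures[[a]], cohort$signatures[[b]])
      row <- tibble::tibble(
        probe_id = paste0(cohort$probe_id[a], "-", cohort$probe_id[b]),
        subject_id = cohort$subject_id[a], shaft_id = cohort$shaft_id[a],
        contact_index = cohort$contact_index[a],
        mni_x = (cohort$mni_x[a] + cohort$mni_x[b]) / 2,
        mni_y = (cohort$mni_y[a] + cohort$mni_y[b]) / 2,
        mni_z = (cohort$mni_z[a] + cohort$mni_z[b]) / 2,
        noise_exponent = cohort$noise_exponent[a],
        trial_noise_sd = cohort$trial_noise_sd[a],
        rhythms = list(dplyr::bind_rows(cohort$rhythms[[a]],
                                        cohort$rhythms[[b]])),
        signatures = list(sigs),
        truth_class = truth_class(sigs),
        epochs = list(cohort$epochs[[a]][ia, , drop = FALSE] -
                        cohort$epochs[[b]][ib, , drop = FALSE]),
        labels = list(cohort$labels[[a]][ia]),
        trials = list(common)
      )
      rows[[length(rows) + 1]] <- row
    }
  }
  if (length(rows) == 0) {
    out <- cohort[0, ]
    out$usable <- logical(0)
    attr(out, "cohort_config") <- attr(cohort, "cohort_config")
    class(out) <- c("lfp_cohort", class(tibble::tibble()))
    return(out)
  }
  out <- dplyr::bind_rows(rows)
  out$usable <- vapply(out$epochs, nrow, integer(1)) > 0
  attr(out, "cohort_config") <- attr(cohort, "cohort_config")
  class(out) <- c("lfp_cohort", class(tibble::tibble()))
  out
}

#' Full preprocessing pass
#'
#' Fixed order: linear detrend (per epoch), 10-sigma artifact rejection on
#' the monopolar contacts (sigma_images is defined per recorded probe), then
#' bipolar derivation.
#'
#' @param cohort An `lfp_cohort`.
#' @param k Artifact-rejection multiplier.
#' @param rereference Derive bipolar probes (default TRUE).
#' @return Preprocessed cohort; the `exclusions` attribute carries the
#'   artifact report.
#' @export
preprocess_cohort <- function(cohort, k = 10, rereference = TRUE) {
  cfg <- attr(cohort, "cohort_config")
  out <- reject_artifacts(detrend_epochs(cohort), k = k)
  excl <- attr(out, "exclusions")
  if (rereference) {
    keep <- out[out$usable, ]
    attr(keep, "cohort_config") <- cfg
    out <- bipolar_rereference(keep)
  }
  attr(out, "cohort_config") <- cfg
  attr(out, "exclusions") <- excl
  out
}
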