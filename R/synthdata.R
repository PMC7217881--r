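#' Synthetic 1/f background trace
#'
#' Generates a zero-mean voltage trace whose expected power spectral density
#' falls off as `1/f^alpha`, by spectrally shaping white Gaussian noise in the
#' Fourier domain. `alpha = 0` gives white noise; `alpha = 1` the pink
#' (1/f) background typical of field-potential recordings.
#'
#' @param n_samples Number of samples (>= 2).
#' @param noise_exponent Spectral slope `alpha` (>= 0).
#' @param seed Optional integer seed; the same seed gives an identical trace.
#' @param fs Sampling rate in Hz (default 512).
#' @return Numeric vector of length `n_samples`, zero mean, unit SD.
#' @export
#' @examples
#' x <- make_background(768, noise_exponent = 1, seed = 1)
make_background <- function(n_samples, noise_exponent = 1, seed = NULL,
                            fs = SF_FS) {
  if (!is.numeric(n_samples) || length(n_samples) != 1 || n_samples < 2) {
    abort("`n_samples` must be a single integer >= 2.")
  }
  if (noise_exponent < 0) abort("`noise_exponent` must be >= 0.")
  n <- as.integer(n_samples)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  w <- rnorm(n)
  if (noise_exponent > 0) {
    # shape |X(f)| by f^(-alpha/2); filter is real and symmetric in the
    # frequency index, so the inverse transform of a real input stays real
    k <- seq_len(n) - 1
    f <- pmin(k, n - k) * fs / n
    h <- c(0, f[-1]^(-noise_exponent / 2))
    w <- Re(fft(fft(w) * h, inverse = TRUE)) / n
  }
  w <- w - mean(w)
  s <- sd(w)
  if (s > 0) w <- w / s
  w
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Band-pass filter a trace (FFT, raised-cosine band edges)
#'
#' Zero-phase frequency-domain filter retaining `[freq_lo, freq_hi]` Hz with
#' 1-Hz raised-cosine transitions, used both by the signature implanter and
#' in tests as an analysis primitive.
#'
#' @param trace Numeric vector.
#' @param freq_lo,freq_hi Pass-band edges in Hz.
#' @param fs Sampling rate in Hz.
#' @return Filtered trace, same length.
#' @export
band_pass <- function(trace, freq_lo, freq_hi, fs = SF_FS) {
  n <- length(trace)
  k <- seq_len(n) - 1
  f <- pmin(k, n - k) * fs / n
  taper <- 1 # Hz transition half-width
  h <- rep(0, n)
  h[f >= freq_lo & f <= freq_hi] <- 1
  lo_ramp <- f > freq_lo - taper & f < freq_lo
  h[lo_ramp] <- 0.5 * (1 + cos(pi * (freq_lo - f[lo_ramp]) / taper))
  hi_ramp <- f > freq_hi & f < freq_hi + taper
  h[hi_ramp] <- 0.5 * (1 + cos(pi * (f[hi_ramp] - freq_hi) / taper))
  Re(fft(fft(trace) * h, inverse = TRUE)) / n
}

# Expected fraction of an implanted component's power that the binned
# Morlet maps recover inside the implanted rectangle: band-edge rows only
# partially capture the band (spectral Gaussian of SD sigma_f/sqrt(2)) and
# window-edge samples lose power to temporal smearing (SD sigma_t/sqrt(2)).
# The implant calibration divides by this so the measured region ratio
# approaches the requested gain.
region_dilution <- function(freq_lo, freq_hi, t_on, t_off,
                            spectral = TRUE) {
  bank <- wavelet_bank()
  rows <- bank[bank$f0 >= freq_lo & bank$f0 <= freq_hi, ]
  if (nrow(rows) == 0) return(1)
  d_f <- if (spectral) {
    # only additive components are spectrally diluted; a suppression of the
    # trace's own band component normalizes against the same rows' baseline,
    # so the spectral capture factor cancels in the ratio
    mean(stats::pnorm((freq_hi - rows$f0) / (rows$sigma_f / sqrt(2))) -
           stats::pnorm((freq_lo - rows$f0) / (rows$sigma_f / sqrt(2))))
  } else 1
  s_t <- mean(rows$sigma_t) * 1000 / sqrt(2) # ms
  tt <- seq(t_on, t_off, length.out = 64)
  d_t <- mean(stats::pnorm((t_off - tt) / s_t) - stats::pnorm((t_on - tt) / s_t))
  max(d_f * d_t, 0.05)
}

# Raised-cosine on/off envelope over [t_on, t_off] ms with `ramp` ms ramps.
signature_envelope <- function(times, t_on, t_off, ramp = 25) {
  env <- numeric(length(times))
  inside <- times >= t_on & times <= t_off
  env[inside] <- 1
  on_ramp <- inside & times < t_on + ramp
  env[on_ramp] <- 0.5 * (1 - cos(pi * (times[on_ramp] - t_on) / ramp))
  off_ramp <- inside & times > t_off - ramp
  env[off_ramp] <- 0.5 * (1 - cos(pi * (t_off - times[off_ramp]) / ramp))
  env
}

#' Implant a band-limited power modulation into a trace
#'
#' Adds (gain > 1) or suppresses (gain < 1) band-limited power inside a
#' time window so that the post/baseline binned power ratio in that
#' time-frequency region approaches `gain` in expectation. Increases are
#' additive: band-limited Gaussian noise, enveloped with 25-ms raised-cosine
#' ramps, scaled against the trace's own baseline band power. Suppressions
#' are multiplicative: the trace's own band-passed component is attenuated
#' by `sqrt(gain)` inside the window, emulating desynchronization of
#' pre-existing rhythms.
#'
#' @param trace Voltage trace covering -500..1000 ms at 512 Hz.
#' @param freq_lo,freq_hi Band edges in Hz (4-150, `freq_lo < freq_hi`).
#' @param t_on,t_off Window in ms after stimulus onset (0 <= t_on < t_off <= 1000).
#' @param gain Target power ratio (> 0); `gain = 1` returns the trace unchanged.
#' @param seed Optional seed for the additive component.
#' @param fs Sampling rate in Hz.
#' @return Modified trace, same length.
#' @export
implant_signature <- function(trace, freq_lo, freq_hi, t_on, t_off, gain,
                              seed = NULL, fs = SF_FS) {
  if (freq_lo >= freq_hi) abort("`freq_lo` must be < `freq_hi`.")
  if (t_on < 0 || t_off > 1000 || t_on >= t_off) {
    abort("Signature window must satisfy 0 <= t_on < t_off <= 1000 ms.")
  }
  if (gain <= 0) abort("`gain` must be > 0.")
  if (gain == 1) return(trace)
  times <- epoch_times(length(trace))
  env <- signature_envelope(times, t_on, t_off)
  win <- env > 0
  base <- times >= -500 & times <= -100
  bp <- band_pass(trace, freq_lo, freq_hi, fs = fs)
  p_base <- mean(bp[base]^2)
  dil <- region_dilution(freq_lo, freq_hi, t_on, t_off, spectral = gain > 1)
  if (gain > 1) {
    if (!is.null(seed)) {
      old <- .Random.seed_save()
      on.exit(.Random.seed_restore(old), add = TRUE)
      set.seed(seed)
    }
    comp <- band_pass(rnorm(length(trace)), freq_lo, freq_hi, fs = fs) * env
    p_comp <- mean(comp[win]^2)
    if (p_comp <= 0) return(trace)
    trace + comp * sqrt((gain - 1) / dil * p_base / p_comp)
  } else {
    # fraction of the band rows' power the suppression can touch: measured
    # on this trace's baseline as (band-passed row power)/(full row power);
    # out-of-band leakage into the rows bounds the achievable decrease
    bank <- wavelet_bank()
    rows <- bank[bank$f0 >= freq_lo & bank$f0 <= freq_hi, ]
    c_f <- 1
    if (nrow(rows) > 0) {
      wfm <- wavelet_fft_matrix(rows, length(trace), fs)
      b_idx <- times >= -500 & times <= -100
      p_full <- rowMeans(tf_power_padded(trace, wfm)[, b_idx, drop = FALSE])
      p_band <- rowMeans(tf_power_padded(bp, wfm)[, b_idx, drop = FALSE])
      if (all(p_full > 0)) c_f <- mean(pmin(p_band / p_full, 1))
    }
    depth <- min((1 - gain) / (dil * c_f), 1 - 1e-3)
    trace - (1 - sqrt(1 - depth)) * env * bp
  }
}

#' Describe one implanted spectrotemporal signature
#'
#' @param category Category label the signature is tied to, or `NA` for a
#'   category-independent response (the probe becomes responsive but carries
#'   no category information).
#' @param freq_lo,freq_hi Band edges in Hz (integers in 4-150).
#' @param t_on,t_off Window in ms (0-1000).
#' @param gain Power ratio (> 1 increase, < 1 suppression).
#' @return One-row tibble.
#' @export
#' @examples
#' signature_spec("face", 61, 90, 100, 300, gain = 3)
signature_spec <- function(category, freq_lo, freq_hi, t_on, t_off, gain) {
  if (freq_lo < 4 || freq_hi > 150 || freq_lo >= freq_hi) {
    abort("Signature band must satisfy 4 <= freq_lo < freq_hi <= 150 Hz.")
  }
  if (t_on < 0 || t_off > 1000 || t_on >= t_off) {
    abort("Signature window must satisfy 0 <= t_on < t_off <= 1000 ms.")
  }
  if (gain <= 0) abort("`gain` must be > 0.")
  if (!is.na(category) && !category %in% sf_categories()) {
    abort(paste0("Unknown category '", category, "'."))
  }
  tibble::tibble(category = as.character(category),
                 freq_lo = freq_lo, freq_hi = freq_hi,
                 t_on = t_on, t_off = t_off, gain = gain)
}

#' Describe one synthetic recording probe
#'
#' @param probe_id Unique probe identifier.
#' @param subject_id,shaft_id Subject and electrode-shaft labels; contacts on
#'   the same (subject, shaft) share a common noise component and are paired
#'   by [bipolar_rereference()].
#' @param contact_index Ordinal position along the shaft (>= 0).
#' @param mni MNI coordinates, numeric length 3 (mm).
#' @param signatures Tibble of [signature_spec()] rows, or `NULL` for a
#'   pure-noise probe.
#' @param noise_exponent Spectral slope of the 1/f^alpha background (>= 0).
#' @param trial_noise_sd SD of the lognormal per-trial jitter applied to the
#'   signature effect (see the package vignette for the calibration).
#' @param rhythms Optional tibble (`freq_lo`, `freq_hi`, `amplitude`) of
#'   standing band-limited rhythms present on every trial across the whole
#'   epoch (baseline included), e.g. an alpha rhythm that a suppression
#'   signature can desynchronize. Amplitude is relative to the unit-SD
#'   background.
#' @return One-row tibble (bind rows of these to build a cohort spec).
#' @export
#' @examples
#' probe_spec("p1", signatures = signature_spec("face", 61, 90, 100, 300, 3))
probe_spec <- function(probe_id, subject_id = "S01", shaft_id = "A",
                       contact_index = 0, mni = c(0, 0, 0),
                       signatures = NULL, noise_exponent = 1,
                       trial_noise_sd = 0.4, rhythms = NULL) {
  if (contact_index < 0) abort("`contact_index` must be >= 0.")
  if (noise_exponent < 0) abort("`noise_exponent` must be >= 0.")
  if (length(mni) != 3) abort("`mni` must have length 3.")
  if (is.null(signatures)) {
    signatures <- signature_spec("face", 4, 5, 0, 1, 1)[0, ]
  }
  tibble::tibble(
    probe_id = as.character(probe_id), subject_id = subject_id,
    shaft_id = shaft_id, contact_index = as.integer(contact_index),
    mni_x = mni[1], mni_y = mni[2], mni_z = mni[3],
    noise_exponent = noise_exponent, trial_noise_sd = trial_noise_sd,
    signatures = list(signatures),
    rhythms = list(rhythms %||% tibble::tibble(freq_lo = numeric(0),
                                               freq_hi = numeric(0),
                                               amplitude = numeric(0)))
  )
}

# Ground-truth class from a probe's signature list.
truth_class <- function(signatures) {
  if (nrow(signatures) == 0) return("non_responsive")
  cats <- unique(signatures$category[!is.na(signatures$category)])
  if (length(cats) == 0) "responsive_only"
  else if (length(cats) == 1) "monopredictive"
  else "polypredictive"
}

#' Generate a synthetic cohort with known ground truth
#'
#' Simulates, for every probe, `trials_per_category` epochs of each of the 8
#' categories: a private 1/f^alpha background per contact, a shared
#' shaft-level noise component (amplitude 0.5 relative to the private
#' background, so bipolar re-referencing has a measurable effect), and the
#' probe's implanted signatures on trials of the matching category (or all
#' trials for category-free signatures). The per-trial signature effect is
#' jittered lognormally (`trial_noise_sd`) so decoding is nontrivial.
#'
#' @param probe_specs Tibble of [probe_spec()] rows.
#' @param trials_per_category Trials per category (>= 2; default 50, i.e. 400
#'   epochs per probe).
#' @param seed Master seed; regeneration under the same seed is bit-identical.
#' @return An `lfp_cohort`: a tibble with one row per probe carrying the
#'   probe metadata, the ground-truth class, and list-columns `epochs`
#'   (trials x 768 matrix) and `labels` (factor). Attributes record the
#'   generation configuration.
#' @export
#' @examples
#' specs <- dplyr::bind_rows(probe_spec("n1"), probe_spec("n2", shaft_id = "B"))
#' coh <- generate_cohort(specs, trials_per_category = 2, seed = 1)
generate_cohort <- function(probe_specs, trials_per_category = 50, seed = 1) {
  if (anyDuplicated(probe_specs$probe_id)) {
    abort("Duplicate `probe_id` in `probe_specs`.")
  }
  if (trials_per_category < 2) abort("`trials_per_category` must be >= 2.")
  cats <- sf_categories()
  n_trials <- trials_per_category * length(cats)
  labels <- factor(rep(cats, each = trials_per_category), levels = cats)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(seed, "cohort"))

  # shared shaft-level noise, one trace per (subject, shaft, trial)
  shaft_key <- paste(probe_specs$subject_id, probe_specs$shaft_id, sep = "/")
  shaft_noise <- list()
  for (sk in unique(shaft_key)) {
    shaft_noise[[sk]] <- t(vapply(seq_len(n_trials), function(i) {
      make_background(SF_N_SAMPLES, noise_exponent = 1)
    }, numeric(SF_N_SAMPLES)))
  }

  epochs <- vector("list", nrow(probe_specs))
  for (p in seq_len(nrow(probe_specs))) {
    sigs <- probe_specs$signatures[[p]]
    sdn <- probe_specs$trial_noise_sd[p]
    shared <- shaft_noise[[shaft_key[p]]]
    em <- matrix(0, n_trials, SF_N_SAMPLES)
    for (i in seq_len(n_trials)) {
      tr <- make_background(SF_N_SAMPLES,
                            noise_exponent = probe_specs$noise_exponent[p]) +
        0.5 * shared[i, ]
      rhy <- probe_specs$rhythms[[p]]
      if (!is.null(rhy) && nrow(rhy) > 0) {
        # standing rhythm: per-trial carrier frequency drifts inside the
        # band, phase is random, amplitude (SD) is stable, so a suppression
        # signature sees a well-defined baseline band power on every trial
        for (s in seq_len(nrow(rhy))) {
          fc <- runif(1, rhy$freq_lo[s], rhy$freq_hi[s])
          ph <- runif(1, 0, 2 * pi)
          tt <- epoch_times(SF_N_SAMPLES) / 1000
          tr <- tr + rhy$amplitude[s] * sqrt(2) * sin(2 * pi * fc * tt + ph)
        }
      }
      if (nrow(sigs) > 0) {
        for (s in seq_len(nrow(sigs))) {
          if (is.na(sigs$category[s]) ||
              sigs$category[s] == as.character(labels[i])) {
            g <- jitter_gain(sigs$gain[s], sdn)
            tr <- implant_signature(tr, sigs$freq_lo[s], sigs$freq_hi[s],
                                    sigs$t_on[s], sigs$t_off[s], g)
          }
        }
      }
      em[i, ] <- tr
    }
    epochs[[p]] <- em
  }

  out <- probe_specs
  out$truth_class <- vapply(probe_specs$signatures, truth_class, character(1))
  out$epochs <- epochs
  out$labels <- rep(list(labels), nrow(probe_specs))
  out$trials <- rep(list(seq_len(n_trials)), nrow(probe_specs))
  attr(out, "cohort_config") <- list(
    trials_per_category = trials_per_category, seed = seed,
    categories = cats, fs = SF_FS, n_samples = SF_N_SAMPLES
  )
  class(out) <- c("lfp_cohort", class(tibble::tibble()))
  out
}

# Lognormal jitter of the signature effect size, mean-preserving on the
# effect (gain - 1 for increases, suppression depth for decreases).
jitter_gain <- function(gain, sd) {
  if (sd <= 0 || gain == 1) return(gain)
  j <- exp(rnorm(1, -sd^2 / 2, sd))
  if (gain > 1) 1 + (gain - 1) * j
  else max(1 - min((1 - gain) * j, 0.999), 1e-3)
}

#' Ground-truth manifest of a cohort
#'
#' @param cohort An `lfp_cohort`.
#' @return Tibble with probe metadata, ground-truth class and trial count
#'   (no waveform data).
#' @export
cohort_manifest <- function(cohort) {
  tibble::tibble(
    probe_id = cohort$probe_id, subject_id = cohort$subject_id,
    shaft_id = cohort$shaft_id, contact_index = cohort$contact_index,
    mni_x = cohort$mni_x, mni_y = cohort$mni_y, mni_z = cohort$mni_z,
    truth_class = cohort$truth_class,
    n_trials = vapply(cohort$epochs, nrow, integer(1))
  )
}
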