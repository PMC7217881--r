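#' Morlet wavelet bank
#'
#' One wavelet per integer center frequency from 4 to 149 Hz (146 rows; the
#' half-open reading of "4 to 150 Hz" consistent with the 146-row map).
#' Cycle counts step with the canonical bands: theta 4-8 Hz -> 3 cycles,
#' alpha 9-14 -> 4, beta 15-30 -> 5, low gamma 31-60 -> 6, high gamma
#' 61-150 -> 6. The Gaussian widths satisfy `sigma_f = 1/(2*pi*sigma_t)` and
#' `f0/sigma_f = n_cycles`.
#'
#' @param freqs Integer center frequencies (default `4:149`).
#' @return Tibble with columns `f0`, `n_cycles`, `sigma_f`, `sigma_t`.
#' @export
#' @examples
#' wavelet_bank()
wavelet_bank <- function(freqs = 4:149) {
  n_cycles <- ifelse(freqs <= 8, 3,
               ifelse(freqs <= 14, 4,
                ifelse(freqs <= 30, 5, 6)))
  sigma_f <- freqs / n_cycles
  tibble::tibble(f0 = as.numeric(freqs), n_cycles = n_cycles,
                 sigma_f = sigma_f, sigma_t = 1 / (2 * pi * sigma_f))
}

# Discrete complex Morlet kernel at f0, truncated at +/- 4 sigma_t and
# L2-normalized (only power ratios matter downstream, so the normalization
# choice cancels in baseline normalization).
morlet_kernel <- function(f0, n_cycles, fs = SF_FS) {
  sigma_t <- n_cycles / (2 * pi * f0)
  h <- ceiling(4 * sigma_t * fs)
  t <- (-h:h) / fs
  # zero-mean the discrete wavelet so a DC offset draws no power
  # (the correction only matters at low cycle counts)
  g <- exp(-t^2 / (2 * sigma_t^2))
  w <- g * exp(2i * pi * f0 * t)
  w <- w - g * (sum(w) / sum(g))
  w / sqrt(sum(Mod(w)^2))
}

# FFT matrix of all bank kernels, positioned for circular convolution on a
# padded trace of length L. Returns list(W = L x nrow(bank) complex matrix,
# pad = padding used).
wavelet_fft_matrix <- function(bank, n, fs = SF_FS) {
  pad <- max(ceiling(4 * bank$sigma_t * fs)) + 1
  L <- n + 2 * pad
  W <- matrix(0i, L, nrow(bank))
  for (j in seq_len(nrow(bank))) {
    k <- morlet_kernel(bank$f0[j], bank$n_cycles[j], fs)
    h <- (length(k) - 1) / 2
    pos <- ((-h:h) %% L) + 1
    col <- numeric(L) + 0i
    col[pos] <- k
    W[, j] <- fft(col)
  }
  list(W = W, pad = pad, L = L)
}

reflect_pad <- function(x, pad) {
  n <- length(x)
  c(x[pmin(pad + 1 - seq_len(pad), n)], x, x[n - seq_len(pad) + 1])
}

tf_power_padded <- function(trace, wfm) {
  s <- fft(reflect_pad(trace, wfm$pad))
  conv <- mvfft(wfm$W * s, inverse = TRUE) / wfm$L
  t(Mod(conv[wfm$pad + seq_along(trace), , drop = FALSE])^2)
}

#' Morlet power time series at one frequency
#'
#' Squared magnitude of the convolution of `trace` with a complex Morlet
#' wavelet of center frequency `f0` and `n_cycles` cycles
#' (`P(t, f0) = |w(t, f0) * s(t)|^2`). Edges are handled by reflection
#' padding over the wavelet support.
#'
#' @param trace Voltage trace sampled at `fs`.
#' @param f0 Center frequency in Hz (below Nyquist).
#' @param n_cycles Number of wavelet cycles (>= 1).
#' @param fs Sampling rate in Hz.
#' @return Nonnegative power series, same length as `trace`.
#' @export
morlet_power <- function(trace, f0, n_cycles, fs = SF_FS) {
  if (n_cycles < 1) abort("`n_cycles` must be >= 1.")
  if (f0 >= fs / 2) abort("`f0` must be below the Nyquist frequency.")
  bank <- tibble::tibble(f0 = f0, n_cycles = n_cycles,
                         sigma_t = n_cycles / (2 * pi * f0))
  wfm <- wavelet_fft_matrix(bank, length(trace), fs)
  drop(tf_power_padded(trace, wfm))
}

#' Full-rate time-frequency power of one epoch
#'
#' @param trace Voltage trace (one epoch, 768 samples at 512 Hz).
#' @param bank Wavelet bank from [wavelet_bank()].
#' @param fs Sampling rate in Hz.
#' @return 146 x 768 nonnegative power matrix (rows follow `bank$f0`).
#' @export
tf_transform <- function(trace, bank = wavelet_bank(), fs = SF_FS) {
  wfm <- wavelet_fft_matrix(bank, length(trace), fs)
  tf_power_padded(trace, wfm)
}

#' Baseline-normalize a power matrix
#'
#' Divides each frequency row by that row's mean power in the baseline
#' window (-500 to -100 ms), yielding dimensionless modulation ratios.
#'
#' @param power Frequency x time power matrix at full sampling rate.
#' @param fs Sampling rate in Hz.
#' @param baseline Baseline window in ms, default `c(-500, -100)`.
#' @return Matrix of the same shape; stationary input gives values near 1.
#' @export
baseline_normalize <- function(power, fs = SF_FS, baseline = c(-500, -100)) {
  times <- epoch_times(ncol(power))
  idx <- times >= baseline[1] & times <= baseline[2]
  base <- rowMeans(power[, idx, drop = FALSE])
  if (any(base <= 0)) {
    abort(paste("Zero baseline power in frequency row(s):",
                paste(which(base <= 0), collapse = ", ")))
  }
  power / base
}

#' Bin a full-rate matrix into 31.25-ms time bins
#'
#' Averages contiguous non-overlapping blocks of 16 samples (768 columns ->
#' 48 bins of 31.25 ms).
#'
#' @param mat Frequency x time matrix whose column count is divisible by
#'   `n_bins`.
#' @param n_bins Number of time bins (default 48).
#' @return Frequency x `n_bins` matrix of bin means.
#' @export
bin_time <- function(mat, n_bins = 48) {
  n <- ncol(mat)
  if (n %% n_bins != 0) {
    abort(sprintf("Column count %d is not divisible by %d bins.", n, n_bins))
  }
  spb <- n / n_bins
  out <- matrix(0, nrow(mat), n_bins)
  for (j in seq_len(n_bins)) {
    out[, j] <- rowMeans(mat[, ((j - 1) * spb + 1):(j * spb), drop = FALSE])
  }
  out
}

#' Spectrotemporal feature map of one epoch
#'
#' The full per-epoch pipeline: Morlet transform, baseline normalization,
#' 31.25-ms binning; yields the 146 x 48 feature map.
#'
#' @inheritParams tf_transform
#' @return 146 x 48 matrix of baseline-normalized power ratios.
#' @export
tf_map <- function(trace, bank = wavelet_bank(), fs = SF_FS) {
  bin_time(baseline_normalize(tf_transform(trace, bank, fs), fs))
}

#' Flatten / restore a 146 x 48 map
#'
#' Flattening is row-major (frequency-major): all 48 time bins of the first
#' frequency row, then the next row, giving 7008 features in a fixed,
#' invertible order.
#'
#' @param map 146 x 48 matrix.
#' @return `flatten_tf()`: named numeric vector of length 7008;
#'   `unflatten_tf()`: the matrix back.
#' @export
flatten_tf <- function(map) {
  v <- as.vector(t(map))
  names(v) <- paste0("f", rep(seq_len(nrow(map)), each = ncol(map)) + 3,
                     "_b", rep(seq_len(ncol(map)), nrow(map)))
  v
}

#' @rdname flatten_tf
#' @param v Numeric vector of length `n_freq * n_bin`.
#' @param n_freq,n_bin Map dimensions.
#' @export
unflatten_tf <- function(v, n_freq = 146, n_bin = 48) {
  matrix(v, n_freq, n_bin, byrow = TRUE)
}

# Per-probe spectral summaries in one pass over epochs: the flattened
# feature matrix plus per-trial mean post-stimulus and baseline power per
# frequency (inputs to the responsiveness test).
tf_probe <- function(epochs, bank = wavelet_bank(), fs = SF_FS) {
  n <- nrow(epochs)
  wfm <- wavelet_fft_matrix(bank, ncol(epochs), fs)
  times <- epoch_times(ncol(epochs))
  b_idx <- times >= -500 & times <= -100
  p_idx <- times >= 0
  feats <- matrix(0, n, nrow(bank) * 48)
  post <- matrix(0, n, nrow(bank))
  base <- matrix(0, n, nrow(bank))
  for (i in seq_len(n)) {
    P <- tf_power_padded(epochs[i, ], wfm)
    base[i, ] <- rowMeans(P[, b_idx, drop = FALSE])
    post[i, ] <- rowMeans(P[, p_idx, drop = FALSE])
    feats[i, ] <- as.vector(t(bin_time(P / base[i, ])))
  }
  colnames(feats) <- names(flatten_tf(matrix(0, nrow(bank), 48)))
  list(features = feats, post = post, base = base)
}

#' Feature matrix of a probe's epochs
#'
#' @param epochs Trials x 768 matrix of voltage traces.
#' @param bank Wavelet bank.
#' @param fs Sampling rate in Hz.
#' @return Trials x 7008 matrix of flattened baseline-normalized TF maps.
#' @export
probe_features <- function(epochs, bank = wavelet_bank(), fs = SF_FS) {
  tf_probe(epochs, bank, fs)$features
}

#' Wilcoxon responsiveness test of one probe
#'
#' Per 1-Hz frequency row, the matched pairs are each trial's mean
#' post-stimulus power (0-1000 ms) and mean baseline power (-500..-100 ms);
#' p-values from the Wilcoxon signed-rank test are Benjamini-Hochberg
#' adjusted across the 146 frequencies, and the probe is responsive when at
#' least two adjusted p-values are `<= alpha`.
#'
#' @param post,base Trials x frequencies matrices of per-trial mean powers
#'   (see [probe_band_power()]), or pass `epochs` to compute them.
#' @param epochs Optional trials x 768 voltage matrix; used when `post` and
#'   `base` are not supplied.
#' @param alpha Significance level on adjusted p-values (default 0.005).
#' @param bank Wavelet bank (when computing from `epochs`).
#' @return List with `table` (tibble: f0, p, p_adj, significant),
#'   `n_significant`, and `responsive`.
#' @export
responsiveness_test <- function(post = NULL, base = NULL, epochs = NULL,
                                alpha = 0.005, bank = wavelet_bank()) {
  if (is.null(post) || is.null(base)) {
    if (is.null(epochs)) abort("Supply `post`/`base` or `epochs`.")
    tp <- tf_probe(epochs, bank)
    post <- tp$post; base <- tp$base
  }
  if (nrow(post) < 6) {
    abort("Responsiveness test needs at least 6 trials (matched pairs).")
  }
  p <- vapply(seq_len(ncol(post)), function(f) {
    d <- post[, f] - base[, f]
    if (all(d == 0)) return(1)
    suppressWarnings(
      wilcox.test(post[, f], base[, f], paired = TRUE, exact = FALSE)$p.value
    )
  }, numeric(1))
  p_adj <- p.adjust(p, method = "BH")
  tab <- tibble::tibble(f0 = bank$f0[seq_len(ncol(post))], p = p,
                        p_adj = p_adj, significant = p_adj <= alpha)
  list(table = tab, n_significant = sum(tab$significant),
       responsive = sum(tab$significant) >= 2)
}

#' Per-trial mean band power of a probe
#'
#' @param epochs Trials x 768 voltage matrix.
#' @param bank Wavelet bank.
#' @param fs Sampling rate.
#' @return List of trials x frequencies matrices `post` (0-1000 ms mean
#'   power) and `base` (baseline mean power).
#' @export
probe_band_power <- function(epochs, bank = wavelet_bank(), fs = SF_FS) {
  tp <- tf_probe(epochs, bank, fs)
  list(post = tp$post, base = tp$base)
}

#' Responsiveness screening of a cohort
#'
#' @param cohort A preprocessed `lfp_cohort`.
#' @param alpha Significance level (default 0.005).
#' @param bank Wavelet bank.
#' @return Tibble: probe_id, n_significant_frequencies, responsive.
#' @export
screen_responsive <- function(cohort, alpha = 0.005, bank = wavelet_bank()) {
  purrr::map_dfr(seq_len(nrow(cohort)), function(p) {
    r <- responsiveness_test(epochs = cohort$epochs[[p]], alpha = alpha,
                             bank = bank)
    tibble::tibble(probe_id = cohort$probe_id[p],
                   n_significant_frequencies = r$n_significant,
                   responsive = r$responsive)
  })
}
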