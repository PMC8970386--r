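# Spectral covariance features: per-segment DFT coefficients at half-Hz
# resolution, all-pairs cross-channel covariances, and robust aggregation
# over segments into the flat base-feature vector.

#' Enumerate channel pairs
#'
#' Deterministic ordering of the `n + n(n-1)/2` unordered channel pairs:
#' all auto pairs (c, c) in canonical channel order first, then cross
#' pairs lexicographic by (c, k), c < k.  For the 19-channel montage this
#' gives 190 pairs (19 auto + 171 cross).
#'
#' @param n_channels number of channels.
#' @return Data frame with columns `c`, `k` (1-based channel indices),
#'   `label`, and `auto`.
#' @export
enumerate_pairs <- function(n_channels = 19) {
  stopifnot(n_channels >= 1)
  auto <- cbind(seq_len(n_channels), seq_len(n_channels))
  cross <- if (n_channels > 1) t(utils::combn(n_channels, 2)) else
    matrix(integer(), 0, 2)
  m <- rbind(auto, cross)
  labs <- if (n_channels == 19) canonical_channels() else
    paste0("ch", seq_len(n_channels))
  data.frame(c = m[, 1], k = m[, 2],
             label = paste0(labs[m[, 1]], "-", labs[m[, 2]]),
             auto = m[, 1] == m[, 2])
}

#' Frequency grid of the spectral features
#' @return The 90 analysis frequencies 0.5, 1.0, ..., 45.0 Hz.
#' @export
spectral_freqs <- function() seq(0.5, 45, by = 0.5)

#' Per-segment Fourier spectra at half-Hz resolution
#'
#' Computes the DFT of every 2-s segment and channel and retains the
#' coefficients at 0.5-45 Hz (bins 1-90 of the 2-s window; DC
#' discarded).  Coefficients are scaled by 1/n_samples so magnitudes are
#' invariant to the sampling rate.  No taper is applied: for a 2-s
#' rectangular window the native bin spacing is exactly 0.5 Hz.
#'
#' @param segs an `eeg_segments` object with 2-s windows.
#' @return An object of class `eeg_spectra`: complex array `sigma` of
#'   dimension 90 x n_channels x n_segments, plus `freqs`.
#' @export
compute_segment_spectra <- function(segs) {
  stopifnot(inherits(segs, "eeg_segments"))
  win <- dim(segs$segments)[1]
  fs <- segs$sampling_rate
  if (abs(segs$segment_length - 2) > 1e-9 || win != round(2 * fs))
    dlb_stop("dlb_resolution_error",
             "half-Hz spectral resolution requires exact 2-s segments")
  if (win / 2 < 91)
    dlb_stop("dlb_resolution_error",
             "sampling rate too low to reach the 45 Hz band edge")
  nc <- dim(segs$segments)[2]
  ns <- dim(segs$segments)[3]
  flat <- matrix(segs$segments, nrow = win)     # win x (nc*ns)
  spec <- stats::mvfft(flat)[2:91, , drop = FALSE] / win
  sigma <- array(spec, dim = c(90, nc, ns))
  structure(list(sigma = sigma, freqs = spectral_freqs(),
                 channel_labels = segs$channel_labels, n_segments = ns),
            class = "eeg_spectra")
}

#' Full-spectral-resolution covariance tensor
#'
#' `chi[j, p, i] = sigma[j, c, i] * Conj(sigma[j, k, i])` for every channel
#' pair p = (c, k).  Auto pairs (c = k) are the per-channel power spectra
#' (real, non-negative); cross pairs carry the complex cross-spectrum.
#'
#' @param spectra an `eeg_spectra` object.
#' @return An object of class `eeg_covariance`: complex array `chi` of
#'   dimension 90 x n_pairs x n_segments plus the `pairs` table.
#' @export
compute_covariances <- function(spectra) {
  stopifnot(inherits(spectra, "eeg_spectra"))
  pairs <- enumerate_pairs(dim(spectra$sigma)[2])
  chi <- cpp_chi_tensor(spectra$sigma,
                        cbind(pairs$c - 1L, pairs$k - 1L))
  structure(list(chi = chi, pairs = pairs, freqs = spectra$freqs,
                 n_segments = dim(chi)[3]),
            class = "eeg_covariance")
}

.estimator_code <- function(estimator) {
  switch(estimator, median = 0L, trimmed_mean = 1L, mean = 2L,
         dlb_stop("dlb_value_error",
                  paste0("unknown robust estimator: ", estimator)))
}

#' Robustly aggregate the covariance tensor over segments
#'
#' Collapses the per-segment covariances into one feature vector per
#' recording by a robust location estimate (default: marginal median of
#' the real and imaginary parts separately).  Segments contaminated by
#' blink, muscle or ECG artefacts are outliers in the per-segment
#' distribution, so the median acts as automatic artefact removal.
#' Imaginary slots of auto pairs are structural zeros, kept so the
#' 190 x 90 x 2 = 34,200 feature layout is uniform across pairs.
#'
#' @param cov an `eeg_covariance` object with at least 3 segments.
#' @param estimator `"median"` (default), `"trimmed_mean"` (20% per
#'   tail), or `"mean"` (non-robust, for comparison).
#' @param subject_id,age,gender subject metadata carried along.
#' @return Object of class `base_features` with `values` (numeric,
#'   length n_pairs x 90 x 2; 34,200 for the full montage).
#' @export
robust_aggregate <- function(cov, estimator = "median",
                             subject_id = "anon", age = NA_real_,
                             gender = NA_character_) {
  stopifnot(inherits(cov, "eeg_covariance"))
  if (cov$n_segments < 3)
    dlb_stop("dlb_aggregation_error",
             "robust aggregation requires at least 3 segments")
  v <- cpp_aggregate_chi(cov$chi, as.integer(cov$pairs$auto),
                         .estimator_code(estimator), .dlb_trim_default)
  structure(list(values = as.numeric(v), subject_id = subject_id,
                 age = age, gender = gender, estimator = estimator,
                 pairs = cov$pairs),
            class = "base_features")
}

#' Names of the flat base-feature vector
#'
#' Ordering is (pair, frequency, {re, im}): feature
#' `(p-1)*180 + (j-1)*2 + 1` is the real part of pair p at frequency j.
#'
#' @param pairs a pair table from [enumerate_pairs()].
#' @return Character vector of feature names like `"Fp1-Fp2_f10_re"`.
#' @export
base_feature_names <- function(pairs = enumerate_pairs()) {
  f <- spectral_freqs()
  unlist(lapply(pairs$label, function(lb)
    as.vector(rbind(paste0(lb, "_f", f, "_re"), paste0(lb, "_f", f, "_im")))))
}

#' Base-feature extraction for one recording
#'
#' Convenience chain: average reference (if needed), band-pass filter,
#' 150-s epoch, 2-s/1-s segmentation, spectra, covariances, robust
#' aggregation.  Returns the intermediate spectra as well, so core
#' features can later be projected per segment without re-reading the
#' signal.
#'
#' @param rec a validated `eeg_record`.
#' @param config configuration list, see [default_config()].
#' @param with_base compute the 34,200 base features (default).  Set to
#'   `FALSE` when the features are only needed for classification with an
#'   already-fitted basis, which projects directly from the per-segment
#'   spectra; `base` is then `NULL`.
#' @return Object of class `subject_features`: `base` (a
#'   `base_features`), `spectra` (an `eeg_spectra`), `subject_id`, `age`,
#'   `gender`.
#' @export
extract_features <- function(rec, config = default_config(),
                             with_base = TRUE) {
  if (!identical(rec$reference, "average"))
    rec <- apply_average_reference(rec)
  rec <- bandpass_filter(rec, low = config$filter$low_hz,
                         high = config$filter$high_hz,
                         order = config$filter$order,
                         zero_phase = config$filter$zero_phase)
  ep <- extract_epoch(rec, duration = config$epoch$duration_s,
                      start = config$epoch$start_s)
  segs <- segment_epoch(ep, length = config$segment$length_s,
                        step = config$segment$step_s)
  spectra <- compute_segment_spectra(segs)
  base <- NULL
  if (with_base) {
    # same computation as compute_covariances() + robust_aggregate() but
    # without materializing the full covariance tensor
    pairs <- enumerate_pairs(dim(spectra$sigma)[2])
    v <- cpp_aggregate_sigma(spectra$sigma, cbind(pairs$c - 1L, pairs$k - 1L),
                             .estimator_code(config$spectral$estimator),
                             .dlb_trim_default)
    base <- structure(list(values = as.numeric(v),
                           subject_id = rec$subject_id,
                           age = rec$age, gender = rec$gender,
                           estimator = config$spectral$estimator,
                           pairs = pairs),
                      class = "base_features")
  }
  structure(list(base = base, spectra = spectra,
                 subject_id = rec$subject_id, age = rec$age,
                 gender = rec$gender),
            class = "subject_features")
}
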