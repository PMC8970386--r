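#' Band-pass filter an EEG record
#'
#' Applies a Butterworth band-pass (default 0.1-70 Hz, order 8) to every
#' channel.  The default application is zero-phase (forward-backward),
#' which doubles the effective magnitude order and, crucially, preserves
#' the cross-channel phase relations on which the spectral covariance
#' features depend; set `zero_phase = FALSE` for a single causal pass.
#'
#' @param rec a validated `eeg_record`.
#' @param low,high band edges in Hz.
#' @param order band-pass filter order (even; the underlying low/high
#'   prototype has order `order/2`).
#' @param zero_phase forward-backward application.
#' @return The filtered record.
#' @export
bandpass_filter <- function(rec, low = 0.1, high = 70, order = 8,
                            zero_phase = TRUE) {
  stopifnot(inherits(rec, "eeg_record"), low > 0, high > low)
  if (order %% 2 != 0) dlb_stop("dlb_value_error", "filter order must be even")
  fs <- rec$sampling_rate
  if (fs <= 2 * high)
    dlb_stop("dlb_nyquist_error",
             sprintf("sampling rate %g Hz cannot represent the %g Hz band edge",
                     fs, high))
  bf <- signal::butter(order / 2, c(low, high) / (fs / 2), type = "pass")
  if (zero_phase) {
    rec$data <- cpp_filtfilt(bf$b, bf$a, rec$data)
  } else {
    rec$data <- apply(rec$data, 2, function(x) signal::filter(bf, x))
  }
  colnames(rec$data) <- canonical_channels()
  attr(rec, "filtered") <- TRUE
  rec
}

#' Designed magnitude response of the band-pass filter
#'
#' Evaluates |H(f)| of the filter that [bandpass_filter()] designs, at
#' the given frequencies; with `zero_phase = TRUE` the squared magnitude
#' of the single-pass design is returned.  Used to verify pass/stop-band
#' attenuation independent of any test signal.
#'
#' @param freqs frequencies in Hz.
#' @inheritParams bandpass_filter
#' @param fs sampling rate in Hz.
#' @return Numeric vector of gains.
#' @export
bandpass_response <- function(freqs, low = 0.1, high = 70, order = 8,
                              fs = 200, zero_phase = TRUE) {
  bf <- signal::butter(order / 2, c(low, high) / (fs / 2), type = "pass")
  z <- exp(-1i * 2 * pi * freqs / fs)
  H <- vapply(z, function(zz) {
    num <- sum(bf$b * zz^(seq_along(bf$b) - 1))
    den <- sum(bf$a * zz^(seq_along(bf$a) - 1))
    Mod(num / den)
  }, 0)
  if (zero_phase) H^2 else H
}

#' Extract the analysis epoch
#'
#' Selects a contiguous slice of the record.  The classification method
#' is undefined for epochs shorter than 150 s, so the default duration is
#' enforced as a minimum upstream of feature extraction.
#'
#' @param rec a validated `eeg_record`.
#' @param duration epoch length in seconds (default 150).
#' @param start epoch start in seconds from the beginning of the record.
#' @return An object of class `eeg_epoch` (fields `record`, `start_time`,
#'   `duration`).
#' @export
extract_epoch <- function(rec, duration = 150, start = 0) {
  stopifnot(inherits(rec, "eeg_record"), duration > 0, start >= 0)
  fs <- rec$sampling_rate
  if (rec$duration < start + duration)
    dlb_stop("dlb_epoch_length_error",
             sprintf("record is %.1f s; need %.1f s from t=%.1f s",
                     rec$duration, duration, start))
  i0 <- round(start * fs)
  n <- round(duration * fs)
  sl <- rec
  sl$data <- rec$data[(i0 + 1):(i0 + n), , drop = FALSE]
  sl$duration <- n / fs
  structure(list(record = sl, start_time = start, duration = sl$duration),
            class = "eeg_epoch")
}

#' Cut an epoch into overlapping analysis segments
#'
#' Windows of `length` seconds starting every `step` seconds; a 150-s
#' epoch with 2-s windows stepped by 1 s yields 149 segments.
#'
#' @param epoch an `eeg_epoch`.
#' @param length window length in seconds (default 2).
#' @param step window step in seconds (default 1).
#' @return An object of class `eeg_segments`: 3-d array `segments`
#'   (sample x channel x segment) plus `segment_length`, `step`, `count`,
#'   `sampling_rate`.
#' @export
segment_epoch <- function(epoch, length = 2, step = 1) {
  stopifnot(inherits(epoch, "eeg_epoch"))
  if (step <= 0) dlb_stop("dlb_value_error", "step must be positive")
  if (epoch$duration < length)
    dlb_stop("dlb_value_error", "epoch shorter than one segment")
  fs <- epoch$record$sampling_rate
  win <- round(length * fs)
  hop <- round(step * fs)
  n <- nrow(epoch$record$data)
  starts <- seq(0, n - win, by = hop)
  segs <- vapply(starts, function(s)
    epoch$record$data[(s + 1):(s + win), , drop = FALSE],
    matrix(0, win, ncol(epoch$record$data)))
  structure(list(segments = segs, segment_length = length, step = step,
                 count = base::length(starts), sampling_rate = fs,
                 channel_labels = colnames(epoch$record$data)),
            class = "eeg_segments")
}
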