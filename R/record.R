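#' Canonical 19-channel 10-20 montage
#'
#' The fixed channel set and ordering used throughout the package.  All
#' channel indices `c` in downstream features refer to this order.  The
#' older temporal names (T3/T4/T5/T6) are canonical; modern equivalents
#' (T7/T8/P7/P8) are mapped on input.
#'
#' @return Character vector of 19 channel names.
#' @export
canonical_channels <- function() {
  c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz", "T3", "T4", "T5", "T6",
    "C3", "C4", "Cz", "P3", "P4", "Pz", "O1", "O2")
}

# old-name synonyms emitted by modern amplifiers (matched case-insensitively)
.channel_synonyms <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")

#' Map a raw channel label to its canonical 10-20 name
#'
#' Strips common prefixes/suffixes (`"EEG "`, reference suffixes such as
#' `"-REF"` or `"-AVG"`), matches case-insensitively, and translates the
#' modern temporal names to the canonical older ones.  Returns `NA` for
#' labels that are not scalp EEG channels of the montage.
#'
#' @param labels character vector of raw labels.
#' @return Character vector of canonical names, `NA` where unmapped.
#' @export
canonical_label <- function(labels) {
  x <- trimws(labels)
  x <- sub("^EEG[ _]*", "", x, ignore.case = TRUE)
  x <- sub("[-_ ](REF|AVG|LE|A1|A2)$", "", x, ignore.case = TRUE)
  lut <- c(canonical_channels(), names(.channel_synonyms))
  idx <- match(toupper(x), toupper(lut))
  out <- lut[idx]
  syn <- !is.na(out) & out %in% names(.channel_synonyms)
  out[syn] <- .channel_synonyms[out[syn]]
  out
}

#' Construct a multichannel EEG record
#'
#' @param data numeric matrix, samples in rows, channels in columns;
#'   column names must map onto the canonical 19-channel montage.
#' @param sampling_rate sampling frequency in Hz.
#' @param reference `"as-recorded"` or `"average"`.
#' @param subject_id opaque identifier.
#' @param age subject age in years, or `NA`.
#' @param gender `"M"`, `"F"`, or `NA`.
#' @param validate check the montage and reorder channels canonically.
#' @return An object of class `eeg_record` with fields `data` (matrix in
#'   canonical channel order), `sampling_rate`, `duration` (seconds),
#'   `reference`, `subject_id`, `age`, `gender`.
#' @export
eeg_record <- function(data, sampling_rate, reference = "as-recorded",
                       subject_id = "anon", age = NA_real_,
                       gender = NA_character_, validate = TRUE) {
  stopifnot(is.matrix(data), is.numeric(data), sampling_rate > 0)
  reference <- match.arg(reference, c("as-recorded", "average"))
  rec <- structure(
    list(data = data, sampling_rate = sampling_rate,
         duration = nrow(data) / sampling_rate, reference = reference,
         subject_id = subject_id, age = age, gender = gender),
    class = "eeg_record"
  )
  if (validate) rec <- validate_record(rec) else rec
}

#' Validate an EEG record against the canonical montage
#'
#' Maps labels through [canonical_label()], drops non-EEG channels with a
#' log entry, requires every canonical electrode exactly once, and
#' reorders columns to the canonical order.
#'
#' @param rec an `eeg_record`.
#' @return The validated record (channels in canonical order).
#' @export
validate_record <- function(rec) {
  stopifnot(inherits(rec, "eeg_record"))
  labs <- colnames(rec$data)
  if (is.null(labs)) dlb_stop("dlb_format_error", "channel labels are missing")
  mapped <- canonical_label(labs)
  drop <- is.na(mapped)
  if (any(drop)) {
    dlb_log("dropping non-EEG channels: ", paste(labs[drop], collapse = ", "))
    rec$data <- rec$data[, !drop, drop = FALSE]
    mapped <- mapped[!drop]
  }
  if (anyDuplicated(mapped))
    dlb_stop("dlb_montage_error",
             paste0("duplicated electrode(s): ",
                    paste(unique(mapped[duplicated(mapped)]), collapse = ", ")))
  missing <- setdiff(canonical_channels(), mapped)
  if (length(missing))
    dlb_stop("dlb_montage_error",
             paste0("missing electrode(s): ", paste(missing, collapse = ", ")),
             channels = missing)
  colnames(rec$data) <- mapped
  rec$data <- rec$data[, canonical_channels(), drop = FALSE]
  rec$duration <- nrow(rec$data) / rec$sampling_rate
  rec
}

#' Re-reference a record to the common average
#'
#' Subtracts, at every sample, the mean across the 19 channels, so that
#' the per-sample channel mean of the output is zero.  Re-applying to an
#' already average-referenced record is a no-op with a classed warning.
#'
#' @param rec a validated `eeg_record`.
#' @return The re-referenced record with `reference = "average"`.
#' @export
apply_average_reference <- function(rec) {
  stopifnot(inherits(rec, "eeg_record"))
  if (identical(rec$reference, "average")) {
    dlb_warn("dlb_idempotency_warning",
             "record is already average-referenced; returning unchanged")
    return(rec)
  }
  rec$data <- rec$data - rowMeans(rec$data)
  rec$reference <- "average"
  rec
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %s: %d ch x %.1f s @ %g Hz (%s reference)\n",
              x$subject_id, ncol(x$data), x$duration, x$sampling_rate,
              x$reference))
  invisible(x)
}
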