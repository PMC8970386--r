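# Minimal EDF (European Data Format) reader/writer covering the plain
# 16-bit continuous-recording subset used for resting-state EEG
# interchange: ASCII headers, one data record per second, little-endian
# int16 samples with per-channel physical scaling.  No installed R
# package provides EDF access, so the format is handled here directly.

.edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1, width)
}

.edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = -1)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4, width = -1)
  .edf_field(s, width)
}

#' Write an EEG record to an EDF file
#'
#' Samples are quantized to 16 bits against a per-channel symmetric
#' physical range covering the channel's absolute maximum, so a re-read
#' reproduces the signal within one quantization step.  Subject id,
#' gender and age are stored in the local-patient-identification header
#' field as `"<id> <M|F|X> age=<years|X>"` and recovered by [read_edf()].
#'
#' @param rec a validated `eeg_record` with integer sampling rate and a
#'   whole number of seconds of data.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_record"))
  if (any(!is.finite(rec$data)))
    dlb_stop("dlb_value_error", "record contains non-finite samples")
  fs <- rec$sampling_rate
  if (fs != round(fs))
    dlb_stop("dlb_value_error", "EDF export requires an integer sampling rate")
  n <- nrow(rec$data)
  if (n %% fs != 0)
    dlb_stop("dlb_value_error",
             "EDF export requires a whole number of 1-s data records")
  n_rec <- n %/% fs
  ns <- ncol(rec$data)
  labs <- colnames(rec$data)

  phys_max <- apply(abs(rec$data), 2, max)
  # round UP at the 4th significant digit so the declared range always
  # covers the channel maximum (nearest-rounding could clip the peaks)
  pow <- 10^(3 - floor(log10(ifelse(phys_max == 0, 1, phys_max))))
  phys_max <- ifelse(phys_max == 0, 1, ceiling(phys_max * pow) / pow)
  dig_max <- 32767L

  gender <- if (is.na(rec$gender)) "X" else rec$gender
  age <- if (is.na(rec$age)) "X" else formatC(rec$age, format = "g")
  patient <- sprintf("%s %s age=%s", gsub(" ", "_", rec$subject_id), gender, age)

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    .edf_field("0", 8),
    .edf_field(patient, 80),
    .edf_field("Startdate 01-JAN-2026 dlbindex", 80),
    .edf_field("01.01.26", 8),
    .edf_field("00.00.00", 8),
    .edf_field(256 + 256 * ns, 8),
    .edf_field("", 44),
    .edf_field(n_rec, 8),
    .edf_field("1", 8),
    .edf_field(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  sig_hdr <- paste0(
    paste(vapply(labs, .edf_field, "", width = 16), collapse = ""),
    paste(rep(.edf_field("AgAgCl impedance<=10kOhm", 80), ns), collapse = ""),
    paste(rep(.edf_field("uV", 8), ns), collapse = ""),
    paste(vapply(-phys_max, .edf_num, "", width = 8), collapse = ""),
    paste(vapply(phys_max, .edf_num, "", width = 8), collapse = ""),
    paste(rep(.edf_field(-dig_max, 8), ns), collapse = ""),
    paste(rep(.edf_field(dig_max, 8), ns), collapse = ""),
    paste(rep(.edf_field("BP 0.1-70 Hz possible", 80), ns), collapse = ""),
    paste(rep(.edf_field(fs, 8), ns), collapse = ""),
    paste(rep(.edf_field("", 32), ns), collapse = "")
  )
  writeChar(sig_hdr, con, eos = NULL)

  # record-major layout: for each 1-s record, all samples of ch1, ch2, ...
  scale <- dig_max / phys_max
  dig <- round(sweep(rec$data, 2, scale, "*"))
  dig <- pmin(pmax(dig, -dig_max), dig_max)
  # reorder to (sample-within-record, channel, record) for record-major output
  dim_ord <- aperm(array(dig, dim = c(fs, n_rec, ns)), c(1, 3, 2))
  writeBin(as.integer(dim_ord), con, size = 2, endian = "little")
  invisible(path)
}

.edf_read_field <- function(raw, off, width) {
  trimws(rawToChar(raw[(off + 1):(off + width)]))
}

#' Read an EDF/EDF+ file into an EEG record
#'
#' Maps channel labels onto the canonical 10-20 montage through the
#' synonym table (T7/T8/P7/P8 and case differences), drops non-EEG
#' channels (EOG, ECG, annotations) with a log entry, and validates that
#' all 19 electrodes are present.  A log note is emitted when no
#' impedance annotation is found in the transducer fields (the recording
#' protocol requires electrode impedances of 10 kOhm or less, which can
#' only be carried as metadata).
#'
#' @param path EDF file path.
#' @return A validated `eeg_record` in canonical channel order.
#' @export
read_edf <- function(path) {
  if (!file.exists(path))
    dlb_stop("dlb_format_error", paste0("file not found: ", path))
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256)
    dlb_stop("dlb_format_error", "file too short to be EDF")
  con <- file(path, "rb")
  on.exit(close(con))
  h <- readBin(con, "raw", 256)
  version <- .edf_read_field(h, 0, 8)
  if (!version %in% c("0"))
    dlb_stop("dlb_format_error", "not an EDF file (bad version field)")
  patient <- .edf_read_field(h, 8, 80)
  n_rec <- suppressWarnings(as.integer(.edf_read_field(h, 236, 8)))
  rec_dur <- suppressWarnings(as.numeric(.edf_read_field(h, 244, 8)))
  ns <- suppressWarnings(as.integer(.edf_read_field(h, 252, 4)))
  if (anyNA(c(n_rec, rec_dur, ns)) || ns < 1)
    dlb_stop("dlb_format_error", "corrupt EDF header")
  sh <- readBin(con, "raw", 256 * ns)
  fld <- function(block_off, width, i, as_num = FALSE) {
    v <- .edf_read_field(sh, block_off * ns + (i - 1) * width, width)
    if (as_num) suppressWarnings(as.numeric(v)) else v
  }
  # cumulative byte offsets of the per-signal header blocks
  labs <- vapply(seq_len(ns), function(i) fld(0, 16, i), "")
  transducers <- vapply(seq_len(ns), function(i) fld(16, 80, i), "")
  pmin_ <- vapply(seq_len(ns), function(i) fld(104, 8, i, TRUE), 0)
  pmax_ <- vapply(seq_len(ns), function(i) fld(112, 8, i, TRUE), 0)
  dmin_ <- vapply(seq_len(ns), function(i) fld(120, 8, i, TRUE), 0)
  dmax_ <- vapply(seq_len(ns), function(i) fld(128, 8, i, TRUE), 0)
  spr <- vapply(seq_len(ns), function(i) fld(216, 8, i, TRUE), 0)
  if (anyNA(spr)) dlb_stop("dlb_format_error", "corrupt EDF signal header")

  total <- sum(spr) * n_rec
  raw_samp <- readBin(con, "integer", n = total, size = 2, endian = "little")
  if (length(raw_samp) < total)
    dlb_stop("dlb_format_error", "EDF data section truncated")

  # slice record-major data into per-channel vectors
  offsets <- c(0, cumsum(spr))
  rec_len <- sum(spr)
  data_list <- lapply(seq_len(ns), function(i) {
    idx <- as.vector(outer(seq_len(spr[i]) + offsets[i],
                           (seq_len(n_rec) - 1) * rec_len, "+"))
    x <- raw_samp[idx]
    gain <- (pmax_[i] - pmin_[i]) / (dmax_[i] - dmin_[i])
    (x - dmin_[i]) * gain + pmin_[i]
  })

  mapped <- canonical_label(labs)
  keep <- !is.na(mapped)
  if (!any(keep)) dlb_stop("dlb_montage_error", "no EEG channels found")
  if (length(unique(spr[keep])) != 1)
    dlb_stop("dlb_format_error", "EEG channels have differing sampling rates")
  fs <- spr[keep][1] / rec_dur
  if (any(!keep))
    dlb_log("dropping non-EEG channels: ",
            paste(labs[!keep], collapse = ", "))
  if (!any(grepl("imped", transducers[keep], ignore.case = TRUE)))
    dlb_log("no impedance annotation in EDF transducer fields; ",
            "the <=10 kOhm electrode impedance rule cannot be verified")

  dat <- do.call(cbind, data_list[keep])
  colnames(dat) <- mapped[keep]

  # recover subject metadata from the patient field when present
  toks <- strsplit(patient, " +")[[1]]
  subject_id <- if (length(toks)) toks[1] else "anon"
  gender <- if (length(toks) >= 2 && toks[2] %in% c("M", "F")) toks[2]
            else NA_character_
  age <- NA_real_
  age_tok <- grep("^age=", toks, value = TRUE)
  if (length(age_tok)) {
    a <- suppressWarnings(as.numeric(sub("^age=", "", age_tok[1])))
    if (!is.na(a)) age <- a
  }
  eeg_record(dat, fs, subject_id = subject_id, age = age, gender = gender)
}
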