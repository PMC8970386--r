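# Seeded synthetic 19-channel EEG cohorts with the qEEG group structure
# the classifier targets: an AD-like group with a posterior dominant
# rhythm near 9 Hz, and a DLB-like group whose dominant rhythm slows into
# the pre-alpha band (5.6-7.9 Hz at full separation), wanders more
# (greater dominant-frequency variability) and carries more diffuse slow
# (1-4 Hz) power -- on top of 1/f background noise with a shared
# volume-conduction component, and optional blink/EMG artefacts.

#' Specify a synthetic cohort
#'
#' `separation` is a single difficulty dial in `[0, 1]`: at 0 the two
#' groups' generative parameter distributions are identical (a null
#' cohort); at 1 the DLB-like group sits fully in the pre-alpha regime.
#' Group means interpolate linearly in between.
#'
#' @param n_dlb,n_ad group sizes.
#' @param separation group separation lambda in `[0, 1]`.
#' @param fs sampling rate in Hz (default 200).
#' @param duration recording length in seconds (default 170, so a clean
#'   150-s epoch always exists).
#' @param seed integer seed; every subject's parameters and signal are
#'   reproducible from it.
#' @param artefact_rate blink/EMG events per minute (default 0).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_dlb, n_ad, separation = 1, fs = 200,
                        duration = 170, seed = 1L, artefact_rate = 0) {
  stopifnot(n_dlb >= 0, n_ad >= 0, separation >= 0, separation <= 1,
            fs >= 160, duration >= 150)
  structure(list(n_dlb = n_dlb, n_ad = n_ad, separation = separation,
                 fs = fs, duration = duration, seed = as.integer(seed),
                 artefact_rate = artefact_rate,
                 age_mean = 76.5, age_sd = 6, age_range = c(50, 90),
                 p_male = 0.5),
            class = "cohort_spec")
}

# group-level generative parameter distributions at separation lambda
.group_params <- function(group, lambda) {
  if (group == "AD") lambda <- 0
  list(
    f0_mean = 9.0 - 2.2 * lambda, f0_sd = 0.5 + 0.1 * lambda,
    f0_clip = c(7.5 - 1.9 * lambda, 10.5 - 2.6 * lambda),
    fv_mean = 0.15 + 0.35 * lambda, fv_sd = 0.05 + 0.05 * lambda,
    fv_clip = c(0.05, 0.5 + 0.5 * lambda),
    slow_mean = 1.0 + 1.0 * lambda, slow_sd = 0.15 + 0.1 * lambda,
    slow_clip = c(0.5, 2.0 + 1.5 * lambda)
  )
}

.clip <- function(x, b) pmin(pmax(x, b[1]), b[2])

#' Draw one subject's generative parameters
#'
#' Reproducible given `(spec$seed, group, index)`.
#'
#' @param spec a `cohort_spec`.
#' @param group `"DLB"` or `"AD"`.
#' @param index subject index within the group.
#' @return Object of class `subject_spec`: dominant frequency (Hz),
#'   dominant-frequency variability (Hz/s random-walk SD), slow-power
#'   gain, age, gender, seed.
#' @export
draw_subject <- function(spec, group, index = 1L) {
  group <- match.arg(group, c("DLB", "AD"))
  seed_i <- as.integer((as.double(spec$seed) * 20011 + index * 2 +
                          (group == "DLB")) %% 2147483647)
  set.seed(seed_i)
  p <- .group_params(group, spec$separation)
  structure(list(
    group = group,
    dominant_freq = .clip(rnorm(1, p$f0_mean, p$f0_sd), p$f0_clip),
    freq_variability = .clip(rnorm(1, p$fv_mean, p$fv_sd), p$fv_clip),
    slow_power_gain = .clip(rnorm(1, p$slow_mean, p$slow_sd), p$slow_clip),
    age = .clip(rnorm(1, spec$age_mean, spec$age_sd), spec$age_range),
    gender = if (runif(1) < spec$p_male) "M" else "F",
    seed = seed_i,
    subject_id = sprintf("%s%03d", tolower(group), index)),
    class = "subject_spec")
}

# k independent unit-variance 1/f (pink) noise series via spectral
# shaping; two real series are packed per complex transform
.pink_noise <- function(n, k = 1) {
  m <- ceiling(k / 2)
  W <- matrix(complex(real = rnorm(n * m), imaginary = rnorm(n * m)), n, m)
  g <- 1 / sqrt(c(Inf, pmin(seq_len(n - 1), n - seq_len(n - 1))))
  X <- stats::mvfft(stats::mvfft(W) * g, inverse = TRUE) / n
  out <- cbind(Re(X), Im(X))[, seq_len(k), drop = FALSE]
  sweep(out, 2, apply(out, 2, stats::sd), "/")
}

# reflect a random walk into [lo, hi]
.reflect <- function(x, lo, hi) {
  r <- hi - lo
  y <- (x - lo) %% (2 * r)
  lo + pmin(y, 2 * r - y)
}

# channel gain profiles over the canonical montage
.topo <- function(values) {
  g <- stats::setNames(rep(values[["default"]], 19), canonical_channels())
  for (nm in setdiff(names(values), "default")) g[nm] <- values[[nm]]
  g
}

.alpha_topo <- function() .topo(list(
  default = 0.25, O1 = 1, O2 = 1, P3 = 0.8, P4 = 0.8, Pz = 0.8,
  T5 = 0.7, T6 = 0.7, C3 = 0.4, C4 = 0.4, Cz = 0.4))

.blink_topo <- function() .topo(list(
  default = 0.05, Fp1 = 1, Fp2 = 1, F3 = 0.5, F4 = 0.5,
  F7 = 0.5, F8 = 0.5, Fz = 0.5))

.emg_topo <- function() .topo(list(
  default = 0.02, T3 = 1, T4 = 1, T5 = 0.6, T6 = 0.6, F7 = 0.6, F8 = 0.6))

#' Generate one subject's synthetic EEG record
#'
#' Per channel: 1/f pink noise (independent per channel plus a shared
#' volume-conduction source mixed at gain 0.3) plus a shared narrow-band
#' oscillation whose instantaneous frequency follows a reflected random
#' walk (per-second SD = `freq_variability`) around `dominant_freq`, with
#' posterior-maximal topography, plus a diffuse 1-4 Hz component scaled
#' by `slow_power_gain`.  Optional blink transients (frontal, < 3 Hz) and
#' EMG bursts (temporal, > 20 Hz) are injected at `spec$artefact_rate`
#' events per minute.  Units are microvolts.
#'
#' @param subject a `subject_spec`.
#' @param spec the parent `cohort_spec`.
#' @return A validated `eeg_record` (as-recorded reference).
#' @export
generate_subject_eeg <- function(subject, spec) {
  stopifnot(inherits(subject, "subject_spec"), inherits(spec, "cohort_spec"))
  if (spec$duration < 150)
    dlb_stop("dlb_value_error", "duration must be at least 150 s")
  set.seed(subject$seed + 1L)
  fs <- spec$fs
  n <- round(spec$duration * fs)
  chs <- canonical_channels()

  # shared narrow-band oscillation with wandering instantaneous frequency
  f0 <- subject$dominant_freq
  steps <- rnorm(n, 0, subject$freq_variability / sqrt(fs))
  f_inst <- .reflect(f0 + cumsum(steps), max(1, f0 - 2), f0 + 2)
  osc <- sin(2 * pi * cumsum(f_inst) / fs)

  # diffuse slow (1-4 Hz) component, shared across channels
  bf <- signal::butter(2, c(1, 4) / (fs / 2), type = "pass")
  slow <- cpp_filtfilt(bf$b, bf$a, matrix(rnorm(n), ncol = 1))[, 1]
  slow <- slow / stats::sd(slow)

  pink <- .pink_noise(n, 20)
  common_pink <- pink[, 20]
  alpha_gain <- .alpha_topo()

  data <- 10 * pink[, 1:19] +
    outer(3 * common_pink, rep(1, 19)) +
    outer(20 * osc, alpha_gain) +
    outer(6 * subject$slow_power_gain * slow, rep(1, 19))
  dimnames(data) <- list(NULL, chs)

  if (spec$artefact_rate > 0) {
    minutes <- spec$duration / 60
    t_idx <- seq_len(n)
    add_events <- function(topo, make_wave) {
      n_ev <- stats::rpois(1, spec$artefact_rate * minutes)
      for (e in seq_len(n_ev)) {
        center <- runif(1, 5, spec$duration - 5) * fs
        wave <- make_wave(center)
        data <<- data + outer(wave, topo)
      }
    }
    add_events(.blink_topo(), function(center) {
      150 * exp(-((t_idx - center) / (0.1 * fs))^2)     # ~0.2 s blink
    })
    emg_bf <- signal::butter(2, 20 / (fs / 2), type = "high")
    add_events(.emg_topo(), function(center) {
      env <- exp(-((t_idx - center) / (0.25 * fs))^2)
      burst <- cpp_filtfilt(emg_bf$b, emg_bf$a,
                            matrix(rnorm(n), ncol = 1))[, 1]
      50 * env * burst / stats::sd(burst)
    })
  }

  eeg_record(data, fs, subject_id = subject$subject_id,
             age = subject$age, gender = subject$gender)
}

#' Simulate a cohort in memory
#'
#' Draws all subjects and generates their records without touching disk.
#'
#' @param spec a `cohort_spec`.
#' @return List: `records` (named list of `eeg_record`), `manifest`
#'   (data frame: subject_id, age, gender, diagnosis), `subjects`
#'   (list of `subject_spec`).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- c(
    lapply(seq_len(spec$n_dlb), function(i) draw_subject(spec, "DLB", i)),
    lapply(seq_len(spec$n_ad), function(i) draw_subject(spec, "AD", i)))
  records <- lapply(subjects, generate_subject_eeg, spec = spec)
  names(records) <- vapply(subjects, `[[`, "", "subject_id")
  manifest <- data.frame(
    subject_id = names(records),
    age = vapply(subjects, `[[`, 0, "age"),
    gender = vapply(subjects, `[[`, "", "gender"),
    diagnosis = vapply(subjects, `[[`, "", "group"))
  list(records = records, manifest = manifest, subjects = subjects)
}

#' Generate a cohort on disk (EDF files + manifest + truth labels)
#'
#' @param spec a `cohort_spec`.
#' @param out_dir writable output directory (created if absent).
#' @return The manifest data frame (with `edf_path` column), invisibly;
#'   also writes `manifest.csv` and `truth.csv`.
#' @export
generate_cohort <- function(spec, out_dir) {
  sim <- simulate_cohort(spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  # EDF export needs whole seconds
  paths <- vapply(names(sim$records), function(id) {
    p <- file.path(out_dir, paste0(id, ".edf"))
    write_edf(sim$records[[id]], p)
    p
  }, "")
  manifest <- sim$manifest
  manifest$edf_path <- unname(paths)
  manifest$drug <- ""
  manifest$dose_mg <- NA_real_
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  write.csv(manifest[, c("subject_id", "diagnosis")],
            file.path(out_dir, "truth.csv"), row.names = FALSE)
  invisible(manifest)
}
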