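# Pair enumeration, segment spectra, covariance tensor, robust
# aggregation, and the single-recording extraction chain.

test_that("pair enumeration covers all 190 pairs, auto pairs first", {
  pairs <- enumerate_pairs()
  expect_equal(nrow(pairs), 190)
  expect_equal(sum(pairs$auto), 19)
  expect_true(all(pairs$auto[1:19]))
  expect_equal(pairs$c[1:19], 1:19)
  cross <- pairs[!pairs$auto, ]
  expect_equal(nrow(cross), 171)
  expect_true(all(cross$c < cross$k))
  expect_false(anyDuplicated(paste(pairs$c, pairs$k)) > 0)
  expect_equal(pairs$label[1], "Fp1-Fp1")
})

test_that("frequency grid is 0.5 to 45 Hz in half-Hz steps", {
  f <- spectral_freqs()
  expect_length(f, 90)
  expect_equal(f[1], 0.5)
  expect_equal(f[90], 45)
  expect_equal(unique(diff(f)), 0.5)
})

test_that("segment spectra recover a pure tone at the right bin", {
  fs <- 200
  t <- seq_len(160 * fs) / fs
  amp <- 7
  chs <- canonical_channels()
  data <- matrix(amp * cos(2 * pi * 10.5 * t), ncol = 19, nrow = length(t),
                 dimnames = list(NULL, chs))
  rec <- eeg_record(data, fs)
  sp <- compute_segment_spectra(segment_epoch(extract_epoch(rec)))
  expect_equal(dim(sp$sigma), c(90, 19, 149))
  mag <- Mod(sp$sigma[, 1, 1])
  peak <- which.max(mag)
  expect_equal(sp$freqs[peak], 10.5)
  # 1/n scaling: a cosine of amplitude A has |coefficient| A/2 at its bin
  expect_equal(mag[peak], amp / 2, tolerance = 1e-8)
  expect_lt(max(mag[-peak]), 1e-8)
})

test_that("segment spectra enforce the half-Hz resolution contract", {
  rec <- tiny_record()
  ep <- extract_epoch(rec)
  expect_error(compute_segment_spectra(segment_epoch(ep, length = 1)),
               class = "dlb_resolution_error")
  slow <- tiny_record(fs = 80, duration = 160)
  sp80 <- segment_epoch(extract_epoch(slow))
  expect_error(compute_segment_spectra(sp80), class = "dlb_resolution_error")
})

test_that("covariance tensor is the pairwise conjugate product", {
  sigma <- random_sigma(nc = 4)
  sp <- structure(list(sigma = sigma, freqs = spectral_freqs(),
                       channel_labels = paste0("ch", 1:4), n_segments = 7),
                  class = "eeg_spectra")
  cov <- compute_covariances(sp)
  expect_equal(dim(cov$chi), c(90, 10, 7))
  p <- cov$pairs
  i <- which(p$c == 2 & p$k == 4)
  expect_equal(cov$chi[, i, 3], sigma[, 2, 3] * Conj(sigma[, 4, 3]))
  # auto pairs: real power spectra, structural zero imaginary part
  a <- which(p$c == 3 & p$k == 3)
  expect_equal(Im(cov$chi[, a, ]), matrix(0, 90, 7))
  expect_true(all(Re(cov$chi[, a, ]) >= 0))
})

test_that("median aggregation resists a contaminated segment", {
  sigma <- random_sigma(nc = 3, ns = 9)
  mk <- function(s) {
    sp <- structure(list(sigma = s, freqs = spectral_freqs(),
                         channel_labels = paste0("ch", 1:3), n_segments = 9),
                    class = "eeg_spectra")
    compute_covariances(sp)
  }
  clean <- mk(sigma)
  dirty_sigma <- sigma
  dirty_sigma[, , 5] <- dirty_sigma[, , 5] * 100   # one artefact segment
  dirty <- mk(dirty_sigma)

  med_clean <- robust_aggregate(clean)$values
  med_dirty <- robust_aggregate(dirty)$values
  mean_clean <- robust_aggregate(clean, "mean")$values
  mean_dirty <- robust_aggregate(dirty, "mean")$values
  expect_lt(mean(abs(med_dirty - med_clean)),
            0.05 * mean(abs(mean_dirty - mean_clean)))

  # estimators agree with their base-R counterparts
  x <- Re(clean$chi[5, 2, ])
  expect_equal(robust_aggregate(clean)$values[(2 - 1) * 180 + (5 - 1) * 2 + 1],
               median(x))
  expect_equal(robust_aggregate(clean, "trimmed_mean")$values[
    (2 - 1) * 180 + (5 - 1) * 2 + 1], mean(x, trim = 0.2))
  expect_error(robust_aggregate(clean, "mode"), class = "dlb_value_error")

  few <- mk(sigma[, , 1:2, drop = FALSE])
  expect_error(robust_aggregate(few), class = "dlb_aggregation_error")
})

test_that("extraction chain produces the 34,200 base features", {
  feats <- shared_cohort()$features[[1]]
  expect_s3_class(feats, "subject_features")
  expect_length(feats$base$values, 34200)
  expect_length(base_feature_names(), 34200)
  expect_equal(base_feature_names()[1], "Fp1-Fp1_f0.5_re")
  expect_true(all(is.finite(feats$base$values)))

  # the imaginary slots of auto pairs are structural zeros
  auto_im <- as.vector(vapply(1:19, function(p)
    (p - 1) * 180 + seq(2, 180, by = 2), numeric(90)))
  expect_true(all(feats$base$values[auto_im] == 0))
  # cross-pair imaginary parts are generally not zero
  expect_gt(sum(feats$base$values != 0), 30000)
})

test_that("fast extraction path matches the reference tensor path", {
  rec <- shared_cohort()$sim$records[[1]]
  rec <- bandpass_filter(apply_average_reference(rec))
  sp <- compute_segment_spectra(segment_epoch(extract_epoch(rec)))
  ref <- robust_aggregate(compute_covariances(sp))
  fast <- shared_cohort()$features[[1]]$base
  expect_identical(ref$values, fast$values)
})

test_that("with_base = FALSE skips the base features but keeps spectra", {
  rec <- tiny_record()
  f <- extract_features(rec, with_base = FALSE)
  expect_null(f$base)
  expect_s3_class(f$spectra, "eeg_spectra")
  expect_error(feature_table(list(f)), class = "dlb_value_error")
})
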