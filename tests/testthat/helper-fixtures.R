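# Shared fixtures, memoized so expensive objects are built once per test
# run regardless of how many test files use them.

.fixture_env <- new.env(parent = emptyenv())

.memo <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

# A small deterministic 19-channel record: mixed sinusoids + noise.
# Long enough (160 s) for the full preprocessing chain.
tiny_record <- function(fs = 200, duration = 160, seed = 1,
                        subject_id = "tiny", age = 75, gender = "M") {
  set.seed(seed)
  n <- duration * fs
  t <- seq_len(n) / fs
  chs <- canonical_channels()
  data <- sapply(seq_along(chs), function(ci)
    10 * sin(2 * pi * (8 + 0.2 * ci) * t + ci) + rnorm(n, sd = 3))
  colnames(data) <- chs
  eeg_record(data, fs, subject_id = subject_id, age = age, gender = gender)
}

# Small labeled synthetic cohort with extracted features, shared by the
# feature-model, classifier, and pipeline tests.
shared_cohort <- function() {
  .memo("cohort", function() {
    spec <- cohort_spec(8, 8, separation = 1, seed = 42)
    sim <- simulate_cohort(spec)
    feats <- qeeg_extract(sim$manifest, sim$records)
    labels <- sim$manifest$diagnosis[match(names(feats),
                                           sim$manifest$subject_id)]
    list(sim = sim, features = feats, labels = labels,
         base = dlbindex:::.base_matrix(lapply(feats, function(s) s$base)))
  })
}

# Trained model set on the shared cohort (pooled; the cohort is too small
# for stable gender strata).
shared_model <- function() {
  .memo("model", function() {
    co <- shared_cohort()
    suppressWarnings(qeeg_train(co$features, co$sim$manifest))
  })
}

# One preprocessed spectra object from the shared cohort
shared_spectra <- function() shared_cohort()$features[[1]]$spectra

# Small random complex spectra cube (for kernel-level tests)
random_sigma <- function(nf = 90, nc = 4, ns = 7, seed = 3) {
  set.seed(seed)
  array(complex(real = rnorm(nf * nc * ns),
                imaginary = rnorm(nf * nc * ns)),
        dim = c(nf, nc, ns))
}
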