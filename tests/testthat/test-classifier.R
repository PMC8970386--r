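# GA feature selection, SVM training and de-standardization, index
# calibration, gender-stratified model sets.

.toy_problem <- function(n = 30, nf = 10, informative = c(2, 7), seed = 21,
                         sep = 3) {
  set.seed(seed)
  labels <- rep(c("DLB", "AD"), length.out = n)
  C <- matrix(rnorm(n * nf), n, nf)
  for (j in informative)
    C[, j] <- C[, j] + ifelse(labels == "DLB", sep, -sep)
  age <- runif(n, 60, 90)
  list(C = C, age = age, labels = labels)
}

test_that("the de-standardized index formula reproduces the SVM exactly", {
  tp <- .toy_problem()
  mask <- rep(FALSE, 10)
  mask[c(2, 5, 7)] <- TRUE
  fit <- train_svm(tp$C, tp$age, tp$labels, mask = mask)
  expect_length(fit$beta, 10)
  expect_true(all(fit$beta[!mask] == 0))
  # recompute the decision values from the explicit formula
  manual <- drop(tp$C %*% fit$beta) + fit$beta_age1 * tp$age +
    fit$beta_age2 * tp$age^2 + fit$rho
  expect_equal(manual, fit$raw_index, tolerance = 1e-10)
  # the raw index separates the toy classes with DLB high
  expect_gt(roc_auc(fit$raw_index, tp$labels), 0.95)
  expect_error(train_svm(tp$C, tp$age, rep("DLB", 30)),
               class = "dlb_value_error")
})

test_that("cross-validated AUC reflects class separation", {
  tp <- .toy_problem()
  set.seed(1)
  folds <- dlbindex:::.stratified_folds(tp$labels, 5)
  expect_equal(sort(unique(folds)), 1:5)
  expect_true(all(table(folds, tp$labels) >= 2))
  X <- dlbindex:::.standardize(tp$C)$X
  expect_gt(svm_cv_auc(X, tp$labels, folds), 0.9)
  null <- .toy_problem(sep = 0, seed = 22)
  Xn <- dlbindex:::.standardize(null$C)$X
  a <- svm_cv_auc(Xn, null$labels, folds)
  expect_gt(a, 0.15)
  expect_lt(a, 0.85)
})

test_that("GA selection finds the informative features", {
  tp <- .toy_problem(n = 40)
  ga <- ga_select_features(tp$C, tp$age, tp$labels, seed = 5)
  # the two informative features are redundant; at least one must be kept
  expect_true(any(ga$mask[c(2, 7)]))
  expect_lt(sum(ga$mask), 9)          # parsimony keeps the subset small
  expect_gt(ga$fitness, 0.9)
  expect_equal(ga$history, cummax(ga$history))  # elitism: monotone best
  expect_gt(ga$n_evaluated, 50)
})

test_that("index calibration places the cut-off at Youden's optimum", {
  raw <- c(-3, -2.5, -2, -1, 0.5, 1, 1.5, 2, 2.5, 3)
  labels <- rep(c("AD", "DLB"), each = 5)
  cal <- calibrate_index_scale(raw, labels)
  # perfect separation: the only optimal gap is (0.5, 1), so the
  # midpoint candidate 0.75 must be chosen
  expect_gt(cal$cutoff, 0.5)
  expect_lt(cal$cutoff, 1)
  expect_equal(cal$sd_ad, sd(raw[1:5]))
  idx <- (raw - cal$cutoff) / cal$sd_ad
  expect_true(all(idx[labels == "DLB"] >= 0))
  expect_true(all(idx[labels == "AD"] < 0))
  expect_error(calibrate_index_scale(raw, rep("DLB", 10)),
               class = "dlb_value_error")
})

test_that("model set training, classification and persistence", {
  co <- shared_cohort()
  ms <- shared_model()
  expect_s3_class(ms, "dlb_model_set")
  expect_true(length(ms$models) >= 1)

  preds <- qeeg_classify(co$features, ms)
  expect_equal(nrow(preds), 16)
  expect_true(all(is.finite(preds$index)))
  expect_equal(preds$classification, ifelse(preds$index >= 0, "DLB", "AD"))
  # training-cohort resubstitution should recover most labels
  truth <- co$sim$manifest$diagnosis[match(preds$subject_id,
                                           co$sim$manifest$subject_id)]
  expect_gt(mean(preds$classification == truth), 0.75)

  # persistence round trip
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(ms, path)
  ms2 <- load_model(path)
  s <- co$features[[3]]
  expect_equal(classify_subject(s, ms2), classify_subject(s, ms))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(format = "other"), bad)
  expect_error(load_model(bad), class = "dlb_format_error")
})

test_that("sparse gender strata fall back to the pooled model", {
  co <- shared_cohort()
  # force a single female subject: her stratum cannot be trained
  feats <- co$features
  genders <- vapply(feats, function(s) s$gender, "")
  target <- if (sum(genders == "F") <= sum(genders == "M")) "M" else "F"
  keep_one <- which(genders != target)[1]
  for (i in seq_along(feats))
    feats[[i]]$gender <- if (i == keep_one) setdiff(c("M", "F"), target) else target
  expect_warning(
    ms <- train_model(feats, co$labels),
    class = "dlb_pooled_fallback_warning")
  expect_true("pooled" %in% names(ms$models))
  # the lone subject classifies through the pooled model
  res <- classify_subject(feats[[keep_one]], ms)
  expect_true(res$classification %in% c("DLB", "AD"))

  # age is mandatory at classification time
  s <- feats[[2]]
  s$age <- NA_real_
  expect_error(classify_subject(s, ms), class = "dlb_age_required_error")
})
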