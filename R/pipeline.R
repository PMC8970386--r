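# Reproducible end-to-end workflow commands: extraction over a cohort
# manifest, training, classification, evaluation, and a self-contained
# synthetic validation run.  These are the functions the command-line
# wrapper (inst/cli/dlbindex) dispatches to.

.resolve_records <- function(manifest, records = NULL) {
  if (!is.null(records)) return(records[manifest$subject_id])
  if (is.null(manifest$edf_path))
    dlb_stop("dlb_run_error", "manifest has no edf_path and no records given")
  stats::setNames(as.list(manifest$edf_path), manifest$subject_id)
}

#' Extract base features for every recording in a manifest
#'
#' Per-row failures (unreadable file, bad montage, short recording) are
#' logged and skipped so one corrupt file does not abort a cohort run; a
#' run with zero successful rows is an error.
#'
#' @param manifest data frame with columns `subject_id`, `age`, `gender`,
#'   and either `edf_path` or a matching `records` list.
#' @param records optional named list of in-memory `eeg_record`s keyed by
#'   subject id (used instead of reading EDFs).
#' @param config pipeline configuration.
#' @param with_base compute the 34,200 base features (default); see
#'   [extract_features()].
#' @return Named list of `subject_features`; failures are reported in the
#'   `failures` attribute (named character vector of messages).
#' @export
qeeg_extract <- function(manifest, records = NULL,
                         config = default_config(), with_base = TRUE) {
  if (nrow(manifest) == 0)
    dlb_stop("dlb_run_error", "empty manifest")
  src <- .resolve_records(manifest, records)
  out <- list()
  failures <- character()
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$subject_id[i]
    res <- tryCatch({
      rec <- src[[id]]
      if (is.character(rec)) rec <- read_edf(rec)
      rec$subject_id <- id
      if (!is.na(manifest$age[i])) rec$age <- manifest$age[i]
      if (!is.null(manifest$gender) && !is.na(manifest$gender[i]))
        rec$gender <- manifest$gender[i]
      extract_features(rec, config, with_base = with_base)
    }, dlb_error = function(e) e, error = function(e) e)
    if (inherits(res, "error")) {
      failures[id] <- conditionMessage(res)
      dlb_log("extraction failed for ", id, ": ", conditionMessage(res))
    } else out[[id]] <- res
  }
  if (length(out) == 0)
    dlb_stop("dlb_run_error", "no recording could be processed")
  attr(out, "failures") <- failures
  out
}

#' Turn extracted features into a flat table
#'
#' One row per recording, 34,200 feature columns named
#' `<pair>_f<freq>_<re|im>` plus `subject_id`, `age`, `gender`.
#'
#' @param features list of `subject_features` from [qeeg_extract()].
#' @return A data frame.
#' @export
feature_table <- function(features) {
  if (any(vapply(features, function(s) is.null(s$base), TRUE)))
    dlb_stop("dlb_value_error",
             "features were extracted with with_base = FALSE; base features are required here")
  X <- do.call(rbind, lapply(features, function(s) s$base$values))
  colnames(X) <- base_feature_names()
  cbind(data.frame(
    subject_id = vapply(features, `[[`, "", "subject_id"),
    age = vapply(features, function(s) as.numeric(s$age), 0),
    gender = vapply(features, `[[`, "", "gender")),
    as.data.frame(X))
}

#' Train gender-specific models from a labeled manifest
#'
#' @param features list of `subject_features`.
#' @param manifest data frame with `subject_id` and `diagnosis`.
#' @param config pipeline configuration.
#' @return A `dlb_model_set`.
#' @export
qeeg_train <- function(features, manifest, config = default_config()) {
  ids <- vapply(features, `[[`, "", "subject_id")
  m <- manifest[match(ids, manifest$subject_id), , drop = FALSE]
  if (anyNA(m$diagnosis))
    dlb_stop("dlb_run_error", "missing diagnosis for some extracted subjects")
  if (length(unique(m$diagnosis)) < 2)
    dlb_stop("dlb_run_error", "training needs both DLB and AD subjects")
  train_model(features, m$diagnosis, config)
}

#' Classify extracted recordings
#'
#' @param features list of `subject_features`.
#' @param model_set a trained `dlb_model_set`.
#' @return Data frame: `subject_id`, `index` (AD-SD units),
#'   `classification` (`"DLB"` iff index >= 0).  Row-level failures
#'   (e.g. missing age) are logged, reported in the `failures`
#'   attribute, and omitted from the output.
#' @export
qeeg_classify <- function(features, model_set) {
  rows <- list()
  failures <- character()
  for (s in features) {
    res <- tryCatch(classify_subject(s, model_set),
                    dlb_error = function(e) e, error = function(e) e)
    if (inherits(res, "error")) {
      failures[s$subject_id] <- conditionMessage(res)
      dlb_log("classification failed for ", s$subject_id, ": ",
              conditionMessage(res))
    } else rows[[s$subject_id]] <- as.data.frame(res)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  out
}

#' Evaluate predictions against clinical truth, with subgroups
#'
#' Computes overall diagnostic metrics and, for each named subgroup rule,
#' the metrics on the filtered cohort -- mirroring a validation report
#' with an all-subjects column and medication-subgroup columns.
#'
#' @param predictions data frame from [qeeg_classify()] (`subject_id`,
#'   `classification`).
#' @param truth data frame with `subject_id` and `diagnosis`; may carry a
#'   `medications` attribute (long-format medication table).
#' @param rules named list of medication rules (see
#'   [rule_donepezil_gt5()]).
#' @param ci_level confidence level for the exact CIs.
#' @return List of `diagnostic_metrics`, one per column (first entry
#'   `"all"`), with the matched cohorts' confusion tables attached.
#' @export
qeeg_evaluate <- function(predictions, truth, rules = list(),
                          ci_level = 0.95) {
  unmatched <- setdiff(predictions$subject_id, truth$subject_id)
  if (length(unmatched))
    dlb_stop("dlb_run_error",
             paste0("predictions without truth rows: ",
                    paste(unmatched, collapse = ", ")))
  eval_on <- function(t) {
    p <- predictions[match(t$subject_id, predictions$subject_id), ,
                     drop = FALSE]
    keep <- !is.na(p$subject_id)
    tab <- confusion(p$classification[keep], t$diagnosis[keep])
    met <- diagnostic_metrics(tab, ci_level)
    attr(met, "confusion") <- tab
    met
  }
  out <- list(all = eval_on(truth))
  for (nm in names(rules))
    out[[nm]] <- eval_on(subgroup_filter(truth, rules[[nm]]))
  out
}

#' Format an evaluation as a compact report table
#'
#' @param evaluation output of [qeeg_evaluate()].
#' @return Character vector of report lines (one block per column).
#' @export
format_evaluation <- function(evaluation) {
  unlist(lapply(names(evaluation), function(nm)
    c(sprintf("== %s ==", nm), format(evaluation[[nm]]), "")))
}

#' Self-contained synthetic validation run
#'
#' Simulates independent training and test cohorts at a given group
#' separation, trains the full pipeline on the training cohort, and
#' evaluates on the held-out cohort.  This is the package's stand-in for
#' a clinical validation study: with full separation the pipeline should
#' recover the group structure on unseen subjects; with zero separation
#' (a null cohort) held-out performance should hover at chance.
#'
#' @param n_train,n_test per-class cohort sizes (train / held-out).
#' @param separation group separation lambda.
#' @param seed integer seed driving simulation and training.
#' @param config pipeline configuration (its `seed` is overwritten).
#' @return List: `auc`, `accuracy`, `metrics` (a `diagnostic_metrics`),
#'   `predictions`, `model_set`.
#' @export
run_validation_study <- function(n_train = 40, n_test = 20, separation = 1,
                                 seed = 1L, config = default_config()) {
  config$seed <- as.integer(seed)
  train_spec <- cohort_spec(n_train, n_train, separation, seed = seed)
  test_spec <- cohort_spec(n_test, n_test, separation,
                           seed = seed + 500000L)
  train <- simulate_cohort(train_spec)
  feats <- qeeg_extract(train$manifest, train$records, config)
  model_set <- suppressWarnings(qeeg_train(feats, train$manifest, config))
  rm(train, feats)

  test <- simulate_cohort(test_spec)
  test_feats <- qeeg_extract(test$manifest, test$records, config,
                             with_base = FALSE)
  preds <- qeeg_classify(test_feats, model_set)
  truth <- test$manifest[match(preds$subject_id, test$manifest$subject_id), ]
  auc <- roc_auc(preds$index, truth$diagnosis)
  tab <- confusion(preds$classification, truth$diagnosis)
  met <- diagnostic_metrics(tab)
  list(auc = auc, accuracy = met$accuracy$estimate / 100, metrics = met,
       predictions = cbind(preds, diagnosis = truth$diagnosis),
       model_set = model_set)
}
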