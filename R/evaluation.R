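# Diagnostic-performance statistics: confusion metrics with exact
# binomial confidence intervals, ROC AUC, Fisher exact test, binomial
# power, and declarative medication-subgroup filtering.  DLB is the
# positive class throughout.

#' Cross-tabulate predictions against clinical truth
#'
#' @param predictions,truths equal-length vectors over `{"DLB", "AD"}`.
#' @return Object of class `confusion_table`: `tp`, `fn`, `tn`, `fp`
#'   (DLB positive).
#' @export
confusion <- function(predictions, truths) {
  predictions <- as.character(predictions)
  truths <- as.character(truths)
  if (length(predictions) != length(truths))
    dlb_stop("dlb_value_error", "prediction and truth lengths differ")
  ok <- c("DLB", "AD")
  if (!all(predictions %in% ok) || !all(truths %in% ok))
    dlb_stop("dlb_value_error", "labels must be 'DLB' or 'AD'")
  structure(list(
    tp = sum(predictions == "DLB" & truths == "DLB"),
    fn = sum(predictions == "AD" & truths == "DLB"),
    tn = sum(predictions == "AD" & truths == "AD"),
    fp = sum(predictions == "DLB" & truths == "AD")),
    class = "confusion_table")
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided interval from inversion of the binomial tails (beta-quantile
#' form); the lower bound is 0 when no successes, the upper 100 when all.
#'
#' @param successes,n counts.
#' @param level confidence level (default 0.95).
#' @return Numeric `c(lower, upper)` in percent.
#' @export
clopper_pearson <- function(successes, n, level = 0.95) {
  if (n < 1 || successes < 0 || successes > n)
    dlb_stop("dlb_value_error", "invalid counts")
  a <- 1 - level
  lo <- if (successes == 0) 0 else qbeta(a / 2, successes, n - successes + 1)
  hi <- if (successes == n) 1 else qbeta(1 - a / 2, successes + 1, n - successes)
  100 * c(lower = lo, upper = hi)
}

#' Sensitivity, specificity and accuracy with exact CIs
#'
#' Sensitivity is the percentage of clinical DLB subjects classified DLB,
#' specificity the percentage of clinical AD subjects classified AD, and
#' accuracy the percentage of agreements; 95% confidence intervals are
#' exact binomial (Clopper-Pearson).  Values are kept at full precision;
#' rounding to one decimal happens only in [format()]/printing.
#'
#' @param tab a `confusion_table`.
#' @param ci_level confidence level.
#' @return Object of class `diagnostic_metrics`: per metric the point
#'   estimate (%) and `(lower, upper)` CI, plus `n_pos`, `n_neg`.
#' @export
diagnostic_metrics <- function(tab, ci_level = 0.95) {
  stopifnot(inherits(tab, "confusion_table"))
  n_pos <- tab$tp + tab$fn
  n_neg <- tab$tn + tab$fp
  if (n_pos == 0 || n_neg == 0)
    dlb_stop("dlb_metrics_error", "both classes must be represented")
  n <- n_pos + n_neg
  mk <- function(x, m) list(estimate = 100 * x / m,
                            ci = clopper_pearson(x, m, ci_level))
  structure(list(sensitivity = mk(tab$tp, n_pos),
                 specificity = mk(tab$tn, n_neg),
                 accuracy = mk(tab$tp + tab$tn, n),
                 n_pos = n_pos, n_neg = n_neg, ci_level = ci_level),
            class = "diagnostic_metrics")
}

#' @export
format.diagnostic_metrics <- function(x, ...) {
  line <- function(nm, m)
    sprintf("%-12s %.1f (%.1f-%.1f)", nm, m$estimate, m$ci[1], m$ci[2])
  paste(c(sprintf("n (DLB, AD)  %d (%d, %d)", x$n_pos + x$n_neg,
                  x$n_pos, x$n_neg),
          line("Sensitivity", x$sensitivity),
          line("Specificity", x$specificity),
          line("Accuracy", x$accuracy)), collapse = "\n")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a random DLB subject's score
#' exceeds a random AD subject's, ties counted one half.
#'
#' @param scores numeric scores (higher = more DLB-like).
#' @param labels `"DLB"`/`"AD"` per score.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.character(labels)
  pos <- scores[labels == "DLB"]
  neg <- scores[labels == "AD"]
  if (length(pos) == 0 || length(neg) == 0)
    dlb_stop("dlb_value_error", "both classes required for AUC")
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Two-sided p-value by the sum of hypergeometric probabilities of all
#' tables with the observed margins that are no more probable than the
#' observed one (relative tolerance 1e-7 on the comparison), i.e. the
#' convention of [stats::fisher.test()], which performs the computation.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == 2) || any(tab < 0) || any(tab != round(tab)))
    dlb_stop("dlb_value_error", "need a 2x2 table of non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    dlb_stop("dlb_value_error", "table has a zero margin")
  stats::fisher.test(tab)$p.value
}

#' Power of the exact one-sample binomial test
#'
#' Finds the smallest critical count `k*` with
#' `P(X >= k* | p0) <= alpha` and returns the power
#' `P(X >= k* | p1)` of the corresponding exact test (one-sided; the
#' two-sided variant splits alpha).
#'
#' @param n sample size.
#' @param p0 null proportion.
#' @param p1 alternative proportion.
#' @param alpha test level (default 0.05).
#' @param one_sided one-sided alternative `p > p0` (default TRUE).
#' @return List: `power`, `critical` (k*), `size` (achieved level).
#' @export
binomial_power <- function(n, p0, p1, alpha = 0.05, one_sided = TRUE) {
  stopifnot(n >= 1, p0 > 0, p0 < 1, p1 > 0, p1 < 1)
  a <- if (one_sided) alpha else alpha / 2
  tail <- function(k) 1 - pbinom(k - 1, n, p0)   # P(X >= k | p0)
  ks <- 0:(n + 1)
  ok <- vapply(ks, tail, 0) <= a
  k_star <- ks[which(ok)[1]]
  list(power = 1 - pbinom(k_star - 1, n, p1),
       critical = k_star, size = tail(k_star))
}

#' Medication subgroup exclusion rules
#'
#' Declarative rules over a long-format medication table (columns
#' `subject_id`, `drug`, `dose_mg`): `rule_donepezil_gt5()` excludes
#' subjects taking more than 5 mg/day donepezil;
#' `rule_achei_half_max()` excludes subjects taking any
#' acetylcholinesterase inhibitor above half its maximum approved daily
#' dose (donepezil 10, rivastigmine 18, galantamine 24 mg/day, so
#' half-max 5 / 9 / 12); `rule_none()` keeps everyone.
#'
#' @return A rule object for [subgroup_filter()].
#' @export
rule_donepezil_gt5 <- function() {
  structure(list(limits = c(donepezil = 5)), class = "medication_rule",
            label = "excluding donepezil > 5 mg")
}

#' @rdname rule_donepezil_gt5
#' @export
rule_achei_half_max <- function() {
  structure(list(limits = c(donepezil = 5, rivastigmine = 9,
                            galantamine = 12)),
            class = "medication_rule",
            label = "excluding any AChEI > half the maximum dose")
}

#' @rdname rule_donepezil_gt5
#' @export
rule_none <- function() {
  structure(list(limits = c()), class = "medication_rule",
            label = "all subjects")
}

#' Filter a cohort manifest by a medication rule
#'
#' Excludes every subject with at least one medication row whose drug is
#' covered by the rule and whose dose exceeds the rule's limit.
#' Medication rows with a covered drug but missing dose cannot be judged;
#' they are skipped with a classed warning (the subject is kept unless
#' another row excludes it).
#'
#' @param manifest data frame with a `subject_id` column.
#' @param rule a rule from [rule_donepezil_gt5()] and friends.
#' @param medications long-format data frame (`subject_id`, `drug`,
#'   `dose_mg`); defaults to `attr(manifest, "medications")`.
#' @return The filtered manifest.
#' @export
subgroup_filter <- function(manifest, rule = rule_none(),
                            medications = attr(manifest, "medications")) {
  stopifnot(inherits(rule, "medication_rule"))
  if (length(rule$limits) == 0 || is.null(medications) ||
      nrow(medications) == 0)
    return(manifest)
  med <- medications[tolower(medications$drug) %in% names(rule$limits), ,
                     drop = FALSE]
  if (nrow(med) == 0) return(manifest)
  missing_dose <- is.na(med$dose_mg)
  if (any(missing_dose)) {
    dlb_warn("dlb_row_skipped_warning",
             sprintf("%d medication row(s) matched by the rule lack a dose and were skipped",
                     sum(missing_dose)))
    med <- med[!missing_dose, , drop = FALSE]
  }
  over <- med$dose_mg > rule$limits[tolower(med$drug)]
  excluded <- unique(med$subject_id[over])
  out <- manifest[!manifest$subject_id %in% excluded, , drop = FALSE]
  attr(out, "medications") <- medications
  out
}
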