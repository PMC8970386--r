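# Diagnostic metrics, exact intervals, AUC, Fisher test, power, and
# medication-subgroup filtering.

test_that("confusion table counts with DLB positive", {
  tab <- confusion(c("DLB", "DLB", "AD", "AD", "DLB"),
                   c("DLB", "AD", "AD", "DLB", "DLB"))
  expect_equal(tab$tp, 2)
  expect_equal(tab$fp, 1)
  expect_equal(tab$tn, 1)
  expect_equal(tab$fn, 1)
  expect_error(confusion("DLB", c("DLB", "AD")), class = "dlb_value_error")
  expect_error(confusion("MCI", "DLB"), class = "dlb_value_error")
})

test_that("Clopper-Pearson matches binom.test and handles the edges", {
  for (case in list(c(13, 18), c(31, 39), c(7, 11))) {
    ref <- binom.test(case[1], case[2])$conf.int
    expect_equal(unname(clopper_pearson(case[1], case[2])), 100 * ref,
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
  expect_equal(unname(clopper_pearson(0, 10)[1]), 0)
  expect_equal(unname(clopper_pearson(10, 10)[2]), 100)
  expect_error(clopper_pearson(5, 4), class = "dlb_value_error")
})

test_that("diagnostic metrics compute the three rates with CIs", {
  tab <- confusion(rep(c("DLB", "AD", "DLB", "AD"), c(13, 5, 3, 18)),
                   rep(c("DLB", "DLB", "AD", "AD"), c(13, 5, 3, 18)))
  met <- diagnostic_metrics(tab)
  expect_equal(met$sensitivity$estimate, 100 * 13 / 18)
  expect_equal(met$specificity$estimate, 100 * 18 / 21)
  expect_equal(met$accuracy$estimate, 100 * 31 / 39)
  txt <- format(met)
  expect_match(txt, "Sensitivity  72.2")
  expect_match(txt, "n \\(DLB, AD\\)  39 \\(18, 21\\)")
  lop <- confusion(rep("DLB", 3), rep("DLB", 3))
  expect_error(diagnostic_metrics(lop), class = "dlb_metrics_error")
})

test_that("ROC AUC equals the Mann-Whitney probability", {
  # DLB scores {3, 2}, AD scores {1, 2}: 3 wins + 1 tie of 4 pairs
  expect_equal(roc_auc(c(3, 2, 1, 2), c("DLB", "DLB", "AD", "AD")), 0.875)
  expect_equal(roc_auc(c(5, 5, 5, 5), c("DLB", "DLB", "AD", "AD")), 0.5)
  expect_equal(roc_auc(c(9, 8, 1, 2), c("DLB", "DLB", "AD", "AD")), 1)
  expect_equal(roc_auc(c(1, 2, 9, 8), c("DLB", "DLB", "AD", "AD")), 0)
  expect_error(roc_auc(1:3, rep("DLB", 3)), class = "dlb_value_error")
})

test_that("Fisher exact test wraps the conditional exact computation", {
  tab <- matrix(c(3, 3, 2, 10), 2)
  expect_equal(fisher_exact(tab), fisher.test(tab)$p.value)
  expect_equal(fisher_exact(matrix(c(10, 0, 0, 10), 2)),
               fisher.test(matrix(c(10, 0, 0, 10), 2))$p.value)
  expect_error(fisher_exact(matrix(c(1, -1, 2, 3), 2)),
               class = "dlb_value_error")
  expect_error(fisher_exact(matrix(c(0, 0, 2, 3), 2)),
               class = "dlb_value_error")
  expect_error(fisher_exact(matrix(1:6, 2)), class = "dlb_value_error")
})

test_that("binomial power uses the exact critical region", {
  bp <- binomial_power(39, p0 = 0.5, p1 = 0.8)
  # the critical count is the smallest k with P(X >= k | p0) <= alpha
  expect_lte(1 - pbinom(bp$critical - 1, 39, 0.5), 0.05)
  expect_gt(1 - pbinom(bp$critical - 2, 39, 0.5), 0.05)
  expect_equal(bp$power, 1 - pbinom(bp$critical - 1, 39, 0.8))
  expect_gt(bp$power, binomial_power(39, 0.5, 0.7)$power)
  expect_gt(binomial_power(80, 0.5, 0.7)$power,
            binomial_power(40, 0.5, 0.7)$power)
})

test_that("medication rules filter the manifest declaratively", {
  manifest <- data.frame(subject_id = paste0("s", 1:6),
                         diagnosis = rep(c("DLB", "AD"), 3))
  meds <- data.frame(
    subject_id = c("s1", "s2", "s2", "s3", "s4", "s5"),
    drug = c("donepezil", "donepezil", "rivastigmine", "Donepezil",
             "galantamine", "memantine"),
    dose_mg = c(10, 5, 12, NA, 8, 28))
  attr(manifest, "medications") <- meds

  expect_equal(subgroup_filter(manifest, rule_none()), manifest)

  # s1 over 5 mg donepezil; s3's dose is unknown -> warned, kept
  expect_warning(
    out <- subgroup_filter(manifest, rule_donepezil_gt5()),
    class = "dlb_row_skipped_warning")
  expect_setequal(out$subject_id, c("s2", "s3", "s4", "s5", "s6"))

  # half-max rule additionally drops s2 (rivastigmine 12 > 9); memantine
  # is not an AChEI and never excludes
  expect_warning(
    out2 <- subgroup_filter(manifest, rule_achei_half_max()),
    class = "dlb_row_skipped_warning")
  expect_setequal(out2$subject_id, c("s3", "s4", "s5", "s6"))

  # without a medication table the manifest passes through
  plain <- manifest
  attr(plain, "medications") <- NULL
  expect_equal(subgroup_filter(plain, rule_donepezil_gt5()), plain)
})
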