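fx <- reference_count_cohort()

test_that("analysis-set assembly applies the endpoint inclusion rules", {
  ms <- assemble_analysis_set(fx, "MS")
  expect_equal(nrow(ms), 242)  # CIS + RIS + inconclusive excluded
  expect_equal(sum(ms$label), 45)
  ocb <- assemble_analysis_set(fx, "OCB")
  expect_equal(nrow(ocb), 252)
  expect_equal(sum(ocb$label), 65)
  only_cis <- fx[fx$diagnosis == "CIS", ]
  expect_error(assemble_analysis_set(only_cis, "MS"), "degenerate")
  no_ocb <- fx
  no_ocb$ocb_bands[1] <- NA
  expect_error(assemble_analysis_set(no_ocb, "OCB"), "OCB result")
})

test_that("confusion matrices count the standard 2x2 cells", {
  expect_equal(unclass(confusion(c(TRUE, FALSE), c(TRUE, FALSE))),
               list(tp = 1L, fp = 0L, fn = 0L, tn = 1L),
               ignore_attr = TRUE)
  expect_equal(unclass(confusion(c(TRUE, TRUE, FALSE),
                                 c(FALSE, TRUE, TRUE))),
               list(tp = 1L, fp = 1L, fn = 1L, tn = 0L),
               ignore_attr = TRUE)
  ms <- assemble_analysis_set(fx, "MS")
  cm <- confusion(ms$label, ocb_positive(ms$ocb_bands))
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(40, 18, 5, 179))
  expect_error(confusion(c(TRUE, FALSE), TRUE), "equal length")
})

test_that("Wilson intervals match closed-form checks and prop.test", {
  expect_equal(round(wilson_interval(40, 45), 4),
               c(lower = 0.7650, upper = 0.9516))
  expect_equal(round(wilson_interval(42, 45), 4),
               c(lower = 0.8214, upper = 0.9771))
  # zero successes: lower bound is exactly 0
  expect_identical(wilson_interval(0, 45)[["lower"]], 0)
  expect_identical(wilson_interval(45, 45)[["upper"]], 1)
  for (case in list(c(3, 10), c(17, 45), c(100, 200), c(1, 8))) {
    pt <- suppressWarnings(
      prop.test(case[1], case[2], correct = FALSE))$conf.int
    expect_equal(unname(wilson_interval(case[1], case[2])),
                 as.numeric(pt), tolerance = 1e-10)
  }
  expect_error(wilson_interval(5, 4), "in \\[0, n\\]")
})

test_that("diagnostic metrics reproduce the OCB contingency column", {
  m <- diagnostic_metrics(list(tp = 40, fp = 18, fn = 5, tn = 179))
  expect_equal(round(m$sensitivity[["estimate"]], 4), 0.8889)
  expect_equal(round(m$specificity[["estimate"]], 4), 0.9086)
  expect_equal(round(m$ppv[["estimate"]], 4), 0.6897)
  expect_equal(round(m$npv[["estimate"]], 4), 0.9728)
  expect_equal(round(m$lr_pos, 3), 9.728)
  expect_equal(m$n, 242)
  # each point estimate sits inside its CI
  for (f in list(m$sensitivity, m$specificity, m$ppv, m$npv)) {
    expect_gte(f[["estimate"]], f[["lower"]])
    expect_lte(f[["estimate"]], f[["upper"]])
  }
  # 44/45 positives detected
  m2 <- diagnostic_metrics(list(tp = 44, fp = 27, fn = 1, tn = 170))
  expect_equal(round(m2$sensitivity[["estimate"]], 4), 0.9778)
})

test_that("degenerate confusion matrices are flagged, not silently zero", {
  perfect <- diagnostic_metrics(list(tp = 7, fp = 0, fn = 0, tn = 12))
  expect_equal(perfect$sensitivity[["estimate"]], 1)
  expect_equal(perfect$specificity[["estimate"]], 1)
  expect_identical(perfect$lr_pos, Inf)
  expect_true(perfect$lr_pos_infinite)
  never_pos <- diagnostic_metrics(list(tp = 0, fp = 0, fn = 3, tn = 12))
  expect_false(never_pos$ppv_defined)
  expect_true(is.na(never_pos$ppv[["estimate"]]))
  expect_error(diagnostic_metrics(list(tp = 1, fp = 0, fn = 1, tn = 0)),
               "condition-negative")
})

test_that("metric point estimates are invariant to row scaling", {
  base <- diagnostic_metrics(list(tp = 12, fp = 7, fn = 4, tn = 30))
  scaled <- diagnostic_metrics(list(tp = 36, fp = 21, fn = 12, tn = 90))
  for (f in c("sensitivity", "specificity", "ppv", "npv")) {
    expect_equal(scaled[[f]][["estimate"]], base[[f]][["estimate"]])
    # intervals shrink with more data
    expect_lt(scaled[[f]][["upper"]] - scaled[[f]][["lower"]],
              base[[f]][["upper"]] - base[[f]][["lower"]])
  }
})

test_that("ROC operating points use midpoint thresholds and '>' rule", {
  scores <- c(3, 5, 1, 4)
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  curve <- roc_curve(scores, labels)
  pts <- curve$points
  expect_equal(pts$threshold, c(0, 2, 3.5, 4.5, 6))
  row2 <- pts[pts$threshold == 2, ]
  expect_equal(c(row2$sensitivity, row2$specificity), c(1, 0.5))
  row45 <- pts[pts$threshold == 4.5, ]
  expect_equal(c(row45$sensitivity, row45$specificity), c(0.5, 1))
  # sentinels: everything-positive and everything-negative
  expect_equal(pts$sensitivity[1], 1)
  expect_equal(pts$specificity[1], 0)
  expect_equal(pts$sensitivity[nrow(pts)], 0)
  expect_equal(pts$specificity[nrow(pts)], 1)
  # complete separation contains a perfect operating point
  sep <- roc_curve(c(10, 9, 1, 2), c(TRUE, TRUE, FALSE, FALSE))$points
  expect_true(any(sep$sensitivity == 1 & sep$specificity == 1))
  # all scores identical: only the two sentinel points
  flat <- roc_curve(rep(2, 6), rep(c(TRUE, FALSE), 3))$points
  expect_equal(nrow(flat), 2)
  expect_equal(flat$sensitivity, c(1, 0))
  expect_equal(flat$specificity, c(0, 1))
  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "degenerate")
})

test_that("sensitivity is non-increasing along the threshold axis", {
  set.seed(7)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    scores <- sample(1:12, n, replace = TRUE)  # ties on purpose
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    pts <- roc_curve(scores, labels)$points
    expect_true(all(diff(pts$sensitivity) <= 0))
    expect_true(all(diff(pts$specificity) >= 0))
  }
})

test_that("AUC equals the tie-corrected pairwise statistic", {
  expect_equal(auc(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(auc(c(2, 2), c(TRUE, FALSE)), 0.5)
  expect_equal(auc(c(9, 8, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  set.seed(11)
  for (i in 1:50) {
    n <- sample(4:25, 1)
    scores <- sample(1:8, n, replace = TRUE)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    expect_equal(auc(scores, labels), brute_auc(scores, labels))
    # invariance under a strictly increasing transform
    expect_equal(auc(exp(scores / 3), labels), auc(scores, labels))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  for (i in 1:10) {
    scores <- c(rlnorm(30, 2, 1), rlnorm(40, 0, 1.2))
    labels <- rep(c(TRUE, FALSE), c(30, 40))
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores,
                                          direction = "<", quiet = TRUE)))
    expect_equal(auc(scores, labels), ref, tolerance = 1e-12)
  }
})

test_that("Youden cutoff selection favors sensitivity on ties", {
  curve <- roc_curve(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))
  best <- optimal_cutoff(curve)
  # J ties at 0.5 for thresholds 2 and 4.5; screening tie-break -> 2
  expect_equal(best$threshold, 2)
  expect_equal(best$sensitivity, 1)
  expect_equal(best$specificity, 0.5)
  sep <- roc_curve(c(10, 9, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(optimal_cutoff(sep)$youden, 1)
  flat <- roc_curve(rep(2, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(optimal_cutoff(flat)$sensitivity, 1)  # higher-sens sentinel
})

test_that("Mann-Whitney matches enumeration and handles ties", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3, tolerance = 1e-12)
  expect_identical(r$method, "exact")
  r2 <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r2$p, 0.1, tolerance = 1e-12)
  same <- mann_whitney(c(1, 2, 2, 5), c(1, 2, 2, 5))
  expect_equal(same$p, 1.0)
  expect_identical(same$method, "normal")
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
  set.seed(17)
  for (i in 1:20) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    v <- sample(1:1000, n1 + n2)  # distinct => exact branch
    x <- v[seq_len(n1)]
    y <- v[-seq_len(n1)]
    expect_equal(mann_whitney(x, y)$p, mw_enum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("exact and normal-approximation p agree closely at n = 6 + 6", {
  set.seed(19)
  for (i in 1:25) {
    v <- sample(1:10000, 12)
    x <- v[1:6]
    y <- v[7:12]
    p_exact <- mann_whitney(x, y)$p
    p_norm <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_lt(abs(p_exact - p_norm), 0.02)
  }
})
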