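#' Assemble an analysis set for a diagnostic endpoint
#'
#' Applies the cohort inclusion rules used for diagnostic-accuracy analysis.
#' For the MS endpoint, patients with CIS, RIS or an inconclusive final
#' diagnosis are excluded and the reference label is a final MS diagnosis.
#' For the OCB endpoint all patients are kept and the reference label is OCB
#' positivity (at least two CSF-exclusive bands), which requires an OCB
#' result for every record.
#'
#' @param cohort Cohort data frame with columns `diagnosis` (one of `"MS"`,
#'   `"CIS"`, `"RIS"`, `"INCONCLUSIVE"`, `"OTHER"`) and `ocb_bands`.
#' @param endpoint `"MS"` (MS vs. no MS) or `"OCB"` (OCB positive vs.
#'   negative).
#' @return The subset data frame with a logical column `label` appended.
#' @export
assemble_analysis_set <- function(cohort, endpoint = c("MS", "OCB")) {
  endpoint <- match.arg(toupper(endpoint), c("MS", "OCB"))
  allowed <- c("MS", "CIS", "RIS", "INCONCLUSIVE", "OTHER")
  if (!all(cohort$diagnosis %in% allowed)) {
    stop("diagnosis labels must be one of: ", paste(allowed, collapse = ", "))
  }
  if (endpoint == "MS") {
    out <- cohort[cohort$diagnosis %in% c("MS", "OTHER"), , drop = FALSE]
    out$label <- out$diagnosis == "MS"
  } else {
    if (anyNA(cohort$ocb_bands)) {
      stop(sum(is.na(cohort$ocb_bands)),
           " record(s) lack an OCB result; the OCB endpoint requires one ",
           "for every patient")
    }
    out <- cohort
    out$label <- ocb_positive(out$ocb_bands)
  }
  if (nrow(out) == 0L || !any(out$label) || all(out$label)) {
    stop("degenerate analysis set: both endpoint classes must be present")
  }
  rownames(out) <- NULL
  out
}

#' Two-by-two confusion matrix
#'
#' @param labels Logical reference labels (disease / condition present).
#' @param predictions Logical test results.
#' @return An object of class `confusion_matrix` with counts `tp`, `fp`,
#'   `fn`, `tn`.
#' @export
confusion <- function(labels, predictions) {
  labels <- as.logical(labels)
  predictions <- as.logical(predictions)
  if (length(labels) != length(predictions)) {
    stop("`labels` and `predictions` must have equal length")
  }
  if (length(labels) == 0L) stop("empty input")
  if (anyNA(labels) || anyNA(predictions)) {
    stop("missing values in labels or predictions; resolve or exclude them ",
         "before tabulating")
  }
  structure(list(
    tp = sum(labels & predictions),
    fp = sum(!labels & predictions),
    fn = sum(labels & !predictions),
    tn = sum(!labels & !predictions)
  ), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("test +", "test -"),
                              c("condition +", "condition -")))
  print(m)
  invisible(x)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Two-sided Wilson score interval without continuity correction. Vectorised
#' over `successes`.
#'
#' @param successes Number of successes (0..n).
#' @param n Number of trials, at least 1.
#' @param conf.level Confidence level in (0, 1); default 0.95.
#' @return A two-column matrix with columns `lower` and `upper`, one row per
#'   element of `successes` (dropped to a named vector for scalar input).
#' @examples
#' wilson_interval(40, 45)  # 0.7650 - 0.9516
#' @export
wilson_interval <- function(successes, n, conf.level = 0.95) {
  stopifnot(n >= 1, conf.level > 0, conf.level < 1)
  if (any(successes < 0) || any(successes > n) ||
      any(successes != round(successes))) {
    stop("`successes` must be integers in [0, n]")
  }
  z <- qnorm(1 - (1 - conf.level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  lower <- ifelse(successes == 0, 0, pmax(0, centre - half))
  upper <- ifelse(successes == n, 1, pmin(1, centre + half))
  out <- cbind(lower = lower, upper = upper)
  if (length(successes) == 1L) out[1L, ] else out
}

#' Diagnostic accuracy metrics with Wilson confidence intervals
#'
#' Sensitivity, specificity, predictive values and the positive likelihood
#' ratio from a 2x2 confusion matrix. Each proportion carries a Wilson score
#' interval computed on its own denominator. When specificity is exactly 1
#' the likelihood ratio is reported as `Inf` and flagged. A predictive value
#' whose denominator is zero is reported as `NA` and flagged, never silently
#' zero.
#'
#' @param cm A [confusion()] result, or a list with `tp`, `fp`, `fn`, `tn`.
#' @param conf.level Confidence level for the intervals; default 0.95.
#' @return An object of class `diagnostic_metrics`: for each of
#'   `sensitivity`, `specificity`, `ppv`, `npv` a numeric vector
#'   `(estimate, lower, upper)`; plus `lr_pos`, flags, counts and `n`.
#' @examples
#' diagnostic_metrics(confusion(rep(c(TRUE, FALSE), c(45, 197)),
#'                              rep(c(TRUE, FALSE, TRUE, FALSE),
#'                                  c(40, 5, 18, 179))))
#' @export
diagnostic_metrics <- function(cm, conf.level = 0.95) {
  counts <- c(tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  pos <- cm$tp + cm$fn
  neg <- cm$fp + cm$tn
  if (pos < 1L || neg < 1L) {
    stop("both condition-positive and condition-negative records are ",
         "required")
  }
  prop_ci <- function(x, d) {
    if (d == 0L) return(c(NA_real_, NA_real_, NA_real_))
    c(x / d, wilson_interval(x, d, conf.level))
  }
  sens <- prop_ci(cm$tp, pos)
  spec <- prop_ci(cm$tn, neg)
  ppv <- prop_ci(cm$tp, cm$tp + cm$fp)
  npv <- prop_ci(cm$tn, cm$tn + cm$fn)
  names(sens) <- names(spec) <- names(ppv) <- names(npv) <-
    c("estimate", "lower", "upper")
  spec_perfect <- spec[["estimate"]] == 1
  structure(list(
    sensitivity = sens, specificity = spec, ppv = ppv, npv = npv,
    lr_pos = if (isTRUE(spec_perfect)) Inf else
      sens[["estimate"]] / (1 - spec[["estimate"]]),
    lr_pos_infinite = isTRUE(spec_perfect),
    ppv_defined = cm$tp + cm$fp > 0L,
    npv_defined = cm$tn + cm$fn > 0L,
    cm = cm, conf.level = conf.level,
    n = pos + neg
  ), class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, digits = 4, ...) {
  fmt <- function(v) {
    if (anyNA(v)) return("undefined (zero denominator)")
    sprintf("%.*f (%.*f-%.*f)", digits, v[1], digits, v[2], digits, v[3])
  }
  cat("Diagnostic accuracy (n = ", x$n, ", ",
      format(100 * x$conf.level), "% Wilson CI)\n", sep = "")
  cat("  Sensitivity: ", fmt(x$sensitivity), "\n", sep = "")
  cat("  Specificity: ", fmt(x$specificity), "\n", sep = "")
  cat("  PPV:         ", fmt(x$ppv), "\n", sep = "")
  cat("  NPV:         ", fmt(x$npv), "\n", sep = "")
  cat("  LR+:         ",
      if (x$lr_pos_infinite) "Inf (specificity = 1)" else
        format(round(x$lr_pos, digits)), "\n", sep = "")
  invisible(x)
}

roc_validate <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  if (anyNA(scores) || anyNA(labels)) stop("missing scores or labels")
  if (!any(labels) || all(labels)) {
    stop("degenerate input: both classes must be present")
  }
  labels
}

#' Empirical ROC curve
#'
#' Operating points are computed with the positive-classification rule
#' `score > threshold`. Candidate thresholds are the midpoints between
#' adjacent distinct score values, plus one sentinel below the minimum
#' (everything positive) and one above the maximum (everything negative).
#'
#' @param scores Numeric marker values (higher = more disease-like).
#' @param labels Logical reference labels.
#' @return An object of class `kfl_roc`: a data frame `points` with columns
#'   `threshold`, `sensitivity`, `specificity`; the tie-corrected `auc`; and
#'   the class sizes.
#' @export
roc_curve <- function(scores, labels) {
  labels <- roc_validate(scores, labels)
  us <- sort(unique(scores))
  thr <- c(us[1L] - 1,
           if (length(us) > 1L) (us[-length(us)] + us[-1L]) / 2,
           us[length(us)] + 1)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  # counts of each class at each distinct score, then tail sums give the
  # "score > threshold" counts for thresholds in each gap
  pos_at <- vapply(us, function(u) sum(scores == u & labels), numeric(1))
  neg_at <- vapply(us, function(u) sum(scores == u & !labels), numeric(1))
  pos_gt <- c(n_pos, n_pos - cumsum(pos_at))
  neg_gt <- c(n_neg, n_neg - cumsum(neg_at))
  points <- data.frame(
    threshold = thr,
    sensitivity = pos_gt / n_pos,
    specificity = 1 - neg_gt / n_neg
  )
  structure(list(points = points, auc = auc(scores, labels),
                 n_pos = n_pos, n_neg = n_neg),
            class = "kfl_roc")
}

#' @export
print.kfl_roc <- function(x, ...) {
  cat("Empirical ROC curve: ", x$n_pos, " positives, ", x$n_neg,
      " negatives, ", nrow(x$points), " operating points\n", sep = "")
  cat("AUC (tie-corrected): ", format(round(x$auc, 4)), "\n", sep = "")
  invisible(x)
}

#' @export
plot.kfl_roc <- function(x, ...) {
  plot(1 - x$points$specificity, x$points$sensitivity, type = "s",
       xlab = "1 - specificity", ylab = "Sensitivity",
       xlim = c(0, 1), ylim = c(0, 1), ...)
  abline(0, 1, lty = 3)
  invisible(x)
}

#' Tie-corrected area under the ROC curve
#'
#' The probabilistic AUC: the mean over all (positive, negative) pairs of 1
#' if the positive scores higher, 0.5 on a tie, 0 otherwise; computed via
#' midranks as \eqn{U / (n_1 n_2)}.
#'
#' @inheritParams roc_curve
#' @return A value in \[0, 1\].
#' @examples
#' auc(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))  # 0.75
#' @export
auc <- function(scores, labels) {
  labels <- roc_validate(scores, labels)
  r <- rank(scores)
  n_pos <- sum(labels)
  u <- sum(r[labels]) - n_pos * (n_pos + 1) / 2
  u / (n_pos * sum(!labels))
}

#' Optimal ROC cutoff
#'
#' Selects the operating point maximising Youden's J = sensitivity +
#' specificity - 1. Ties are broken toward higher sensitivity (screening
#' intent), then toward the lower threshold.
#'
#' @param curve A [roc_curve()] object.
#' @param criterion Only `"youden"` is implemented.
#' @return Named list: `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
optimal_cutoff <- function(curve, criterion = c("youden")) {
  criterion <- match.arg(criterion)
  pts <- curve$points
  if (nrow(pts) == 0L) stop("empty ROC curve")
  j <- pts$sensitivity + pts$specificity - 1
  ord <- order(-j, -pts$sensitivity, pts$threshold)
  best <- pts[ord[1L], ]
  list(threshold = best$threshold, sensitivity = best$sensitivity,
       specificity = best$specificity, youden = j[ord[1L]])
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples with midrank tie handling.
#' The two-sided p-value is exact (full enumeration of the U distribution)
#' when the pooled sample size does not exceed `exact_max_n` and there are
#' no ties; otherwise the normal approximation with tie correction and
#' continuity correction is used. Computation is delegated to
#' [stats::wilcox.test()], whose exact branch evaluates the same enumeration
#' distribution.
#'
#' @param x,y Numeric samples, both non-empty.
#' @param exact_max_n Pooled-size limit for the exact branch; default 12.
#' @return List with the U statistic for `x` (`U`), the two-sided `p`, and
#'   the `method` used (`"exact"` or `"normal"`).
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, p = 1/3
#' @export
mann_whitney <- function(x, y, exact_max_n = 12) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be ",
                                               "non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= exact_max_n
  wt <- wilcox.test(x, y, exact = exact, correct = TRUE,
                    alternative = "two.sided")
  list(U = unname(wt$statistic), p = wt$p.value,
       method = if (exact) "exact" else "normal")
}
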