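#' Per-test cost and labor configuration
#'
#' Per-unit resources consumed by one oligoclonal-band (OCB) isoelectric
#' focusing test. There are no default rates: they are laboratory-specific
#' and must be configured.
#'
#' @param ocb_labor_hours_per_test Hours of hands-on labor per OCB test.
#' @param ocb_reagent_cost_per_test Reagent cost per OCB test (currency
#'   units).
#' @return A list of class `cost_config`.
#' @export
cost_config <- function(ocb_labor_hours_per_test,
                        ocb_reagent_cost_per_test) {
  stopifnot(is.numeric(ocb_labor_hours_per_test),
            ocb_labor_hours_per_test >= 0,
            is.numeric(ocb_reagent_cost_per_test),
            ocb_reagent_cost_per_test >= 0)
  structure(list(ocb_labor_hours_per_test = ocb_labor_hours_per_test,
                 ocb_reagent_cost_per_test = ocb_reagent_cost_per_test),
            class = "cost_config")
}

#' Resources saved by spared OCB tests
#'
#' @param spared_count Number of OCB tests not performed.
#' @param costs A [cost_config()].
#' @return Named numeric vector `c(hours, cost)`.
#' @export
strategy_savings <- function(spared_count, costs) {
  stopifnot(spared_count >= 0, inherits(costs, "cost_config"))
  c(hours = spared_count * costs$ocb_labor_hours_per_test,
    cost = spared_count * costs$ocb_reagent_cost_per_test)
}

#' Two-tier reflex screening decisions
#'
#' Applies the reflex algorithm for suspected MS to each patient. Tier 1:
#' CSF K-FLC below the limit of detection is reported as "no evidence of
#' intrathecal immunoglobulin synthesis" and OCB testing is spared. Tier 2:
#' detectable K-FLC with a K-Index at or below the screening cutoff also
#' stops, OCB spared. Only patients with a K-Index above the cutoff are
#' reflexed to OCB testing. Reduced strategies skip tier 2
#' (`"tier1_only"`) or reflex everybody (`"ocb_only"`).
#'
#' @param cohort Cohort data frame in the standard schema (see
#'   [read_cohort()]).
#' @param lod CSF K-FLC limit of detection (mg/dl); default 0.03.
#' @param cutoff K-Index screening cutoff; reflex only when the index is
#'   strictly greater. Default 3.045.
#' @param strategy One of `"tier1_plus_kindex"`, `"tier1_only"`,
#'   `"ocb_only"`.
#' @param imputation_value Surrogate for censored CSF K-FLC, see
#'   [impute_censored()].
#' @return Data frame with columns `id`, `tier` (`"TIER1_STOP"`,
#'   `"TIER2_STOP"`, `"REFLEX_OCB"`), `rationale`, `k_index`,
#'   `final_positive` (logical; `NA` = reflexed but OCB result pending).
#' @export
classify_patients <- function(cohort, lod = 0.03, cutoff = 3.045,
                              strategy = c("tier1_plus_kindex",
                                           "tier1_only", "ocb_only"),
                              imputation_value = 1e-4) {
  strategy <- match.arg(strategy)
  stopifnot(cutoff > 0, lod > 0)
  k <- add_kappa_index(cohort, lod = lod,
                       imputation_value = imputation_value)
  below <- !k$csf_detectable
  tier <- rep("REFLEX_OCB", nrow(k))
  if (strategy != "ocb_only") {
    tier[below] <- "TIER1_STOP"
  }
  if (strategy == "tier1_plus_kindex") {
    tier[!below & k$k_index <= cutoff] <- "TIER2_STOP"
  }
  ocb <- ocb_positive(cohort$ocb_bands)
  final_positive <- ifelse(tier == "REFLEX_OCB", ocb, FALSE)
  rationale <- c(
    TIER1_STOP = paste0("CSF K-FLC < ", lod, " mg/dl: no evidence of ",
                        "intrathecal immunoglobulin synthesis; OCB spared"),
    TIER2_STOP = paste0("K-Index <= ", cutoff, ": screen negative; ",
                        "OCB spared"),
    REFLEX_OCB = paste0("K-Index > ", cutoff,
                        ": reflexed to OCB testing")
  )[tier]
  if (strategy == "ocb_only") {
    rationale[tier == "REFLEX_OCB"] <- "OCB testing for every patient"
  }
  data.frame(id = cohort$id, tier = tier, rationale = unname(rationale),
             k_index = k$k_index, final_positive = final_positive)
}

#' Evaluate a reflex screening strategy on a cohort
#'
#' Runs [classify_patients()] over the full cohort, counts spared OCB tests
#' per tier, and scores the strategy as a diagnostic test for MS. Strategy
#' positive means "reflexed and OCB positive"; every tier-stopped patient is
#' strategy negative. Spared counts and fractions are computed on the whole
#' cohort, while the strategy confusion matrix and accuracy metrics use the
#' MS-endpoint analysis set (MS and OTHER diagnoses only, per
#' [assemble_analysis_set()]), matching routine reporting conventions for
#' this design. Reflexed patients without an OCB result are flagged pending
#' and excluded from the confusion matrix with a logged count.
#'
#' @inheritParams classify_patients
#' @param costs Optional [cost_config()]; when supplied, time and reagent
#'   savings for the spared tests are reported.
#' @param conf.level Confidence level for Wilson intervals.
#' @return An object of class `strategy_report`.
#' @export
evaluate_strategy <- function(cohort,
                              strategy = c("tier1_plus_kindex",
                                           "tier1_only", "ocb_only"),
                              lod = 0.03, cutoff = 3.045, costs = NULL,
                              conf.level = 0.95,
                              imputation_value = 1e-4) {
  strategy <- match.arg(strategy)
  if (nrow(cohort) == 0L) stop("empty cohort")
  decisions <- classify_patients(cohort, lod = lod, cutoff = cutoff,
                                 strategy = strategy,
                                 imputation_value = imputation_value)
  spared_tier1 <- sum(decisions$tier == "TIER1_STOP")
  spared_tier2 <- sum(decisions$tier == "TIER2_STOP")
  reflexed <- sum(decisions$tier == "REFLEX_OCB")
  n <- nrow(cohort)

  ms_idx <- cohort$diagnosis %in% c("MS", "OTHER")
  lab <- cohort$diagnosis[ms_idx] == "MS"
  pred <- decisions$final_positive[ms_idx]
  pending <- is.na(pred)
  n_pending <- sum(pending)
  cm <- confusion(lab[!pending], pred[!pending])
  metrics <- diagnostic_metrics(cm, conf.level = conf.level)

  savings <- if (!is.null(costs)) {
    strategy_savings(spared_tier1 + spared_tier2, costs)
  }
  structure(list(
    strategy = strategy, lod = lod, cutoff = cutoff,
    decisions = decisions,
    n = n, spared_tier1 = spared_tier1, spared_tier2 = spared_tier2,
    reflexed = reflexed,
    spared_fraction = (spared_tier1 + spared_tier2) / n,
    pending_ocb = n_pending,
    strategy_cm = cm, metrics = metrics,
    savings = savings, costs = costs
  ), class = "strategy_report")
}

#' @export
print.strategy_report <- function(x, digits = 4, ...) {
  cat("Reflex screening strategy: ", x$strategy,
      " (LOD ", x$lod, " mg/dl, K-Index cutoff ", x$cutoff, ")\n", sep = "")
  cat("  Cohort size:        ", x$n, "\n", sep = "")
  cat("  Spared at tier 1:   ", x$spared_tier1, "\n", sep = "")
  cat("  Spared at tier 2:   ", x$spared_tier2, "\n", sep = "")
  cat("  Reflexed to OCB:    ", x$reflexed,
      if (x$pending_ocb > 0) paste0(" (", x$pending_ocb,
                                    " pending OCB, excluded from metrics)"),
      "\n", sep = "")
  cat("  Spared fraction:    ",
      sprintf("%.1f%%", 100 * x$spared_fraction), "\n", sep = "")
  if (!is.null(x$savings)) {
    cat("  Savings:            ", format(round(x$savings[["hours"]], 2)),
        " h labor, ", format(round(x$savings[["cost"]], 2)),
        " reagent cost units\n", sep = "")
  }
  cat("Strategy as a test for MS (MS/OTHER subset):\n")
  print(x$metrics, digits = digits)
  invisible(x)
}

#' @export
summary.strategy_report <- function(object, ...) {
  c(n = object$n,
    spared_tier1 = object$spared_tier1,
    spared_tier2 = object$spared_tier2,
    reflexed = object$reflexed,
    spared_fraction = object$spared_fraction,
    pending_ocb = object$pending_ocb,
    sensitivity = object$metrics$sensitivity[["estimate"]],
    specificity = object$metrics$specificity[["estimate"]],
    ppv = object$metrics$ppv[["estimate"]],
    npv = object$metrics$npv[["estimate"]])
}
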