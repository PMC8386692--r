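#' Full diagnostic-accuracy evaluation of a cohort
#'
#' Scores the cohort's K-Index against two endpoints: the final MS diagnosis
#' (CIS/RIS/inconclusive excluded, n = MS + OTHER) and OCB status (all
#' patients). For the MS endpoint the OCB test itself is also scored as a
#' comparator classifier. Each configured K-Index cutoff is evaluated with
#' the rule "index > cutoff"; empirical ROC curves and tie-corrected AUCs
#' are computed per endpoint.
#'
#' @param cohort Cohort data frame in the standard schema.
#' @param cutoffs K-Index cutoffs to tabulate; defaults to the screening
#'   cutoff 3.045, the multicentric reference cutoff 6.6 and the
#'   specificity-oriented 12.58.
#' @param conf.level Confidence level for Wilson intervals.
#' @param lod,imputation_value Censoring parameters.
#' @return An object of class `kindex_evaluation`: per-endpoint lists of
#'   [diagnostic_metrics()] blocks (named `"OCB"` and `"K-Index >c"`),
#'   [roc_curve()] objects, and the settings used.
#' @export
evaluate_cohort <- function(cohort, cutoffs = c(3.045, 6.6, 12.58),
                            conf.level = 0.95, lod = 0.03,
                            imputation_value = 1e-4) {
  stopifnot(length(cutoffs) >= 1, all(cutoffs > 0))
  k <- add_kappa_index(cohort, lod = lod,
                       imputation_value = imputation_value)
  endpoints <- list()
  rocs <- list()
  for (ep in c("MS", "OCB")) {
    set <- assemble_analysis_set(k, ep)
    blocks <- list()
    if (ep == "MS") {
      if (anyNA(set$ocb_bands)) {
        stop("OCB comparator requires an OCB result for every MS-endpoint ",
             "record")
      }
      blocks[["OCB"]] <- diagnostic_metrics(
        confusion(set$label, ocb_positive(set$ocb_bands)),
        conf.level = conf.level)
    }
    for (cut in cutoffs) {
      blocks[[sprintf("K-Index >%g", cut)]] <- diagnostic_metrics(
        confusion(set$label, set$k_index > cut), conf.level = conf.level)
    }
    endpoints[[ep]] <- blocks
    rocs[[ep]] <- roc_curve(set$k_index, set$label)
  }
  structure(list(endpoints = endpoints, roc = rocs, cutoffs = cutoffs,
                 conf.level = conf.level, lod = lod,
                 imputation_value = imputation_value),
            class = "kindex_evaluation")
}

#' @export
print.kindex_evaluation <- function(x, digits = 4, ...) {
  fmt <- function(v) sprintf("%.*f (%.*f-%.*f)", digits, v[1],
                             digits, v[2], digits, v[3])
  for (ep in names(x$endpoints)) {
    cat("== Endpoint: ",
        if (ep == "MS") "MS diagnosis (CIS/RIS/inconclusive excluded)"
        else "OCB status (all patients)",
        " ==\n", sep = "")
    cat("AUC: ", format(round(x$roc[[ep]]$auc, digits)), "\n", sep = "")
    for (nm in names(x$endpoints[[ep]])) {
      b <- x$endpoints[[ep]][[nm]]
      cat(sprintf("%-14s sens %s  spec %s  PPV %s  NPV %s  LR+ %s  n=%d\n",
                  nm, fmt(b$sensitivity), fmt(b$specificity), fmt(b$ppv),
                  fmt(b$npv),
                  if (b$lr_pos_infinite) "Inf" else
                    format(round(b$lr_pos, 3)),
                  b$n))
    }
  }
  invisible(x)
}
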