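#' Resolve censored CSF K-FLC concentrations
#'
#' CSF kappa free light chain concentrations below the assay limit of
#' detection (LOD) are censored: the instrument reports no value. For
#' downstream quotients a small positive surrogate is substituted, reflecting
#' the clinical reading "no evidence of intrathecal immunoglobulin synthesis".
#' Values measured at or above the LOD pass through unchanged; the comparison
#' is strict, so a value exactly equal to the LOD counts as detectable.
#'
#' @param value Numeric vector of measured concentrations (mg/dl); `NA` where
#'   the assay reported none.
#' @param below_lod Logical vector flagging censored measurements.
#' @param lod Limit of detection in mg/dl (default 0.03, the CSF K-FLC limit
#'   of a turbidimetric Freelite assay).
#' @param imputation_value Surrogate concentration (mg/dl) substituted for
#'   censored measurements; default 0.0001, an empirical near-zero value.
#' @return Numeric vector of effective concentrations, all positive.
#' @examples
#' impute_censored(NA, below_lod = TRUE)          # 1e-04
#' impute_censored(0.07, below_lod = FALSE)       # unchanged
#' @export
impute_censored <- function(value, below_lod, lod = 0.03,
                            imputation_value = 1e-4) {
  stopifnot(is.numeric(lod), length(lod) == 1L, lod > 0,
            is.numeric(imputation_value), length(imputation_value) == 1L,
            imputation_value > 0)
  below_lod <- as.logical(below_lod)
  n <- max(length(value), length(below_lod))
  value <- rep_len(as.numeric(value), n)
  below_lod <- rep_len(below_lod, n)
  if (anyNA(below_lod)) {
    stop("`below_lod` must be TRUE or FALSE for every record")
  }
  bad <- !below_lod & is.na(value)
  if (any(bad)) {
    stop(sum(bad), " record(s) are flagged detectable but carry no measured ",
         "value; invalid record")
  }
  ifelse(below_lod, imputation_value, value)
}

#' Albumin quotient (Qalb)
#'
#' CSF albumin divided by serum albumin, a dimensionless proxy for blood-CSF
#' barrier permeability. Both inputs must be in the same units.
#'
#' @param csf_alb,serum_alb Positive concentrations (mg/dl).
#' @return Numeric vector `csf_alb / serum_alb`.
#' @examples
#' albumin_quotient(16, 4000)  # 0.004, a typical median in adults
#' @export
albumin_quotient <- function(csf_alb, serum_alb) {
  if (any(!is.finite(csf_alb)) || any(!is.finite(serum_alb)) ||
      any(csf_alb <= 0) || any(serum_alb <= 0)) {
    stop("albumin concentrations must be finite and positive")
  }
  if (any(serum_alb < csf_alb)) {
    warning("serum albumin below CSF albumin in ",
            sum(serum_alb < csf_alb),
            " record(s); physiologically implausible input")
  }
  csf_alb / serum_alb
}

#' Kappa index (K-Index) with censoring policy
#'
#' Computes, per patient, the albumin quotient, the kappa quotient and the
#' kappa index \eqn{(CSF\ K\textrm{-}FLC \times serum\ albumin) /
#' (serum\ K\textrm{-}FLC \times CSF\ albumin)}. Censored CSF K-FLC values
#' are first passed through [impute_censored()], so every record yields a
#' finite, positive index.
#'
#' @param csf_kflc CSF K-FLC concentration (mg/dl); `NA` allowed where
#'   `below_lod` is `TRUE`.
#' @param serum_kflc Serum K-FLC concentration (mg/dl), positive.
#' @param csf_alb,serum_alb Albumin concentrations (mg/dl), positive.
#' @param below_lod Logical; `TRUE` where CSF K-FLC was below the LOD.
#' @param lod,imputation_value Censoring parameters, see [impute_censored()].
#' @return A data frame with one row per record: `q_alb`, `q_kappa`,
#'   `k_index`, `csf_detectable` (logical), `imputed` (logical).
#' @examples
#' kappa_index(0.12, 1.5, 25, 4000)$k_index  # 12.8
#' @export
kappa_index <- function(csf_kflc, serum_kflc, csf_alb, serum_alb,
                        below_lod = FALSE, lod = 0.03,
                        imputation_value = 1e-4) {
  kflc_eff <- impute_censored(csf_kflc, below_lod, lod = lod,
                              imputation_value = imputation_value)
  if (any(!is.finite(serum_kflc)) || any(serum_kflc <= 0)) {
    stop("serum K-FLC must be finite and positive")
  }
  q_alb <- albumin_quotient(csf_alb, serum_alb)
  q_kappa <- kflc_eff / serum_kflc
  below <- rep_len(as.logical(below_lod), length(kflc_eff))
  data.frame(
    q_alb = q_alb,
    q_kappa = q_kappa,
    k_index = q_kappa / q_alb,
    csf_detectable = !below,
    imputed = below
  )
}

#' Append quotient and K-Index columns to a cohort table
#'
#' Convenience wrapper applying [kappa_index()] to a cohort in the standard
#' CSV schema (see [read_cohort()]); adds columns `q_alb`, `q_kappa`,
#' `k_index`, `csf_detectable` and `imputed`.
#'
#' @param cohort Cohort data frame with columns `serum_kflc_mg_dl`,
#'   `csf_kflc_mg_dl`, `csf_kflc_below_lod`, `serum_alb_mg_dl`,
#'   `csf_alb_mg_dl`.
#' @inheritParams kappa_index
#' @return The cohort with the derived columns appended.
#' @export
add_kappa_index <- function(cohort, lod = 0.03, imputation_value = 1e-4) {
  need <- c("serum_kflc_mg_dl", "csf_kflc_mg_dl", "csf_kflc_below_lod",
            "serum_alb_mg_dl", "csf_alb_mg_dl")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("cohort is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  res <- kappa_index(cohort$csf_kflc_mg_dl, cohort$serum_kflc_mg_dl,
                     cohort$csf_alb_mg_dl, cohort$serum_alb_mg_dl,
                     below_lod = cohort$csf_kflc_below_lod,
                     lod = lod, imputation_value = imputation_value)
  cbind(cohort, res)
}

#' Oligoclonal band positivity
#'
#' A CSF study is OCB-positive when at least two oligoclonal bands are
#' visible exclusively in the CSF sample.
#'
#' @param band_count Non-negative integer count of CSF-exclusive bands;
#'   `NA` where OCB testing was not performed.
#' @return Logical vector; `NA` propagates untested status.
#' @examples
#' ocb_positive(c(0, 1, 2, 7, NA))
#' @export
ocb_positive <- function(band_count) {
  if (any(band_count < 0, na.rm = TRUE)) {
    stop("band counts must be non-negative")
  }
  band_count >= 2
}

#' Hyperbolic upper reference limit for the kappa quotient
#'
#' Barrier-dependent reference curves relate the CSF/serum kappa quotient to
#' the albumin quotient through a hyperbolic function
#' \eqn{Q_{lim}(\kappa) = a\sqrt{Q_{alb}^2 + b^2} - c}; an intrathecal
#' kappa fraction is present when the observed kappa quotient exceeds
#' \eqn{Q_{lim}}. The constants (a, b, c) are assay- and study-specific and
#' must be supplied from a published reference curve; none are bundled.
#'
#' @param q_alb Albumin quotient(s), positive.
#' @param params Named list with elements `a`, `b`, `c`.
#' @return Numeric vector of upper-limit kappa quotients.
#' @examples
#' reiber_kflc_limit(4, params = list(a = 1, b = 3, c = 1))  # 4
#' @export
reiber_kflc_limit <- function(q_alb, params = NULL) {
  if (is.null(params) || !all(c("a", "b", "c") %in% names(params)) ||
      any(vapply(params[c("a", "b", "c")], function(p) !is.numeric(p) ||
                   length(p) != 1L || is.na(p), logical(1)))) {
    stop("hyperbolic reference constants `a`, `b`, `c` for the kappa ",
         "quotient limit must be supplied in `params`; they are ",
         "assay-specific published values and are not bundled")
  }
  if (any(q_alb <= 0)) stop("q_alb must be positive")
  params$a * sqrt(q_alb^2 + params$b^2) - params$c
}
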