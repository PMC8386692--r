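#' Synthetic cohort generator configuration
#'
#' Calibration of the synthetic suspected-MS cohort. Concentration-like
#' quantities are log-normal (strictly positive, heavy right tail, matching
#' the published median/min/max shape of routine CSF screening cohorts).
#' Defaults reproduce the study conditions this package models: 252
#' patients, MS prevalence 45/252, ~63.5% of CSF K-FLC below the 0.03 mg/dl
#' LOD, MS median CSF K-FLC 0.26 mg/dl, median albumin quotient 0.004, and
#' a median K-Index near 67 for MS versus ~0.026 (the imputation floor
#' divided by typical serum kappa and Qalb) for non-MS. Serum K-FLC median
#' 0.97 mg/dl is chosen so the configured medians of CSF K-FLC, Qalb and
#' K-Index are mutually consistent. MS, CIS and RIS share the "intrathecal
#' synthesis" CSF K-FLC distribution; OTHER and INCONCLUSIVE share the low
#' one.
#'
#' @param prevalence_ms,frac_cis,frac_ris,frac_inconclusive Diagnosis-class
#'   fractions; the remainder is OTHER.
#' @param csf_kflc_meanlog_ms,csf_kflc_sdlog_ms Log-normal parameters of CSF
#'   K-FLC (mg/dl) for the MS-like classes.
#' @param csf_kflc_meanlog_nonms,csf_kflc_sdlog_nonms Same for the non-MS
#'   classes.
#' @param serum_kflc_meanlog,serum_kflc_sdlog Serum K-FLC (mg/dl).
#' @param qalb_meanlog,qalb_sdlog Albumin quotient.
#' @param serum_alb_mean,serum_alb_sd Serum albumin (mg/dl), normal.
#' @param synth_intercept,synth_slope Logistic model of the latent
#'   intrathecal-synthesis indicator on log10(K-Index).
#' @param bands_min_synth,bands_rate_synth Band count given synthesis:
#'   `bands_min_synth + Poisson(bands_rate_synth)`.
#' @param false_band_rate Poisson rate of spurious bands without synthesis.
#' @param lod,imputation_value Censoring parameters.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(prevalence_ms = 45 / 252,
                          frac_cis = 1 / 252,
                          frac_ris = 2 / 252,
                          frac_inconclusive = 7 / 252,
                          csf_kflc_meanlog_ms = log(0.26),
                          csf_kflc_sdlog_ms = 1.05,
                          csf_kflc_meanlog_nonms = log(0.01),
                          csf_kflc_sdlog_nonms = 1.42,
                          serum_kflc_meanlog = log(0.97),
                          serum_kflc_sdlog = 0.45,
                          qalb_meanlog = log(0.004),
                          qalb_sdlog = 0.4,
                          serum_alb_mean = 4300,
                          serum_alb_sd = 300,
                          synth_intercept = -0.9,
                          synth_slope = 1.7,
                          bands_min_synth = 2,
                          bands_rate_synth = 3,
                          false_band_rate = 0.05,
                          lod = 0.03,
                          imputation_value = 1e-4) {
  cfg <- as.list(environment())
  fr <- c(prevalence_ms, frac_cis, frac_ris, frac_inconclusive)
  if (any(fr < 0) || sum(fr) > 1) {
    stop("class fractions must be non-negative and sum to at most 1")
  }
  if (any(c(csf_kflc_sdlog_ms, csf_kflc_sdlog_nonms, serum_kflc_sdlog,
            qalb_sdlog, serum_alb_sd) <= 0)) {
    stop("scale parameters must be positive")
  }
  stopifnot(lod > 0, imputation_value > 0, false_band_rate >= 0,
            bands_rate_synth >= 0, bands_min_synth >= 0)
  structure(cfg, class = "cohort_config")
}

empty_cohort <- function() {
  data.frame(id = character(), diagnosis = character(),
             serum_kflc_mg_dl = numeric(), csf_kflc_mg_dl = numeric(),
             csf_kflc_below_lod = logical(), serum_alb_mg_dl = numeric(),
             csf_alb_mg_dl = numeric(), ocb_bands = integer(),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic suspected-MS cohort
#'
#' Draws a cohort with the statistical structure of a routine CSF screening
#' population: diagnosis labels by class fractions; CSF K-FLC from
#' class-specific log-normals (mass below the LOD becomes censored); serum
#' K-FLC, albumin quotient and serum albumin from their distributions (CSF
#' albumin derived as Qalb x serum albumin); OCB band counts drawn
#' conditional on a latent intrathecal-synthesis indicator whose probability
#' increases with the (imputed) K-Index, so discordant OCB/K-Index cells
#' arise naturally. Deterministic for a fixed seed.
#'
#' @param n Number of patients.
#' @param config A [cohort_config()].
#' @param seed Optional integer seed; when supplied the RNG state is set.
#' @return Cohort data frame in the standard schema (see [read_cohort()]).
#' @export
generate_cohort <- function(n = 252, config = cohort_config(),
                            seed = NULL) {
  stopifnot(inherits(config, "cohort_config"), n >= 0,
            n == round(n))
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) return(empty_cohort())
  probs <- c(MS = config$prevalence_ms, CIS = config$frac_cis,
             RIS = config$frac_ris,
             INCONCLUSIVE = config$frac_inconclusive)
  probs <- c(probs, OTHER = 1 - sum(probs))
  diagnosis <- sample(names(probs), n, replace = TRUE, prob = probs)
  ms_like <- diagnosis %in% c("MS", "CIS", "RIS")
  csf_true <- rlnorm(n,
                     ifelse(ms_like, config$csf_kflc_meanlog_ms,
                            config$csf_kflc_meanlog_nonms),
                     ifelse(ms_like, config$csf_kflc_sdlog_ms,
                            config$csf_kflc_sdlog_nonms))
  below <- csf_true < config$lod
  serum_kflc <- rlnorm(n, config$serum_kflc_meanlog,
                       config$serum_kflc_sdlog)
  q_alb <- rlnorm(n, config$qalb_meanlog, config$qalb_sdlog)
  serum_alb <- pmax(rnorm(n, config$serum_alb_mean, config$serum_alb_sd),
                    1500)
  kflc_eff <- ifelse(below, config$imputation_value, csf_true)
  k_index <- kflc_eff / (serum_kflc * q_alb)
  p_synth <- plogis(config$synth_intercept +
                      config$synth_slope * log10(k_index))
  synth <- runif(n) < p_synth
  bands <- ifelse(synth,
                  config$bands_min_synth + rpois(n, config$bands_rate_synth),
                  rpois(n, config$false_band_rate))
  data.frame(
    id = sprintf("S%05d", seq_len(n)),
    diagnosis = diagnosis,
    serum_kflc_mg_dl = serum_kflc,
    csf_kflc_mg_dl = ifelse(below, NA_real_, csf_true),
    csf_kflc_below_lod = below,
    serum_alb_mg_dl = serum_alb,
    csf_alb_mg_dl = q_alb * serum_alb,
    ocb_bands = as.integer(bands),
    stringsAsFactors = FALSE
  )
}

#' Censored fraction implied by a generator configuration
#'
#' Closed-form mixture probability that a generated CSF K-FLC value falls
#' below the LOD, marginalised over the diagnosis classes.
#'
#' @param config A [cohort_config()].
#' @return A probability.
#' @export
implied_censored_fraction <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  w_ms_like <- config$prevalence_ms + config$frac_cis + config$frac_ris
  w_non <- 1 - w_ms_like
  p_ms <- stats::plnorm(config$lod, config$csf_kflc_meanlog_ms,
                        config$csf_kflc_sdlog_ms)
  p_non <- stats::plnorm(config$lod, config$csf_kflc_meanlog_nonms,
                         config$csf_kflc_sdlog_nonms)
  w_ms_like * p_ms + w_non * p_non
}

fixture_block <- function(n, diagnosis, k_index = NA_real_, bands = 0L,
                          censored = FALSE, serum_kflc = 1.25,
                          q_alb = 0.004, csf_kflc = NULL) {
  serum_alb <- 4200
  if (censored) {
    csf <- NA_real_
  } else if (!is.null(csf_kflc)) {
    csf <- csf_kflc
    q_alb <- csf / (k_index * serum_kflc)  # pin the printed K-Index exactly
  } else {
    csf <- k_index * serum_kflc * q_alb
    stopifnot(csf > 0.03)  # representative values must stay detectable
  }
  data.frame(
    diagnosis = rep(diagnosis, n),
    serum_kflc_mg_dl = rep(serum_kflc, n),
    csf_kflc_mg_dl = rep(csf, n),
    csf_kflc_below_lod = rep(censored, n),
    serum_alb_mg_dl = rep(serum_alb, n),
    csf_alb_mg_dl = rep(q_alb * serum_alb, n),
    ocb_bands = rep(as.integer(bands), n),
    stringsAsFactors = FALSE
  )
}

#' Deterministic cohort reconstructed from published patient-flow counts
#'
#' Builds a 252-patient cohort whose joint strata match, simultaneously,
#' every marginal count printed for a published routine-screening cohort of
#' patients with suspected MS: 45 MS / 1 CIS / 2 RIS / 7 inconclusive / 197
#' other diagnoses; 160 censored CSF K-FLC (157 other, 2 inconclusive, 1
#' MS); 92 detectable (62 OCB-positive, 30 OCB-negative); 65 OCB-positive
#' overall (40 MS, 2 RIS, 1 CIS, 4 inconclusive, 18 other), three of them
#' censored and none of those MS; 44 MS with K-Index > 3.045, 42 with
#' K-Index > 6.6, 41 with K-Index > 12.58; 27/25/19 non-MS false positives
#' at the three cutoffs; and 13 detectable patients with K-Index <= 3.045.
#'
#' Only the strata are published, not patient-level values, so numeric
#' entries are synthetic representative constants placed inside the correct
#' open interval of each stratum (three individually reported patients --
#' K-Index 3.26 with CSF K-FLC 0.12 mg/dl, K-Index 4.48 with 0.07 mg/dl,
#' and an inconclusive case at 8.49 -- are pinned to their reported values).
#' Analyses must rely on stratum membership only, never on the arbitrary
#' constants.
#'
#' @return Cohort data frame in the standard schema, 252 rows.
#' @export
reference_count_cohort <- function() {
  blocks <- list(
    # MS (45): 1 censored OCB-; 44 detectable, of which 41 > 12.58
    fixture_block(1, "MS", censored = TRUE, serum_kflc = 1.2),
    fixture_block(38, "MS", k_index = 80, bands = 4, serum_kflc = 1.2),
    fixture_block(3, "MS", k_index = 70, bands = 0, serum_kflc = 1.2),
    fixture_block(1, "MS", k_index = 9, bands = 4),
    fixture_block(1, "MS", k_index = 3.26, bands = 7, serum_kflc = 2.4,
                  csf_kflc = 0.12),
    fixture_block(1, "MS", k_index = 4.48, bands = 0, serum_kflc = 1.5,
                  csf_kflc = 0.07),
    # CIS (1) and RIS (2): detectable, OCB+, very high K-Index
    fixture_block(1, "CIS", k_index = 90, bands = 4, serum_kflc = 1.2),
    fixture_block(2, "RIS", k_index = 90, bands = 4, serum_kflc = 1.2),
    # Inconclusive (7): 2 censored OCB-; 4 very high OCB+; one at 8.49 OCB-
    fixture_block(2, "INCONCLUSIVE", censored = TRUE, serum_kflc = 1.2),
    fixture_block(4, "INCONCLUSIVE", k_index = 75, bands = 4,
                  serum_kflc = 1.2),
    fixture_block(1, "INCONCLUSIVE", k_index = 8.49, bands = 0),
    # Other (197): 157 censored (3 OCB+); 40 detectable in strata
    fixture_block(3, "OTHER", censored = TRUE, bands = 2,
                  serum_kflc = 1.2),
    fixture_block(154, "OTHER", censored = TRUE, serum_kflc = 1.2),
    fixture_block(13, "OTHER", k_index = 60, bands = 4, serum_kflc = 1.2),
    fixture_block(6, "OTHER", k_index = 30, bands = 0, serum_kflc = 1.2),
    fixture_block(6, "OTHER", k_index = 9, bands = 0),
    fixture_block(1, "OTHER", k_index = 4.5, bands = 4, serum_kflc = 1.8,
                  q_alb = 0.005),
    fixture_block(1, "OTHER", k_index = 4.5, bands = 0, serum_kflc = 1.8,
                  q_alb = 0.005),
    fixture_block(1, "OTHER", k_index = 2, bands = 2, serum_kflc = 2.5,
                  q_alb = 0.0065),
    fixture_block(12, "OTHER", k_index = 2, bands = 0, serum_kflc = 2.5,
                  q_alb = 0.0065)
  )
  out <- do.call(rbind, blocks)
  out <- cbind(id = sprintf("P%03d", seq_len(nrow(out))), out,
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Cohort calibration summary
#'
#' Per-group medians and ranges of CSF K-FLC (on the imputed scale) and
#' K-Index, censored fraction and diagnosis counts -- the descriptive shape
#' routinely reported for CSF screening cohorts. Groups: all patients, MS,
#' no-MS (OTHER diagnoses), OCB-positive and OCB-negative.
#'
#' @param cohort Cohort data frame in the standard schema.
#' @param lod,imputation_value Censoring parameters.
#' @return List with elements `groups` (data frame of per-group summaries),
#'   `censored_n`, `censored_fraction`, and `diagnosis_counts`.
#' @export
calibration_summary <- function(cohort, lod = 0.03,
                                imputation_value = 1e-4) {
  if (nrow(cohort) == 0L) stop("empty cohort")
  k <- add_kappa_index(cohort, lod = lod,
                       imputation_value = imputation_value)
  kflc_eff <- impute_censored(k$csf_kflc_mg_dl, k$csf_kflc_below_lod,
                              lod = lod,
                              imputation_value = imputation_value)
  ocb <- ocb_positive(k$ocb_bands)
  groups <- list(
    all = rep(TRUE, nrow(k)),
    MS = k$diagnosis == "MS",
    no_MS = k$diagnosis == "OTHER",
    OCB_pos = !is.na(ocb) & ocb,
    OCB_neg = !is.na(ocb) & !ocb
  )
  summarise <- function(sel) {
    if (!any(sel)) {
      return(data.frame(n = 0L, kflc_median = NA_real_, kflc_min = NA_real_,
                        kflc_max = NA_real_, kindex_median = NA_real_,
                        kindex_min = NA_real_, kindex_max = NA_real_))
    }
    data.frame(n = sum(sel),
               kflc_median = median(kflc_eff[sel]),
               kflc_min = min(kflc_eff[sel]),
               kflc_max = max(kflc_eff[sel]),
               kindex_median = median(k$k_index[sel]),
               kindex_min = min(k$k_index[sel]),
               kindex_max = max(k$k_index[sel]))
  }
  tab <- do.call(rbind, lapply(groups, summarise))
  tab <- cbind(group = names(groups), tab, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(groups = tab,
       censored_n = sum(k$csf_kflc_below_lod),
       censored_fraction = mean(k$csf_kflc_below_lod),
       diagnosis_counts = table(factor(k$diagnosis,
                                       levels = c("MS", "CIS", "RIS",
                                                  "INCONCLUSIVE",
                                                  "OTHER"))))
}
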