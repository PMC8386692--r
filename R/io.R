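cohort_columns <- c("id", "diagnosis", "serum_kflc_mg_dl",
                    "csf_kflc_mg_dl", "csf_kflc_below_lod",
                    "serum_alb_mg_dl", "csf_alb_mg_dl", "ocb_bands")

validation_stop <- function(errors) {
  stop(errorCondition(
    paste0("cohort validation failed:\n",
           paste0("  ", errors, collapse = "\n")),
    class = c("cohort_validation_error", "error")))
}

parse_num <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  out[!is.na(x) & trimws(x) == ""] <- NA_real_
  out
}

#' Read a cohort CSV
#'
#' Reads the standard one-row-per-patient schema: `id`, `diagnosis`,
#' `serum_kflc_mg_dl`, `csf_kflc_mg_dl` (empty when below the LOD),
#' `csf_kflc_below_lod` (true/false), `serum_alb_mg_dl`, `csf_alb_mg_dl`,
#' `ocb_bands` (empty when OCB untested). All concentrations are mg/dl with
#' decimal point; no unit conversion is attempted. Row-level problems are
#' collected with their file line numbers and raised together as a
#' `cohort_validation_error`. The below-LOD invariant is enforced: a flagged
#' row must have an empty value or one strictly below the LOD.
#'
#' @param path Path to the CSV file (header row mandatory, UTF-8).
#' @param lod Limit of detection used for the consistency check.
#' @return Cohort data frame.
#' @export
read_cohort <- function(path, lod = 0.03) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, colClasses = "character", na.strings = NULL,
                  fileEncoding = "UTF-8")
  miss <- setdiff(cohort_columns, names(raw))
  if (length(miss)) {
    validation_stop(paste0("missing required column(s): ",
                           paste(miss, collapse = ", ")))
  }
  n <- nrow(raw)
  line <- seq_len(n) + 1L  # header is line 1
  errors <- character()
  add_err <- function(bad, msg) {
    if (any(bad)) {
      errors <<- c(errors,
                   paste0("line ", line[bad], ": ", msg))
    }
  }
  allowed <- c("MS", "CIS", "RIS", "INCONCLUSIVE", "OTHER")
  add_err(!(raw$diagnosis %in% allowed),
          paste0("diagnosis must be one of ",
                 paste(allowed, collapse = "/")))
  num_col <- function(col, allow_empty = FALSE) {
    x <- raw[[col]]
    v <- parse_num(x)
    bad <- is.na(v) & trimws(x) != ""
    add_err(bad, paste0("non-numeric value in ", col))
    if (!allow_empty) add_err(trimws(x) == "", paste0("empty ", col))
    v
  }
  serum_kflc <- num_col("serum_kflc_mg_dl")
  csf_kflc <- num_col("csf_kflc_mg_dl", allow_empty = TRUE)
  serum_alb <- num_col("serum_alb_mg_dl")
  csf_alb <- num_col("csf_alb_mg_dl")
  below_raw <- tolower(trimws(raw$csf_kflc_below_lod))
  bad_flag <- !(below_raw %in% c("true", "false"))
  add_err(bad_flag, "csf_kflc_below_lod must be true or false")
  below <- below_raw == "true"
  bands_raw <- trimws(raw$ocb_bands)
  bands <- parse_num(raw$ocb_bands)
  add_err(bands_raw != "" &
            (is.na(bands) | bands < 0 | bands != round(bands)),
          "ocb_bands must be empty or a non-negative integer")
  add_err(!bad_flag & below & !is.na(csf_kflc) & csf_kflc >= lod,
          paste0("csf_kflc_below_lod is true but csf_kflc_mg_dl >= ", lod))
  add_err(!bad_flag & !below & is.na(csf_kflc),
          "csf_kflc_below_lod is false but csf_kflc_mg_dl is empty")
  pos <- function(v, col) add_err(!is.na(v) & v <= 0,
                                  paste0(col, " must be positive"))
  pos(serum_kflc, "serum_kflc_mg_dl")
  pos(csf_kflc, "csf_kflc_mg_dl")
  pos(serum_alb, "serum_alb_mg_dl")
  pos(csf_alb, "csf_alb_mg_dl")
  if (length(errors)) validation_stop(errors)
  if (any(serum_alb < csf_alb)) {
    warning("serum albumin below CSF albumin in ",
            sum(serum_alb < csf_alb), " row(s); check the input")
  }
  data.frame(id = raw$id, diagnosis = raw$diagnosis,
             serum_kflc_mg_dl = serum_kflc, csf_kflc_mg_dl = csf_kflc,
             csf_kflc_below_lod = below, serum_alb_mg_dl = serum_alb,
             csf_alb_mg_dl = csf_alb,
             ocb_bands = ifelse(bands_raw == "", NA_integer_,
                                as.integer(bands)),
             stringsAsFactors = FALSE)
}

#' Write a cohort CSV
#'
#' Inverse of [read_cohort()]: censoring flags are written as `true`/`false`
#' and missing values as empty cells, so a round trip is lossless.
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort[, cohort_columns]
  out$csf_kflc_below_lod <- ifelse(out$csf_kflc_below_lod, "true", "false")
  write.csv(out, path, row.names = FALSE, na = "", quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Run configuration
#'
#' Central configuration for the analysis pipeline, defaulting to the
#' routine screening constants: LOD 0.03 mg/dl, imputation value 0.0001
#' mg/dl, screening K-Index cutoff 3.045 (with 6.6 and 12.58 also
#' tabulated), 95% confidence. All values can be overridden here or from a
#' YAML file via [load_run_config()].
#'
#' @param lod,imputation_value Censoring parameters (mg/dl).
#' @param kindex_cutoff Screening cutoff used by the reflex algorithm.
#' @param cutoffs Cutoffs tabulated by [evaluate_cohort()].
#' @param confidence Confidence level for Wilson intervals.
#' @param ocb_labor_hours_per_test,ocb_reagent_cost_per_test Optional cost
#'   model rates; both must be supplied to enable savings reporting.
#' @param seed Optional integer seed for simulation subcommands.
#' @return A list of class `run_config`.
#' @export
run_config <- function(lod = 0.03, imputation_value = 1e-4,
                       kindex_cutoff = 3.045,
                       cutoffs = c(3.045, 6.6, 12.58),
                       confidence = 0.95,
                       ocb_labor_hours_per_test = NULL,
                       ocb_reagent_cost_per_test = NULL,
                       seed = NULL) {
  stopifnot(lod > 0, imputation_value > 0, kindex_cutoff > 0,
            all(cutoffs > 0), confidence > 0, confidence < 1)
  structure(list(lod = lod, imputation_value = imputation_value,
                 kindex_cutoff = kindex_cutoff, cutoffs = cutoffs,
                 confidence = confidence,
                 ocb_labor_hours_per_test = ocb_labor_hours_per_test,
                 ocb_reagent_cost_per_test = ocb_reagent_cost_per_test,
                 seed = seed),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Flat key-value YAML; keys are the arguments of [run_config()]. Unknown
#' keys are rejected.
#'
#' @param path Path to the YAML file.
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  do.call(run_config, vals)
}

cost_config_from <- function(config) {
  if (is.null(config$ocb_labor_hours_per_test) ||
      is.null(config$ocb_reagent_cost_per_test)) return(NULL)
  cost_config(config$ocb_labor_hours_per_test,
              config$ocb_reagent_cost_per_test)
}

round4 <- function(x) {
  if (is.numeric(x)) round(x, 4) else x
}

metrics_block <- function(m) {
  tri <- function(v) list(estimate = round4(v[["estimate"]]),
                          ci_low = round4(v[["lower"]]),
                          ci_high = round4(v[["upper"]]))
  list(sensitivity = tri(m$sensitivity), specificity = tri(m$specificity),
       ppv = tri(m$ppv), npv = tri(m$npv),
       lr_pos = if (m$lr_pos_infinite) "Inf" else round4(m$lr_pos),
       tp = m$cm$tp, fp = m$cm$fp, fn = m$cm$fn, tn = m$cm$tn,
       n = m$n)
}

#' Emit a JSON evaluation report
#'
#' Writes a JSON document mirroring the per-classifier contingency-table
#' layout (point estimates, Wilson CIs and n per block, rendered to 4
#' decimals), optionally a tidy CSV of ROC operating points as a sidecar,
#' and run metadata (configuration echo, seed, package version).
#'
#' @param results A [evaluate_cohort()] and/or [evaluate_strategy()] result;
#'   a list containing either or both under names `evaluation` and
#'   `strategy` is also accepted.
#' @param path Output JSON path.
#' @param roc_csv Optional path for the ROC operating-point CSV sidecar
#'   (columns: endpoint, threshold, sensitivity, specificity).
#' @param config Optional [run_config()] echoed into the metadata.
#' @return `path`, invisibly.
#' @export
emit_report <- function(results, path, roc_csv = NULL, config = NULL) {
  if (inherits(results, "kindex_evaluation")) {
    results <- list(evaluation = results)
  } else if (inherits(results, "strategy_report")) {
    results <- list(strategy = results)
  }
  doc <- list(metadata = list(
    package = "kappascreen",
    version = as.character(packageVersion("kappascreen")),
    config = if (!is.null(config)) unclass(config),
    seed = if (!is.null(config)) config$seed
  ))
  ev <- results$evaluation
  if (!is.null(ev)) {
    doc$endpoints <- lapply(ev$endpoints, function(blocks) {
      lapply(blocks, metrics_block)
    })
    doc$auc <- lapply(ev$roc, function(r) round4(r$auc))
    if (!is.null(roc_csv)) {
      pts <- do.call(rbind, lapply(names(ev$roc), function(ep) {
        cbind(endpoint = ep, ev$roc[[ep]]$points)
      }))
      write.csv(pts, roc_csv, row.names = FALSE, quote = FALSE)
    }
  }
  st <- results$strategy
  if (!is.null(st)) {
    doc$strategy <- list(
      strategy = st$strategy, lod = st$lod, cutoff = st$cutoff,
      n = st$n, spared_tier1 = st$spared_tier1,
      spared_tier2 = st$spared_tier2, reflexed = st$reflexed,
      spared_fraction = round4(st$spared_fraction),
      pending_ocb = st$pending_ocb,
      metrics = metrics_block(st$metrics),
      savings = if (!is.null(st$savings)) as.list(round4(st$savings)),
      cost_rates = if (!is.null(st$costs)) unclass(st$costs)
    )
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
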