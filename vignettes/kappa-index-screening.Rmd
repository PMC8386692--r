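---
title: "Kappa index screening for suspected multiple sclerosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kappa index screening for suspected multiple sclerosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kappascreen)
```

## The problem

Intrathecal immunoglobulin synthesis is the laboratory hallmark of multiple
sclerosis (MS). The reference method, oligoclonal band (OCB) detection by
isoelectric focusing, is labor-intensive, slow and partly subjective.
Kappa free light chains (K-FLC) measured by turbidimetry in paired serum and
CSF samples offer an automated, quantitative alternative. This package
implements the full analysis pipeline for evaluating K-FLC-based screening in
a routine cohort of patients with suspected MS: the kappa index with its
detection-limit censoring policy, diagnostic-accuracy statistics, and a
two-tier reflex algorithm that decides when OCB testing can be spared.

## The kappa index model

For each patient, with all concentrations in mg/dl:

$$Q_{alb} = \frac{\mathrm{CSF\ albumin}}{\mathrm{serum\ albumin}}, \qquad
  Q_{\kappa} = \frac{\mathrm{CSF\ K\text{-}FLC}}{\mathrm{serum\ K\text{-}FLC}}, \qquad
  \mathrm{K\text{-}Index} = \frac{Q_{\kappa}}{Q_{alb}}.$$

Dividing the kappa quotient by the albumin quotient corrects, linearly, for
blood--CSF barrier permeability: a leaky barrier raises CSF concentrations of
*all* serum proteins, and albumin — synthesised only peripherally — measures
that leak. The index is dimensionless and scale-invariant: multiplying both
albumin values, or both kappa values, by any positive constant leaves it
unchanged (a property the test suite checks on random inputs).

### Censoring at the detection limit

CSF K-FLC is frequently below the assay's limit of detection
(LOD, default 0.03 mg/dl — the CSF limit of a turbidimetric Freelite assay);
in a routine suspected-MS population this affects roughly two thirds of
samples. `impute_censored()` substitutes an empirical near-zero value,
0.0001 mg/dl, for censored measurements. Two details matter:

* The comparison is **strict**: a value measured exactly at the LOD is
  detectable and passes through unchanged.
* The substitution can never create a screen positive. With any plausible
  serum kappa (0.5--3 mg/dl) and albumin quotient (0.002--0.01), the imputed
  index stays below 0.11 — two orders of magnitude under the lowest cutoff
  in use (3.045). The test suite asserts this over a parameter grid.

Imputed records carry an `imputed` flag so reports can count them.

### The hyperbolic reference curve

`reiber_kflc_limit()` evaluates the non-linear barrier-dependent upper
reference limit $Q_{lim}(\kappa) = a\sqrt{Q_{alb}^2 + b^2} - c$; an
intrathecal kappa fraction is present when $Q_\kappa$ exceeds it. The
constants are assay- and study-specific published values; the function
deliberately has **no defaults** and errors with a message naming the
missing constants, because shipping silently wrong constants would be worse
than requiring explicit configuration.

## Diagnostic-accuracy statistics

`evaluate_cohort()` scores the index against two endpoints. For the MS
endpoint, patients with CIS, RIS or an inconclusive final diagnosis are
excluded (they are neither MS nor clean controls); the OCB endpoint keeps
everyone. Choices that were genuinely open, and how they were resolved:

* **Confidence intervals**: Wilson score, two-sided, *without* continuity
  correction. This reproduces published contingency tables for this design
  to four decimals (e.g. 40/45 → 0.7650--0.9516; 42/45 → 0.8214--0.9771),
  which identifies the method even where reports do not name it. One known
  divergence: some commercial software uses the Wilson/Brown hybrid, which
  special-cases proportions within one or two successes of the boundary, so
  printed upper bounds for proportions like 44/45 can differ from plain
  Wilson by a few thousandths near 1. Plain Wilson is kept for coherence;
  its 95% coverage at n = 45 stays within [0.92, 0.98] across p = 0.1, 0.5,
  0.9 (checked by simulation).
* **ROC conventions**: positives are `score > threshold` (matching the
  ">3.045" style of clinical cutoff statements); candidate thresholds are
  midpoints between adjacent distinct scores plus a sentinel on each side.
  The AUC is the tie-corrected rank statistic $U/(n_1 n_2)$, i.e. the
  probability that a random positive outscores a random negative, ties
  counting one half — identical to the trapezoidal area under the empirical
  curve.
* **Optimal cutoff**: Youden's $J$ = sensitivity + specificity − 1, the
  standard reading of "best combination of sensitivity and specificity".
  Ties are broken toward **higher sensitivity** (this is a screening test;
  a missed MS case costs more than a spared OCB test gained), then toward
  the lower threshold.
* **Likelihood ratio** at specificity 1 is reported as `Inf` with a flag,
  and a predictive value with an empty denominator as `NA` with a flag —
  never silently zero.
* **Mann--Whitney**: exact p by enumeration when the pooled sample has at
  most 12 observations and no ties (the exact branch exists mainly so the
  implementation can be validated against full enumeration); otherwise the
  normal approximation with midrank tie correction and continuity
  correction, which is the only regime relevant at cohort sizes.

## The reflex screening algorithm

`evaluate_strategy()` implements the two-tier algorithm:

1. **Tier 1** — CSF K-FLC below the LOD: report "no evidence of intrathecal
   immunoglobulin synthesis", spare the OCB test.
2. **Tier 2** — detectable K-FLC but K-Index ≤ cutoff (default 3.045):
   screen negative, spare the OCB test. The stop rule is "≤" so that
   "higher than the cutoff" — and only that — triggers reflex.
3. **Reflex** — K-Index above the cutoff: perform OCB; the strategy's final
   result is the OCB result.

Two conventions deserve a note because they interact:

* Spared-test counts and fractions are computed on the **whole cohort**
  (every patient whose OCB would have been skipped), while the strategy's
  confusion matrix and accuracy metrics are computed on the **MS-endpoint
  subset** (MS and OTHER diagnoses only). This mixed convention is how such
  strategies are reported in practice — savings are operational, accuracy
  is diagnostic — and both sets of published figures for this design
  (≈68.7% spared; tier-1-only specificity 0.9239, PPV 72.73%, NPV 97.33%)
  are reproduced only under it.
* Reflexed patients lacking an OCB result are counted as **pending** and
  excluded from the confusion matrix with a logged count; imputing them in
  either direction would manufacture accuracy.

The cost model is linear: spared tests × configured per-test labor hours
and reagent cost. There are deliberately no default rates — they are
laboratory-specific, and published aggregate figures for this design imply
mutually inconsistent per-test rates, so `cost_config()` requires explicit
values and reports echo them.

## The synthetic cohort generator

`generate_cohort()` emulates a routine suspected-MS screening population so
the pipeline can be exercised, calibrated and property-tested without
patient data. Structure and defaults:

| Quantity | Distribution | Default | Rationale |
|---|---|---|---|
| diagnosis | categorical | MS 45/252, CIS 1/252, RIS 2/252, inconclusive 7/252 | routine-cohort class mix |
| CSF K-FLC, MS/CIS/RIS | log-normal | median 0.26 mg/dl, sdlog 1.05 | published MS median; sdlog puts ~2% below the LOD (1 MS of 45) |
| CSF K-FLC, other/inconclusive | log-normal | median 0.01 mg/dl, sdlog 1.42 | ~78% below LOD, giving ~63.5% censored overall (160/252) |
| serum K-FLC | log-normal | median 0.97 mg/dl, sdlog 0.45 | within the adult reference interval; chosen so the medians of CSF K-FLC, Q~alb~ and K-Index are mutually consistent (0.26/(0.97×0.004) ≈ 67) |
| albumin quotient | log-normal | median 0.004, sdlog 0.4 | published median; sdlog covers the reported min--max at ≈3 sd |
| serum albumin | normal | 4300 ± 300 mg/dl | adult reference range |
| OCB bands | latent-synthesis model | logistic(−0.9 + 1.7·log₁₀ K-Index); 2 + Poisson(3) bands given synthesis, Poisson(0.05) otherwise | couples OCB to the index through a shared latent cause, so discordant cells (OCB⁺ with censored K-FLC, OCB⁻ with high index) occur at realistic rates |

Medians of ratios of independent log-normals are ratios of medians, which is
what makes the calibration exactly solvable from published group medians.
The generator is deterministic for a fixed seed, and a closed-form
`implied_censored_fraction()` gives the mixture probability the censored
fraction must recover (a property the suite tests at n = 20,000 within
three binomial standard errors, alongside an AUC recovery check against a
Monte-Carlo oracle drawn directly from the configured distributions with
ten-fold samples).

What the generator does **not** emulate: measurement error of the
turbidimetric assay, correlation between serum K-FLC and barrier function,
longitudinal CIS→MS conversion, and laboratory batch effects. Passing tests
on synthetic cohorts therefore demonstrate the *statistical machinery* is
correct under the declared data-generating process, not that the published
accuracy transfers to any particular real population — population AUCs and
group medians depend on patient-level data no desk analysis can recover.

## The count-reconstructed cohort

`reference_count_cohort()` builds a deterministic 252-patient cohort whose
joint strata satisfy, simultaneously, every marginal count published for a
routine-screening cohort of this design: the 45/1/2/7/197 diagnosis split,
the 160-patient censored stratum (157 other, 2 inconclusive, 1 MS), the OCB
margins (65 positive: 40 MS, 2 RIS, 1 CIS, 4 inconclusive, 18 other; 3
positives censored, none MS), and the K-Index cutoff strata at 3.045, 6.6
and 12.58 for both endpoints. Some cells are not printed anywhere and were
back-derived as the unique solution consistent with all printed
sensitivities and specificities at once (e.g. 41 MS above 12.58; the
19/6/2/13 split of detectable non-MS across cutoff bands). Two published
count statements for this design contradict each other (3 vs. 13 non-MS
OCB-positive patients above 6.6); only 13 is consistent with the printed
OCB-endpoint columns, and the fixture uses it. Similarly, the censored
fraction 160/252 = 63.49% appears rounded both to 63.4% and 63.8% in
different places; the fixture uses the count.

Within a stratum, numeric values are **synthetic representative constants**
placed inside the correct open interval (three individually reported
patients — K-Index 3.26 with CSF K-FLC 0.12 mg/dl, 4.48 with 0.07 mg/dl,
and an inconclusive case at 8.49 — are pinned exactly). Analyses must rely
on stratum membership only; any result that would change if a
representative constant moved within its interval is not supported by this
cohort, and the test suite only asserts count- and threshold-level facts.

## Numerical and engineering choices

* Units are mg/dl throughout; the CSV reader validates rather than
  converts, and collects row-level problems with file line numbers before
  failing, so a malformed cohort fails loudly and completely.
* Censoring flags are authoritative: a record flagged below-LOD uses the
  surrogate even if a value is present, and a detectable record with no
  value is an invalid-record error.
* Exact Mann--Whitney enumeration is capped at 12 pooled observations;
  beyond that the distribution is effectively normal and enumeration buys
  nothing.
* Test and validation problem sizes — 20,000-patient recovery cohorts,
  200,000-draw Monte-Carlo AUC oracle, 10,000-replicate coverage
  simulations, full enumeration of all two-group rank configurations up to
  n = 10 — were chosen to make Monte-Carlo noise small relative to the
  asserted tolerances while keeping the default suite fast.

## Limitations

* The Wilson/Brown boundary divergence noted above: intervals for
  proportions within ~2 successes of 0 or n may differ in the third or
  fourth decimal from software using the hybrid.
* AUCs, group medians and p-values computed on synthetic cohorts
  characterise the generator's calibration, not any real population.
* The clinical-override pathway ("test anyway on strong clinical
  suspicion") is representable only as the caller choosing not to apply a
  tier stop; the package contains no logic for it.
* Lambda free light chains, IgG indices and isoelectric-focusing image
  interpretation are out of scope.
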