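# Published benchmark tables used to validate the ranking and pooling
# machinery against values reported in the literature.

#' Published method-ranking benchmark
#'
#' Per-correlate performance rankings of mtDNA-CN estimation methods
#' reported by a published cross-platform comparison in two US
#' cardiovascular cohorts (ARIC and MESA): four methods (Illumina Exome
#' Chip, Affymetrix 6.0 array, WES, WGS) ranked on five correlates in
#' ARIC, and three methods on four correlates in MESA (WBC count was not
#' available there, and the two PCR-based methods tied on the Duffy locus,
#' receiving the average rank 2.5). Rank 1 = most significant association.
#'
#' These rankings are reference inputs for validating [rank_methods()] and
#' [kendalls_w()]: the ARIC matrix yields W = 0.792 and the MESA matrix
#' (tie-corrected) W = 0.8167.
#'
#' @return A tibble: `cohort`, `method`, `correlate`, `rank`.
#' @export
reference_rankings <- function() {
  aric <- tibble(
    cohort = "ARIC",
    method = rep(c("ExomeChip", "Affymetrix", "WES", "WGS"), each = 5),
    correlate = rep(c("age", "sex", "wbc", "duffy", "cvd"), times = 4),
    rank = c(2, 4, 3, 4, 4,
             3, 2, 2, 2, 2,
             4, 3, 4, 3, 3,
             1, 1, 1, 1, 1)
  )
  mesa <- tibble(
    cohort = "MESA",
    method = rep(c("ExomeChip", "Affymetrix", "qPCR"), each = 4),
    correlate = rep(c("age", "sex", "duffy", "cvd"), times = 3),
    rank = c(2, 3, 2.5, 3,
             1, 1, 1, 1,
             3, 2, 2.5, 2)
  )
  bind_rows(aric, mesa)
}

#' Published cohort-characteristics benchmark
#'
#' Baseline participant characteristics of the two cohorts in the same
#' published comparison: per-cohort N, female count, Black count, mean and
#' SD of age (and of WBC where measured), and incident-CVD counts. Pooling
#' these rows with [pool_cohort_summaries()] reproduces the published
#' combined figures (N = 4,574; mean age 61.4 years; 55.3% female).
#'
#' @return A tibble in the [summarize_cohort()] layout.
#' @export
reference_cohort_summary <- function() {
  tibble(
    cohort = c("ARIC", "MESA"),
    n = c(1085, 3489),
    n_female = c(672, 1856),
    pct_female = 100 * c(672 / 1085, 1856 / 3489),
    n_black = c(958, 1226),
    pct_black = 100 * c(958 / 1085, 1226 / 3489),
    age_mean = c(57.1, 62.7),
    age_sd = c(5.9, 10.2),
    wbc_mean = c(5.8, NA),
    wbc_sd = c(1.7, NA),
    n_events = c(174, 270),
    pct_events = 100 * c(174 / 1085, 270 / 3489)
  )
}

#' Published extraction-variance benchmark
#'
#' Replicate variances of the three DNA-extraction methods (direct cell
#' lysis, phenol-chloroform-isoamyl alcohol, silica-column kit) reported
#' by the same study's reproducibility experiment (15 replicates, qPCR in
#' triplicate). Used both as a validation target for [var_f_test()] (the
#' PCIAA vs Qiagen ratio gives F = 0.29, p = 0.03 on 14 and 14 df) and as
#' default generator settings for [generate_extraction_replicates()].
#'
#' @return A named numeric vector of variances.
#' @export
reference_extraction_variances <- function() {
  c(Lyse = 0.02, PCIAA = 0.17, Qiagen = 0.59)
}
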