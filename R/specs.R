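#' Specification of a simulated cohort
#'
#' Bundles the demographic structure, covariate effect sizes and survival
#' parameters of a simulated population cohort. The defaults describe a
#' biracial US cardiovascular cohort of the kind mtDNA-CN has been studied
#' in: mean age near 57 with SD 6, roughly 62% female and 88% Black,
#' white blood cell (WBC) counts of 5.8 +/- 1.7 (10^3 cells/ul) with ~15%
#' missing, and administrative censoring of incident cardiovascular disease
#' (CVD) at 15 years of follow-up.
#'
#' The latent true copy number is log-normal:
#' \deqn{\log CN = \mu + \beta_{age}(age - \bar a) + \beta_{sex} I(female)
#'   + \beta_{wbc}(WBC - \bar w) + \beta_{duffy.direct} D + center + \epsilon}
#' with \eqn{\epsilon \sim N(0, latent\_sd^2)}. The Duffy-null allele dosage
#' `D` (rs2814778) acts on copy number only through WBC by default
#' (`beta_duffy_direct = 0`): carriers have lower WBC, and WBC in turn is
#' negatively associated with copy number, which makes the Duffy locus an
#' external validator for any copy-number estimate that is not adjusted for
#' WBC. Event times for incident CVD are exponential with per-individual
#' hazard \eqn{h_0 \exp(\gamma z)} where `z` is the within-cohort z-score of
#' log copy number, so `gamma_cvd = log(0.63)` corresponds to a hazard ratio
#' of 0.63 per SD of copy number.
#'
#' Default effect magnitudes are chosen to reflect the consistently reported
#' correlate directions (copy number higher in women, declining with age,
#' negatively correlated with WBC, protective for incident CVD) at strengths
#' that make all five correlates clearly detectable in cohorts of a few
#' thousand individuals.
#'
#' @param n_individuals Number of individuals.
#' @param fraction_female,fraction_black Cohort composition, proportions.
#' @param age_mean,age_sd Age distribution, years.
#' @param wbc_mean,wbc_sd WBC distribution, 10^3 cells/ul (`wbc_sd` is the
#'   residual SD around the Duffy-genotype means).
#' @param wbc_missing_rate Proportion of WBC values set missing completely at
#'   random.
#' @param duffy_null_freq Duffy-null (rs2814778 alternate) allele frequency in
#'   Black participants; near zero in White participants.
#' @param beta_age Effect on log copy number per year of age.
#' @param beta_sex Effect on log copy number of female vs male sex.
#' @param beta_wbc Effect on log copy number per 10^3 cells/ul WBC.
#' @param beta_duffy_on_wbc Shift in WBC (10^3 cells/ul) per Duffy-null allele.
#' @param beta_duffy_direct Direct effect of Duffy dosage on log copy number
#'   (0 by default: the locus acts only through WBC).
#' @param gamma_cvd Log hazard ratio for incident CVD per SD of log copy
#'   number. The default `log(0.63)` is protective.
#' @param baseline_hazard Baseline CVD hazard, events per person-year.
#' @param followup_horizon Administrative censoring horizon, years.
#' @param latent_mean Mean log copy number; `exp(latent_mean)` is the typical
#'   mitochondrial genome count per cell (default 150).
#' @param latent_sd SD of the residual latent log copy number; must be >= 0
#'   (0 gives a degenerate cohort useful for pipeline checks).
#' @param center_effect_sd SD of DNA-collection-center shifts on log copy
#'   number (centers introduce technical offsets that downstream
#'   harmonization must absorb).
#' @param n_centers Number of collection centers.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_individuals = 1000,
                        fraction_female = 0.619,
                        fraction_black = 0.883,
                        age_mean = 57.1, age_sd = 5.9,
                        wbc_mean = 5.8, wbc_sd = 1.7,
                        wbc_missing_rate = 0.149,
                        duffy_null_freq = 0.8,
                        beta_age = -0.01,
                        beta_sex = 0.15,
                        beta_wbc = -0.09,
                        beta_duffy_on_wbc = -1.0,
                        beta_duffy_direct = 0,
                        gamma_cvd = log(0.63),
                        baseline_hazard = 0.012,
                        followup_horizon = 15,
                        latent_mean = log(150),
                        latent_sd = 0.35,
                        center_effect_sd = 0.05,
                        n_centers = 4,
                        seed = 1L) {
  check_count(n_individuals, "n_individuals")
  check_proportion(fraction_female, "fraction_female")
  check_proportion(fraction_black, "fraction_black")
  check_proportion(wbc_missing_rate, "wbc_missing_rate")
  check_proportion(duffy_null_freq, "duffy_null_freq")
  check_nonneg(age_sd, "age_sd")
  check_nonneg(wbc_sd, "wbc_sd")
  check_nonneg(latent_sd, "latent_sd")
  check_nonneg(center_effect_sd, "center_effect_sd")
  check_nonneg(baseline_hazard, "baseline_hazard")
  check_nonneg(followup_horizon, "followup_horizon")
  check_count(n_centers, "n_centers")
  spec <- as.list(environment())
  structure(spec, class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>", x$n_individuals, "individuals;",
      sprintf("%.0f%% female, %.0f%% Black;", 100 * x$fraction_female,
              100 * x$fraction_black),
      sprintf("HR per SD = %.2f", exp(x$gamma_cvd)), "\n")
  invisible(x)
}

#' Specification of platform-level measurement noise
#'
#' Collects the technical-noise parameters of every simulated measurement
#' platform. Magnitudes are free parameters of the simulation; the defaults
#' order the platforms the way cross-platform comparisons have found them
#' (whole-genome sequencing nearly noise-free, arrays intermediate, qPCR
#' noisiest), with the dominant qPCR and array components placed at the
#' sample level (DNA extraction and quality, hybridization efficiency)
#' rather than the replicate level, where real platform noise concentrates.
#'
#' @param qpcr_ct_sd Replicate-level SD of each Ct measurement, cycles.
#' @param qpcr_sample_sd Sample-level SD of the delta-Ct shift shared by all
#'   of a sample's replicates (extraction/DNA-quality noise), cycles.
#' @param qpcr_pipette_slope Linear drift of delta-Ct per pipetting position,
#'   cycles per position.
#' @param plate_effect_sd SD of qPCR plate random intercepts, cycles.
#' @param outlier_rate Fraction of qPCR replicates grossly perturbed
#'   (2 to 5 cycles).
#' @param qpcr_plate_size Wells per qPCR plate (samples x replicates).
#' @param dpcr_partitions Partitions per digital-PCR well (default 36,000).
#' @param dpcr_volume_ul Digital-PCR reaction volume, ul.
#' @param dpcr_lambda_rpph1 Mean copies per partition of the nuclear target;
#'   the mitochondrial target scales with true copy number.
#' @param dpcr_plate_sd SD of multiplicative plate effects on the dPCR ratio
#'   (log scale).
#' @param dpcr_wells_per_plate Wells per dPCR plate.
#' @param array_probe_sd Per-probe log R ratio (LRR) noise SD.
#' @param array_sample_sd Sample-level LRR shift on mitochondrial probes not
#'   captured by autosomal technical covariates (hybridization efficiency).
#' @param batch_effect_loadings SDs of probe loadings for each shared latent
#'   batch factor; length gives the number of factors.
#' @param array_gc_amplitude SD of per-sample GC wave coefficients.
#' @param wgs_total_reads_mean,wes_total_reads_mean Mean total aligned reads.
#' @param wes_batch_sd Scale of the metric-driven distortion of WES
#'   mitochondrial coverage (log scale).
#' @param wes_metric_loadings Relative loadings of the six emitted sequencing
#'   metrics on the WES distortion; zeros mark pure-noise metrics.
#' @param seed Integer seed for the platform noise streams.
#'
#' @return An object of class `platform_noise_spec`.
#' @export
platform_noise_spec <- function(qpcr_ct_sd = 0.25,
                                qpcr_sample_sd = 0.5,
                                qpcr_pipette_slope = 0.005,
                                plate_effect_sd = 0.25,
                                outlier_rate = 0.02,
                                qpcr_plate_size = 96,
                                dpcr_partitions = 36000,
                                dpcr_volume_ul = 15,
                                dpcr_lambda_rpph1 = 0.004,
                                dpcr_plate_sd = 0.05,
                                dpcr_wells_per_plate = 24,
                                array_probe_sd = 0.4,
                                array_sample_sd = 0.35,
                                batch_effect_loadings = c(0.3, 0.15),
                                array_gc_amplitude = 0.1,
                                wgs_total_reads_mean = 3e7,
                                wes_total_reads_mean = 6e7,
                                wes_batch_sd = 0.2,
                                wes_metric_loadings = c(1, 0.5, 0, 0, 0, 0),
                                seed = 1L) {
  for (nm in c("qpcr_ct_sd", "qpcr_sample_sd", "plate_effect_sd",
               "dpcr_plate_sd", "array_probe_sd", "array_sample_sd",
               "array_gc_amplitude", "wes_batch_sd", "dpcr_lambda_rpph1")) {
    check_nonneg(get(nm), nm)
  }
  check_proportion(outlier_rate, "outlier_rate")
  check_count(dpcr_partitions, "dpcr_partitions")
  check_count(dpcr_wells_per_plate, "dpcr_wells_per_plate")
  spec <- as.list(environment())
  spec$nm <- NULL
  structure(spec, class = "platform_noise_spec")
}

#' @export
print.platform_noise_spec <- function(x, ...) {
  cat("<platform_noise_spec>",
      sprintf("qPCR Ct sd %.2f (+%.2f/sample); array probe sd %.2f (+%.2f/sample); %d dPCR partitions",
              x$qpcr_ct_sd, x$qpcr_sample_sd, x$array_probe_sd,
              x$array_sample_sd, x$dpcr_partitions), "\n")
  invisible(x)
}
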