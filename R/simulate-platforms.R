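# Platform-level measurement simulators. Each draws from its own seed
# sub-stream of the noise spec so platforms can be generated in any order
# or combination without changing one another's values.

#' Simulate qPCR replicate plates
#'
#' Lays cohort samples onto plates and emits replicate-level Ct values for a
#' mitochondrial (ND1) and a nuclear (RPPH1) target. The mitochondrial Ct
#' decreases by one cycle per doubling of true copy number (so delta-Ct =
#' Ct_RPPH1 - Ct_ND1 rises with copy number), pipetting order adds a linear
#' drift, plates get random intercepts, samples get a shared
#' extraction-quality shift, and a small fraction of replicates is grossly
#' perturbed.
#'
#' @param cohort A tibble from [generate_cohort()].
#' @param noise A [platform_noise_spec()].
#' @param replicates_per_sample Replicates per sample (default 3,
#'   i.e. triplicate).
#' @return A tibble of replicates: `sample_id`, `plate_id`,
#'   `pipetting_order`, `ct_nd1`, `ct_rpph1`.
#' @export
generate_qpcr_plates <- function(cohort, noise, replicates_per_sample = 3) {
  check_columns(cohort, c("id", "true_cn"), "`cohort`")
  check_count(replicates_per_sample, "replicates_per_sample")
  stopifnot(inherits(noise, "platform_noise_spec"))
  n <- nrow(cohort)
  samples_per_plate <- max(1L, floor(noise$qpcr_plate_size / replicates_per_sample))
  withr::with_seed(substream_seed(noise$seed, 2L), {
    plate_idx <- ceiling(seq_len(n) / samples_per_plate)
    n_plates <- max(plate_idx)
    plate_int <- rnorm(n_plates, 0, noise$plate_effect_sd)
    sample_shift <- rnorm(n, 0, noise$qpcr_sample_sd)

    reps <- tidyr::expand_grid(sample_row = seq_len(n),
                               replicate = seq_len(replicates_per_sample))
    reps <- reps |>
      mutate(
        plate = plate_idx[.data$sample_row],
        sample_id = cohort$id[.data$sample_row]
      ) |>
      group_by(.data$plate) |>
      mutate(pipetting_order = seq_len(dplyr::n())) |>
      ungroup()

    m <- nrow(reps)
    base_rpph1 <- 26
    ct_rpph1 <- base_rpph1 +
      noise$qpcr_pipette_slope * reps$pipetting_order +
      rnorm(m, 0, noise$qpcr_ct_sd)
    ct_nd1 <- base_rpph1 -
      log2(cohort$true_cn[reps$sample_row]) -
      sample_shift[reps$sample_row] +
      plate_int[reps$plate] +
      rnorm(m, 0, noise$qpcr_ct_sd)
    outlier <- runif(m) < noise$outlier_rate
    ct_nd1[outlier] <- ct_nd1[outlier] +
      sample(c(-1, 1), sum(outlier), replace = TRUE) * runif(sum(outlier), 2, 5)

    tibble(
      sample_id = reps$sample_id,
      plate_id = sprintf("P%03d", reps$plate),
      pipetting_order = reps$pipetting_order,
      ct_nd1 = ct_nd1,
      ct_rpph1 = ct_rpph1
    )
  })
}

#' Simulate digital PCR wells
#'
#' One well per sample: both targets are partitioned into
#' `noise$dpcr_partitions` compartments and positive-partition counts are
#' drawn as Binomial(partitions, 1 - exp(-lambda)), with the nuclear-target
#' mean occupancy `noise$dpcr_lambda_rpph1` and the mitochondrial target
#' scaled by true copy number, so the ND1:RPPH1 concentration ratio equals
#' true copy number in expectation. Plates add a small multiplicative
#' distortion to the mitochondrial occupancy.
#'
#' @inheritParams generate_qpcr_plates
#' @return A tibble: `sample_id`, `plate_id`, `positives_nd1`,
#'   `positives_rpph1`, `n_partitions`, `well_volume`.
#' @export
generate_dpcr_wells <- function(cohort, noise) {
  check_columns(cohort, c("id", "true_cn"), "`cohort`")
  stopifnot(inherits(noise, "platform_noise_spec"))
  n <- nrow(cohort)
  withr::with_seed(substream_seed(noise$seed, 3L), {
    plate_idx <- ceiling(seq_len(n) / noise$dpcr_wells_per_plate)
    plate_eff <- rnorm(max(plate_idx), 0, noise$dpcr_plate_sd)
    lambda_r <- rep(noise$dpcr_lambda_rpph1, n)
    lambda_n <- lambda_r * cohort$true_cn * exp(plate_eff[plate_idx])
    tibble(
      sample_id = cohort$id,
      plate_id = sprintf("D%03d", plate_idx),
      positives_nd1 = rbinom(n, noise$dpcr_partitions, 1 - exp(-lambda_n)),
      positives_rpph1 = rbinom(n, noise$dpcr_partitions, 1 - exp(-lambda_r)),
      n_partitions = noise$dpcr_partitions,
      well_volume = noise$dpcr_volume_ul
    )
  })
}

#' Simulate genotyping-array probe intensities
#'
#' Emits a samples-by-probes log R ratio (LRR) matrix together with a probe
#' annotation table and a genotype matrix. Mitochondrial-probe LRR is
#' centered on the within-cohort-centered log2 of true copy number;
#' autosomal probes carry no copy-number signal. All probes share latent
#' batch factors (one per entry of `noise$batch_effect_loadings`), a
#' per-sample GC wave acting on probe GC fraction, and independent probe
#' noise; mitochondrial probes additionally get a per-sample hybridization
#' shift that autosomal technical covariates cannot capture.
#'
#' @inheritParams generate_qpcr_plates
#' @param n_mito_probes Number of mitochondrial probes (default 25, the
#'   curated high-quality probe count of the Affymetrix 6.0 array).
#' @param n_auto_probes Number of autosomal probes (default 43,316 as on the
#'   filtered Affymetrix 6.0 set; use a few hundred for quick simulations).
#' @return A list: `lrr` (samples x probes matrix), `probes` (annotation
#'   tibble: `probe_id`, `chromosome`, `position`, `gc_fraction`, `is_mito`),
#'   `genotypes` (samples x probes matrix coded 0/1/2 with NA for no-calls;
#'   mitochondrial probes are mostly homozygous), and `batch_factors` (the
#'   latent sample scores, for validation only).
#' @export
generate_array_intensities <- function(cohort, noise,
                                       n_mito_probes = 25,
                                       n_auto_probes = 43316) {
  check_columns(cohort, c("id", "true_cn"), "`cohort`")
  stopifnot(inherits(noise, "platform_noise_spec"))
  check_count(n_mito_probes, "n_mito_probes")
  check_count(n_auto_probes, "n_auto_probes")
  n <- nrow(cohort)
  withr::with_seed(substream_seed(noise$seed, 4L), {
    p <- n_mito_probes + n_auto_probes
    probes <- tibble(
      probe_id = c(sprintf("mt_%03d", seq_len(n_mito_probes)),
                   sprintf("snp_%06d", seq_len(n_auto_probes))),
      chromosome = c(rep("MT", n_mito_probes),
                     sample(as.character(1:22), n_auto_probes, replace = TRUE)),
      position = c(sort(sample.int(16569, n_mito_probes)),
                   sample.int(2.4e8, n_auto_probes, replace = TRUE)),
      gc_fraction = rbeta(p, 8, 8),
      is_mito = rep(c(TRUE, FALSE), c(n_mito_probes, n_auto_probes))
    ) |>
      arrange(.data$is_mito == FALSE, .data$chromosome, .data$position)

    n_factors <- length(noise$batch_effect_loadings)
    factors <- matrix(rnorm(n * n_factors), n, n_factors)
    loadings <- matrix(rnorm(p * n_factors), p, n_factors) *
      rep(noise$batch_effect_loadings, each = p)
    batch <- factors %*% t(loadings)

    gc_coef <- rnorm(n, 0, noise$array_gc_amplitude)
    gc_centered <- probes$gc_fraction - mean(probes$gc_fraction)
    signal <- log2(cohort$true_cn) - mean(log2(cohort$true_cn))
    sample_shift <- rnorm(n, 0, noise$array_sample_sd)

    lrr <- batch + outer(gc_coef, gc_centered) +
      matrix(rnorm(n * p, 0, noise$array_probe_sd), n, p)
    mito_cols <- which(probes$is_mito)
    lrr[, mito_cols] <- lrr[, mito_cols] + signal + sample_shift

    geno <- matrix(NA_integer_, n, p)
    # mitochondrial probes: nearly always homozygous calls
    for (j in mito_cols) {
      geno[, j] <- ifelse(runif(n) < 0.98, sample(c(0L, 2L), n, replace = TRUE), 1L)
    }
    auto_cols <- which(!probes$is_mito)
    maf <- runif(length(auto_cols), 0.05, 0.5)
    for (k in seq_along(auto_cols)) {
      g <- rbinom(n, 2L, maf[k])
      g[runif(n) < 0.005] <- NA_integer_
      geno[, auto_cols[k]] <- g
    }
    dimnames(lrr) <- list(cohort$id, probes$probe_id)
    dimnames(geno) <- list(cohort$id, probes$probe_id)
    list(lrr = lrr, probes = probes, genotypes = geno, batch_factors = factors)
  })
}

#' Simulate sequencing read-count summaries
#'
#' Mitochondrial read counts are Binomial(total reads, p) with success
#' probability proportional to true copy number (one mitochondrial genome of
#' 16,569 bp against two copies of a 3.2 Gb nuclear genome). Whole-genome
#' sequencing (WGS) emits clean counts; whole-exome sequencing (WES)
#' multiplies the mitochondrial capture probability by a distortion driven
#' by named sequencing metrics and emits the metrics table alongside.
#'
#' @inheritParams generate_qpcr_plates
#' @param platform `"wgs"` or `"wes"`.
#' @return For WGS, a tibble `sample_id`, `mito_reads`,
#'   `total_aligned_reads`, `platform`. For WES, a list with that tibble
#'   (`readcounts`) and a `metrics` tibble of six named metrics.
#' @export
generate_read_counts <- function(cohort, noise, platform = c("wgs", "wes")) {
  check_columns(cohort, c("id", "true_cn"), "`cohort`")
  stopifnot(inherits(noise, "platform_noise_spec"))
  platform <- match.arg(platform)
  n <- nrow(cohort)
  stream <- if (platform == "wgs") 5L else 6L
  withr::with_seed(substream_seed(noise$seed, stream), {
    p_base <- cohort$true_cn * 16569 / (2 * 3.2e9)
    total_mean <- if (platform == "wgs") noise$wgs_total_reads_mean else noise$wes_total_reads_mean
    total <- pmax(1, round(rnorm(n, total_mean, 0.05 * total_mean)))
    if (platform == "wgs") {
      mito <- rbinom(n, total, pmin(1, p_base))
      return(tibble(sample_id = cohort$id, mito_reads = mito,
                    total_aligned_reads = total, platform = "wgs"))
    }
    metric_names <- c("mean_insert_size", "pct_pf_reads_aligned",
                      "mean_base_quality", "gc_dropout",
                      "pct_chimeras", "total_yield_gb")
    z <- matrix(rnorm(n * 6), n, 6)
    load <- noise$wes_metric_loadings
    if (length(load) != 6) abort("`wes_metric_loadings` must have length 6.")
    distort <- exp(noise$wes_batch_sd * as.vector(z %*% load))
    # exome capture pulls down off-target mitochondrial reads ~10x
    mito <- rbinom(n, total, pmin(1, 0.1 * p_base * distort))
    scale_loc <- rbind(c(200, 15), c(0.98, 0.01), c(36, 1),
                       c(2, 0.5), c(1, 0.3), c(8, 1))
    metrics <- as_tibble(setNames(
      lapply(1:6, function(j) scale_loc[j, 1] + scale_loc[j, 2] * z[, j]),
      metric_names))
    metrics <- bind_cols(tibble(sample_id = cohort$id), metrics)
    list(
      readcounts = tibble(sample_id = cohort$id, mito_reads = mito,
                          total_aligned_reads = total, platform = "wes"),
      metrics = metrics
    )
  })
}

#' Simulate a DNA-extraction reproducibility experiment
#'
#' Emulates a replicate experiment in which aliquots of a single cell
#' culture are extracted by several methods and measured by qPCR in
#' triplicate runs: each method gets `n_replicates` extraction replicates
#' with method-specific between-replicate variance, each measured once per
#' run, with shared per-run (plate) intercepts and run-level measurement
#' noise. The target variances apply to the per-replicate values after plate
#' mean-zeroing and run averaging, so the generator allocates
#' `method_variances - run_sd^2 / n_runs` (floored at zero) to the
#' replicate effects.
#'
#' @param n_replicates Extraction replicates per method (default 15).
#' @param n_runs Measurement runs, each on its own plate (default 3).
#' @param method_variances Named numeric vector of target variances of the
#'   run-averaged replicate values, one per extraction method. Defaults to
#'   the three-method design (direct lysis, organic solvent, silica column)
#'   with variances 0.02, 0.17 and 0.59.
#' @param method_means Method-level mean shifts (extraction chemistry
#'   changes the estimate itself, not only its spread).
#' @param run_sd Within-run measurement noise SD.
#' @param run_intercept_sd SD of shared per-run plate intercepts (removed by
#'   plate mean-zeroing downstream).
#' @param seed Integer seed.
#' @return A tibble: `method`, `replicate_id`, `run_id`, `plate_id`, `value`.
#' @export
generate_extraction_replicates <- function(n_replicates = 15, n_runs = 3,
                                           method_variances = c(Lyse = 0.02,
                                                                PCIAA = 0.17,
                                                                Qiagen = 0.59),
                                           method_means = NULL,
                                           run_sd = 0.05,
                                           run_intercept_sd = 0.2,
                                           seed = 1L) {
  check_count(n_replicates, "n_replicates")
  check_count(n_runs, "n_runs")
  check_nonneg(run_sd, "run_sd")
  if (any(method_variances < 0)) abort("`method_variances` must be >= 0.")
  if (is.null(names(method_variances))) {
    names(method_variances) <- paste0("method", seq_along(method_variances))
  }
  if (is.null(method_means)) {
    method_means <- seq_along(method_variances) * 0.5
  }
  withr::with_seed(substream_seed(seed, 7L), {
    run_int <- rnorm(n_runs, 0, run_intercept_sd)
    rows <- imap(as.list(method_variances), function(v, meth) {
      rep_var <- max(0, v - run_sd^2 / n_runs)
      rep_eff <- rnorm(n_replicates, 0, sqrt(rep_var))
      grid <- tidyr::expand_grid(replicate_id = seq_len(n_replicates),
                                 run_id = seq_len(n_runs))
      grid |>
        mutate(
          method = meth,
          plate_id = sprintf("R%02d", .data$run_id),
          value = method_means[[which(names(method_variances) == meth)]] +
            rep_eff[.data$replicate_id] + run_int[.data$run_id] +
            rnorm(nrow(grid), 0, run_sd)
        ) |>
        select("method", "replicate_id", "run_id", "plate_id", "value")
    })
    list_rbind(unname(rows))
  })
}
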