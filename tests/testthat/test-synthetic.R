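test_that("invalid cohort specifications are rejected with a message", {
  expect_error(cohort_spec(fraction_female = 1.2), "proportion")
  expect_error(cohort_spec(latent_sd = -0.1), "non-negative")
  expect_error(cohort_spec(n_individuals = 0), "integer")
  expect_error(platform_noise_spec(qpcr_ct_sd = -1), "non-negative")
  expect_error(generate_cohort(list()), "cohort_spec")
})

test_that("identical seeds give bit-identical tables, different seeds differ", {
  spec <- cohort_spec(n_individuals = 120, seed = 42)
  expect_identical(generate_cohort(spec), generate_cohort(spec))
  expect_false(identical(generate_cohort(spec),
                         generate_cohort(cohort_spec(n_individuals = 120,
                                                     seed = 43))))
  noise <- platform_noise_spec(seed = 9)
  co <- generate_cohort(spec)
  expect_identical(generate_qpcr_plates(co, noise),
                   generate_qpcr_plates(co, noise))
  expect_identical(generate_dpcr_wells(co, noise),
                   generate_dpcr_wells(co, noise))
})

test_that("a no-effect, zero-dispersion cohort has constant copy number", {
  co <- generate_cohort(cohort_spec(
    n_individuals = 30, beta_age = 0, beta_sex = 0, beta_wbc = 0,
    beta_duffy_on_wbc = 0, beta_duffy_direct = 0, center_effect_sd = 0,
    latent_sd = 0, seed = 5))
  expect_true(all(co$true_cn == co$true_cn[1]))
  expect_true(all(co$true_cn > 0))
})

test_that("generated age and CVD effects are recovered by regression oracles", {
  co <- generate_cohort(cohort_spec(n_individuals = 5000, beta_age = -0.01,
                                    gamma_cvd = log(0.63), seed = 17))
  fit <- lm(log(true_cn) ~ age + sex + wbc + duffy_dosage, data = co)
  est <- summary(fit)$coefficients["age", ]
  expect_lt(abs(est[1] - (-0.01)), 3 * est[2])

  z <- scale(log(co$true_cn))[, 1]
  cox <- survival::coxph(survival::Surv(followup_time, event) ~ z, data = co)
  sm <- summary(cox)$coefficients
  expect_lt(abs(sm[1, "coef"] - log(0.63)), 3 * sm[1, "se(coef)"])
})

test_that("event rate under a null hazard matches the exponential model", {
  spec <- cohort_spec(n_individuals = 4000, gamma_cvd = 0,
                      baseline_hazard = 0.012, followup_horizon = 15,
                      seed = 23)
  co <- generate_cohort(spec)
  expected <- 1 - exp(-0.012 * 15)
  observed <- mean(co$event)
  expect_lt(abs(observed - expected),
            3 * sqrt(expected * (1 - expected) / nrow(co)))
})

test_that("Duffy dosage affects copy number only through WBC", {
  co <- generate_cohort(cohort_spec(n_individuals = 8000, seed = 31,
                                    wbc_missing_rate = 0))
  blacks <- co[co$ethnicity == "Black", ]
  # marginal association present (through WBC)...
  marg <- summary(lm(log(true_cn) ~ duffy_dosage, data = blacks))$coefficients
  expect_lt(marg["duffy_dosage", 4], 0.01)
  # ...but conditional on WBC the partial association vanishes
  part <- summary(lm(log(true_cn) ~ duffy_dosage + wbc,
                     data = blacks))$coefficients
  expect_gt(part["duffy_dosage", 4], 0.01)
  expect_lt(abs(part["duffy_dosage", 1]), 3 * part["duffy_dosage", 2])
})

test_that("with all noise off, every platform is monotone in true copy number", {
  # 30 samples fit one qPCR plate; across plates the plate adjustment may
  # subtract different constants, so monotonicity is a within-plate property
  co <- plain_cohort(n = 30, seed = 3)
  noise <- silent_noise(seed = 3)

  reps <- generate_qpcr_plates(co, noise)
  q <- suppressWarnings(qpcr_estimate(reps))
  truth <- co$true_cn[match(q$estimates$sample_id, co$id)]
  expect_equal(cor(q$estimates$estimate, truth, method = "spearman"), 1)

  arr <- generate_array_intensities(co, noise, n_auto_probes = 40)
  est <- mito_raw_estimate(arr$lrr, arr$genotypes, arr$probes)
  expect_equal(cor(est$raw_estimate, co$true_cn, method = "spearman"), 1)

  # read sampling is inherent to sequencing, so the ratio is monotone only
  # up to binomial counting noise
  rc <- wgs_ratio(generate_read_counts(co, noise, "wgs"))
  expect_gt(cor(rc$ratio, co$true_cn, method = "spearman"), 0.95)
})

test_that("qPCR generator encodes copy number as delta-Ct in log2 units", {
  co <- plain_cohort(n = 8, seed = 2, latent_sd = 0)
  co$true_cn <- 100 * 4^(seq_len(8) %% 2)  # alternating 100 and 400
  reps <- delta_ct(generate_qpcr_plates(co, silent_noise()))
  per_sample <- tapply(reps$dct, reps$sample_id, unique)
  expect_true(all(lengths(per_sample) == 1))  # replicates identical
  gap <- mean(unlist(per_sample[co$id[co$true_cn == 400]])) -
    mean(unlist(per_sample[co$id[co$true_cn == 100]]))
  expect_equal(gap, 2, tolerance = 1e-10)     # log2(4) cycles
})

test_that("dPCR generator follows the Poisson occupancy law", {
  co <- plain_cohort(n = 400, seed = 8, latent_sd = 0)
  co$true_cn <- rep(1, 400)  # lambda_nd1 = lambda_rpph1
  noise <- silent_noise(seed = 8, dpcr_lambda_rpph1 = 1, dpcr_partitions = 36000)
  wells <- generate_dpcr_wells(co, noise)
  frac <- mean(wells$positives_nd1 / wells$n_partitions)
  se <- sqrt((1 - exp(-1)) * exp(-1) / (400 * 36000))
  expect_lt(abs(frac - (1 - exp(-1))), 4 * se)
  # lambda = 0 gives no positives, ever
  co0 <- co; co0$true_cn <- rep(0.0, 400)
  w0 <- generate_dpcr_wells(co0, silent_noise(seed = 8, dpcr_lambda_rpph1 = 0))
  expect_true(all(w0$positives_nd1 == 0) && all(w0$positives_rpph1 == 0))
})

test_that("array generator honors published default probe counts", {
  expect_equal(formals(generate_array_intensities)$n_mito_probes, 25)
  expect_equal(formals(generate_array_intensities)$n_auto_probes, 43316)
  co <- plain_cohort(n = 4, seed = 1)
  arr <- generate_array_intensities(co, silent_noise())
  expect_equal(dim(arr$lrr), c(4, 25 + 43316))
  expect_equal(sum(arr$probes$is_mito), 25)
})

test_that("an injected batch factor is recovered as the first technical PC", {
  co <- plain_cohort(n = 300, seed = 12)
  noise <- platform_noise_spec(array_probe_sd = 0.2, array_sample_sd = 0,
                               batch_effect_loadings = 0.5,
                               array_gc_amplitude = 0, seed = 12)
  arr <- generate_array_intensities(co, noise, n_auto_probes = 120)
  auto <- arr$probes$probe_id[!arr$probes$is_mito]
  pcs <- technical_covariates(arr$lrr[, auto], k = 2)
  expect_gt(abs(cor(pcs[, 1], arr$batch_factors[, 1])), 0.9)
})

test_that("read-count generator scales linearly with copy number", {
  co <- plain_cohort(n = 2000, seed = 4, latent_sd = 0)
  co$true_cn <- rep(c(100, 200), 1000)
  rc <- generate_read_counts(co, silent_noise(seed = 4), "wgs")
  m <- tapply(rc$mito_reads, co$true_cn, mean)
  expect_equal(unname(m["200"] / m["100"]), 2, tolerance = 0.02)
  # and the WGS ratio is unbiased for the underlying read fraction
  p_true <- 100 * 16569 / (2 * 3.2e9)
  ratio <- wgs_ratio(rc)$ratio[co$true_cn == 100]
  expect_lt(abs(mean(ratio) / p_true - 1), 0.01)
})

test_that("WES generator emits a metrics table driving the batch distortion", {
  co <- plain_cohort(n = 250, seed = 6)
  noise <- platform_noise_spec(wes_batch_sd = 0.3,
                               wes_metric_loadings = c(1, 0, 0, 0, 0, 0),
                               seed = 6)
  wes <- generate_read_counts(co, noise, "wes")
  expect_named(wes, c("readcounts", "metrics"))
  expect_equal(nrow(wes$metrics), 250)
  ratio <- wgs_ratio(wes$readcounts)$ratio
  # distortion is tied to the loaded metric
  expect_lt(cor.test(log(ratio), wes$metrics$mean_insert_size)$p.value, 1e-6)
})

test_that("extraction generator reproduces target variances and degeneracy", {
  reps <- generate_extraction_replicates(seed = 21)
  v <- compare_extractions(reps)$method_stats
  targets <- reference_extraction_variances()
  for (m in names(targets)) {
    obs <- v$variance[v$method == m]
    # sample variance lies within the central 95% F envelope of the target
    expect_gt(obs / targets[[m]], qchisq(0.025, 14) / 14)
    expect_lt(obs / targets[[m]], qchisq(0.975, 14) / 14)
  }
  const <- generate_extraction_replicates(
    method_variances = c(only = 0), run_sd = 0, run_intercept_sd = 0, seed = 2)
  expect_equal(var(const$value), 0)
})

test_that("cohort summaries pool correctly across cohorts", {
  co1 <- plain_cohort(n = 150, seed = 1)
  co2 <- plain_cohort(n = 350, seed = 2, age_mean = 65)
  s <- summarize_cohort(list(A = co1, B = co2))
  expect_equal(nrow(s), 2)
  pooled <- pool_cohort_summaries(s)
  expect_equal(pooled$n, 500)
  expect_equal(pooled$age_mean,
               (150 * s$age_mean[1] + 350 * s$age_mean[2]) / 500)
  expect_equal(pooled$n_female, sum(s$n_female))
  # single cohort: pooled equals the cohort summary
  one <- pool_cohort_summaries(s[1, ])
  expect_equal(one$age_mean, s$age_mean[1])
  expect_equal(one$pct_female, s$pct_female[1])
  expect_error(summarize_cohort(list(A = co1[0, ])), "empty")
})
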