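test_that("delta-Ct follows its definition and flags missing values", {
  reps <- tibble::tibble(sample_id = "a", plate_id = "P1",
                         pipetting_order = 1:3,
                         ct_nd1 = c(20, 25, NA), ct_rpph1 = c(25, 25, 25))
  d <- delta_ct(reps)
  expect_equal(d$dct, c(5, 0, NA))
  expect_equal(d$dct_missing, c(FALSE, FALSE, TRUE))
  # equivariance: adding a constant to both targets leaves delta-Ct unchanged
  shifted <- delta_ct(reps |> dplyr::mutate(ct_nd1 = ct_nd1 + 1.7,
                                            ct_rpph1 = ct_rpph1 + 1.7))
  expect_equal(shifted$dct, d$dct)
})

test_that("replicate filters remove by first-failing reason and account for all rows", {
  base <- qpcr_rows(rep(sprintf("s%02d", 1:10), each = 3),
                    dct = rep(5, 30) + rep(c(-0.1, 0, 0.1), 10))
  # one ND1 failure, everything else clean
  bad <- base
  bad$ct_nd1[5] <- 28.5
  res <- filter_replicates(bad)
  expect_equal(nrow(res$kept) + nrow(res$exclusions), nrow(bad))
  expect_equal(res$exclusions$reason, "ND1_CT_HIGH")
  expect_equal(res$exclusions$row, 5L)

  # replicate exactly at the plate means is kept
  clean <- filter_replicates(base)
  expect_equal(nrow(clean$exclusions), 0)

  # a single delta-Ct outlier beyond 3 plate SDs is removed, others kept
  plate <- delta_ct(qpcr_rows(
    rep(sprintf("t%02d", 1:7), each = 3),
    dct = c(rep(5, 20) + seq(-0.095, 0.095, length.out = 20), 0)))
  zscores <- abs(plate$dct - mean(plate$dct)) / sd(plate$dct)
  expect_equal(sum(zscores > 3), 1)  # constructed so exactly one row exceeds
  res2 <- filter_replicates(plate)
  expect_equal(nrow(res2$exclusions), 1)
  expect_equal(res2$exclusions$reason, "DCT_OUTLIER")
  expect_equal(res2$exclusions$row, 21L)

  # RPPH1 plate-relative rule (outlier low, so the ND1 ceiling stays silent)
  plate3 <- base
  plate3$ct_rpph1 <- 26 + c(withr::with_seed(1, rnorm(29, 0, 0.1)), -12)
  plate3$ct_nd1 <- plate3$ct_rpph1 - 5   # keep dct constant
  res3 <- filter_replicates(delta_ct(plate3))
  expect_equal(res3$exclusions$reason, "RPPH1_OUTLIER")
  expect_equal(res3$exclusions$row, 30L)
})

test_that("sample resolution drops outlier replicates and excludes unstable samples", {
  # tight triplicate: kept untouched
  r1 <- resolve_samples(delta_ct(qpcr_rows("a", c(5.0, 5.1, 5.05))))
  expect_equal(r1$estimates$dct, mean(c(5.0, 5.1, 5.05)))
  expect_equal(r1$estimates$n_replicates_used, 3L)

  # one wild replicate: dropped, survivors averaged
  r2 <- resolve_samples(delta_ct(qpcr_rows("a", c(5.0, 5.1, 8.0))))
  expect_equal(r2$estimates$dct, 5.05)
  expect_equal(r2$estimates$n_replicates_used, 2L)
  expect_equal(nrow(r2$dropped_replicates), 1)

  # spread so wide that no single removal rescues it: sample excluded
  x <- c(4.0, 5.5, 7.0)
  expect_true(all(vapply(1:3, function(i) sd(x[-i]) > 0.5, logical(1))))
  r3 <- resolve_samples(delta_ct(qpcr_rows("a", x)))
  expect_equal(nrow(r3$estimates), 0)
  expect_equal(r3$exclusions$reason, "SAMPLE_DCT_SD")

  # no surviving replicates at all
  none <- delta_ct(qpcr_rows("a", c(NA, NA, NA)))
  r4 <- resolve_samples(none)
  expect_equal(r4$exclusions$reason, "NO_REPLICATES")
})

test_that("pipetting correction recovers and removes an injected linear drift", {
  # zero injected slope, zero noise: exact identity
  reps <- delta_ct(generate_qpcr_plates(plain_cohort(n = 32, seed = 5),
                                        silent_noise(seed = 5)))
  corr <- pipetting_correction(reps)
  expect_equal(corr$dct, reps$dct, tolerance = 1e-12)
  expect_equal(attr(corr, "slopes")$slope, 0, tolerance = 1e-12)

  # injected slope, zero noise: corrected values constant per sample,
  # slope recovered exactly
  noisy <- silent_noise(seed = 5)
  noisy$qpcr_pipette_slope <- 0.01
  reps2 <- delta_ct(generate_qpcr_plates(plain_cohort(n = 32, seed = 5), noisy))
  corr2 <- pipetting_correction(reps2)
  expect_equal(attr(corr2, "slopes")$slope, 0.01, tolerance = 1e-10)
  spread <- tapply(corr2$dct, corr2$sample_id, function(v) diff(range(v)))
  expect_lt(max(spread), 1e-10)

  # with replicate noise, the slope estimate is within 2 SE of truth
  noise3 <- platform_noise_spec(qpcr_ct_sd = 0.1, qpcr_sample_sd = 0,
                                plate_effect_sd = 0, outlier_rate = 0,
                                qpcr_pipette_slope = 0.01, seed = 6)
  reps3 <- delta_ct(generate_qpcr_plates(plain_cohort(n = 32, seed = 6), noise3))
  sl <- attr(pipetting_correction(reps3), "slopes")
  expect_lt(abs(sl$slope - 0.01), 2 * sl$slope_se)
})

test_that("plate adjustment shrinks toward the grand mean like a random-intercept model", {
  withr::with_seed(99, {
    plate <- rep(sprintf("P%d", 1:6), each = 20)
    eff <- rep(rnorm(6, 0, 1), each = 20)
    x <- 3 + eff + rnorm(120, 0, 0.5)
  })
  adj <- plate_adjust(x, plate)
  expect_equal(mean(adj), 0, tolerance = 1e-12)
  # residual plate means are near zero
  expect_lt(max(abs(tapply(adj, plate, mean))), 0.15)

  # agreement with the REML random-intercept fit (balanced case)
  fit <- lme4::lmer(x ~ 1 + (1 | plate))
  blup_lmer <- lme4::ranef(fit)$plate[[1]]
  ours <- tapply(x, plate, mean) - mean(x) - tapply(adj, plate, mean)
  expect_equal(as.numeric(ours[rownames(lme4::ranef(fit)$plate)]),
               blup_lmer, tolerance = 1e-5)

  # single plate degenerates to centering (or identity when mean preserved)
  one <- plate_adjust(c(1, 2, 3), rep("P", 3))
  expect_equal(one, c(-1, 0, 1))
  expect_equal(plate_adjust(c(1, 2, 3), rep("P", 3), preserve_mean = TRUE),
               c(1, 2, 3))

  # a small extreme plate is pulled toward zero relative to raw centering
  withr::with_seed(7, {
    plate2 <- c(rep("A", 40), rep("B", 40), rep("C", 4))
    x2 <- c(rnorm(40, 0, 1), rnorm(40, 0.2, 1), rnorm(4, 3, 1))
  })
  adj2 <- plate_adjust(x2, plate2)
  small_mean_adj <- mean(adj2[plate2 == "C"])
  expect_gt(small_mean_adj, 0)  # not fully centered: shrunk toward the grand mean
})

test_that("full qPCR pipeline is affine in log2 true copy number on clean data", {
  co <- plain_cohort(n = 64, seed = 9)
  res <- qpcr_estimate(generate_qpcr_plates(co, silent_noise(seed = 9)))
  truth <- log2(co$true_cn[match(res$estimates$sample_id, co$id)])
  fit <- lm(res$estimates$estimate ~ truth)
  expect_gt(summary(fit)$r.squared, 1 - 1e-10)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 1e-6)
})

test_that("qPCR pipeline survives realistic noise and catches gross outliers", {
  co <- plain_cohort(n = 96, seed = 10)
  noise <- platform_noise_spec(outlier_rate = 0.05, seed = 10)
  res <- qpcr_estimate(generate_qpcr_plates(co, noise))
  expect_gt(nrow(res$estimates), 80)
  truth <- log2(co$true_cn[match(res$estimates$sample_id, co$id)])
  expect_gt(cor(res$estimates$estimate, truth), 0.3)
  expect_true(all(res$exclusions$reason %in%
                    c("MISSING_CT", "ND1_CT_HIGH", "RPPH1_OUTLIER",
                      "DCT_OUTLIER", "SAMPLE_SD_OUTLIER", "SAMPLE_DCT_SD",
                      "NO_REPLICATES")))
})
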