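test_that("p-value ranking averages ties and handles missing correlates", {
  p <- matrix(c(1e-8, 1e-3, 1e-3, NA,
                1e-5, 1e-5, 1e-5, 1e-2), 4, 2,
              dimnames = list(c("a", "b", "c", "d"), c("x", "y")))
  rk <- rank_methods(p)
  expect_equal(unname(rk$ranks[, "x"]), c(1, 2.5, 2.5, NA))
  expect_equal(unname(rk$ranks[, "y"]), c(2, 2, 2, 4))
  expect_equal(rk$mean_ranks$mean_rank, c(1.5, 2.25, 2.25, 4))
  # ranks within a correlate always sum to m(m+1)/2
  expect_equal(sum(rk$ranks[, "y"]), 4 * 5 / 2)
  # all methods tied: everyone gets (m+1)/2
  tied <- rank_methods(matrix(1e-3, 3, 2))
  expect_true(all(tied$ranks == 2))
})

test_that("Kendall's W matches the tie-corrected formula and vegan", {
  # identical rankings: perfect concordance
  same <- rbind(1:4, 1:4, 1:4)
  expect_equal(kendalls_w(same)$w, 1)
  expect_error(kendalls_w(matrix(1, 2, 1)), "2 objects")

  # with no ties, tie-corrected and uncorrected forms coincide
  withr::with_seed(31, {
    for (i in 1:5) {
      rk <- t(replicate(4, sample(5)))
      expect_equal(kendalls_w(rk, tie_correct = TRUE)$w,
                   kendalls_w(rk, tie_correct = FALSE)$w)
      expect_equal(kendalls_w(rk)$w,
                   unname(vegan::kendall.global(t(rk))$Concordance_analysis[1, 1]))
    }
  })

  # tied rankings: cross-check the tie-corrected W against vegan
  tied <- rbind(c(1, 2.5, 2.5, 4), c(2, 1, 3, 4), c(1.5, 1.5, 3, 4))
  expect_equal(kendalls_w(tied)$w,
               unname(vegan::kendall.global(t(tied))$Concordance_analysis[1, 1]))
})

test_that("ratio-standardized scores follow the rule and match a brute-force oracle", {
  p <- matrix(c(1e-4, 1e-2), 2, 1, dimnames = list(c("a", "b"), "x"))
  sc <- score_methods(p)
  expect_equal(unname(sc$scores[, 1]), c(2, 1))
  # all methods equal: everyone scores 1
  eq <- score_methods(matrix(1e-3, 3, 2, dimnames = list(letters[1:3], NULL)))
  expect_true(all(eq$scores == 1))
  # least significant method at p = 1: correlate dropped with a warning
  pm <- matrix(c(1e-4, 1, 1e-3, 1e-2), 2, 2,
               dimnames = list(c("a", "b"), c("x", "y")))
  expect_warning(scw <- score_methods(pm), "undefined")
  expect_equal(colnames(scw$scores), "y")

  # random matrix vs hand-computed ratios
  withr::with_seed(32, pr <- matrix(10^-runif(20, 0.5, 8), 4, 5,
                                    dimnames = list(letters[1:4], NULL)))
  sc2 <- score_methods(pr)
  oracle <- matrix(NA_real_, 4, 5)
  for (j in 1:5) {
    nl <- -log10(pr[, j])
    oracle[, j] <- nl / min(nl)
  }
  expect_equal(unname(sc2$scores), oracle)
  expect_true(all(sc2$scores >= 1))
  expect_equal(sc2$summary$score_sum, rowSums(oracle))
})

test_that("the permutation test matches exhaustive enumeration on small cases", {
  expect_error(permutation_test(matrix(1, 2, 2), n_perm = 0), "n_perm")

  # a method holding every correlate's maximum sits exactly at the floor
  dom <- matrix(c(10, 1, 1, 12, 1.5, 1), 3, 2,
                dimnames = list(c("top", "mid", "low"), NULL))
  pt <- permutation_test(dom, n_perm = 1000, seed = 4)
  expect_equal(pt$perm_p[pt$method == "top"], 1 / 1001)

  # 2 methods x 2 correlates: exact null by enumerating all 4 assignments
  sc <- matrix(c(3.0, 1.0, 1.2, 2.1), 2, 2,
               dimnames = list(c("a", "b"), NULL))
  enumerate_exact <- function(scores, method) {
    i <- which(rownames(scores) == method)
    obs <- sum(scores[i, ])
    draws <- expand.grid(r1 = 1:2, r2 = 1:2)
    nulls <- apply(draws, 1, function(d) scores[d[1], 1] + scores[d[2], 2])
    mean(nulls > obs)
  }
  pt2 <- permutation_test(sc, n_perm = 4000, seed = 5)
  for (m in c("a", "b")) {
    exact <- enumerate_exact(sc, m)
    expect_equal(pt2$perm_p[pt2$method == m],
                 (1 + 4000 * exact) / 4001, tolerance = 0.03)
  }
  # permutation p always lies in [1/(B+1), 1] and is seed-reproducible
  expect_true(all(pt2$perm_p >= 1 / 4001 & pt2$perm_p <= 1))
  expect_identical(pt2, permutation_test(sc, n_perm = 4000, seed = 5))
})

test_that("permutation p-values are roughly uniform under exchangeability", {
  ps <- vapply(1:200, function(s) {
    sc <- matrix(withr::with_seed(2000 + s, rexp(15)), 3, 5)
    rownames(sc) <- c("a", "b", "c")
    permutation_test(sc, n_perm = 199, seed = s)$perm_p[1]
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
  expect_lt(abs(mean(ps < 0.25) - 0.25), 0.1)
})

test_that("head-to-head orders of magnitude follow the definition", {
  p <- matrix(c(1e-8, 1e-6, 1e-4, 1e-4), 2, 2,
              dimnames = list(c("a", "b"), NULL))
  expect_equal(head_to_head(p, "a", "b"), mean(c(2, 0)))
  expect_equal(head_to_head(p, "a", "a"), 0)
  # brute force on a random matrix
  withr::with_seed(33, pr <- matrix(10^-runif(10, 0, 9), 2, 5,
                                    dimnames = list(c("a", "b"), NULL)))
  expect_equal(head_to_head(pr, "a", "b"),
               mean(log10(pr["b", ]) - log10(pr["a", ])))
  expect_error(head_to_head(p, "a", "zz"), "present")
})

test_that("evaluate_methods bundles the stages and exposes broom methods", {
  withr::with_seed(34, pm <- matrix(10^-runif(15, 0.5, 10), 3, 5,
                                    dimnames = list(c("wgs", "array", "qpcr"),
                                                    c("age", "sex", "wbc",
                                                      "duffy", "cvd"))))
  ev <- evaluate_methods(pm, n_perm = 200, seed = 2)
  td <- tidy(ev)
  expect_equal(nrow(td), 3)
  expect_named(td, c("method", "mean_rank", "score_sum", "score_mean",
                     "score_median", "perm_p"))
  gl <- glance(ev)
  expect_true(gl$w >= 0 && gl$w <= 1)
  expect_s3_class(autoplot(ev), "ggplot")
  # permutation outcome invariant to method ordering
  ev2 <- evaluate_methods(pm[c(3, 1, 2), ], n_perm = 200, seed = 2)
  td2 <- tidy(ev2)
  expect_equal(td2$mean_rank[td2$method == "wgs"],
               td$mean_rank[td$method == "wgs"])
})

test_that("the association battery is calibrated on null cohorts", {
  pvals <- list()
  for (s in 1:150) {
    co <- generate_cohort(cohort_spec(
      n_individuals = 250, beta_age = 0, beta_sex = 0, beta_wbc = 0,
      beta_duffy_on_wbc = 0, gamma_cvd = 0, center_effect_sd = 0,
      seed = 4000 + s))
    est <- tibble::tibble(sample_id = co$id, method = "wgs",
                          estimate = log(co$true_cn))
    assoc <- run_battery(est, co)
    pvals[[s]] <- assoc[, c("correlate", "p")]
  }
  pv <- dplyr::bind_rows(pvals)
  for (corr in c("age", "sex", "wbc", "duffy")) {
    x <- pv$p[pv$correlate == corr]
    expect_gt(suppressWarnings(ks.test(x, "punif"))$p.value, 0.01)
  }
})

test_that("battery effects carry the documented signs and magnitudes", {
  co <- generate_cohort(cohort_spec(n_individuals = 5000, seed = 35))
  est <- tibble::tibble(sample_id = co$id, method = "truth",
                        estimate = log(co$true_cn))
  assoc <- run_battery(est, co)
  get <- function(corr, col) assoc[[col]][assoc$correlate == corr]
  expect_lt(get("age", "estimate"), 0)
  expect_gt(get("sex", "estimate"), 0)   # positive in females by convention
  expect_lt(get("wbc", "estimate"), 0)
  expect_gt(get("duffy", "estimate"), 0) # Duffy-null lowers WBC, raises CN
  # Cox stage recovers the injected protective hazard ratio within 3 SE
  expect_lt(abs(get("cvd", "estimate") - log(0.63)), 3 * get("cvd", "se"))
  # too few events: flagged unusable rather than fitted
  co2 <- co |> dplyr::mutate(event = 0L)
  co2$event[1] <- 1L
  assoc2 <- run_battery(est, co2)
  expect_false(assoc2$usable[assoc2$correlate == "cvd"])
})
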