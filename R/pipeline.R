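#' Simulate a full cross-platform method comparison
#'
#' End-to-end simulation of the method-comparison study design on one
#' synthetic cohort: generates ground-truth copy number, measures it with
#' three platforms whose technical noise is ordered (WGS nearly noise-free,
#' array intermediate, qPCR noisiest), runs each platform through its full
#' estimation pipeline, harmonizes, runs the correlate association battery,
#' and evaluates the methods by rank, concordance, score and permutation
#' test. Used to check that the evaluation machinery recovers a known
#' platform-noise ordering.
#'
#' @param seed Integer seed controlling the cohort and every platform
#'   stream.
#' @param n_individuals Cohort size (default 2000).
#' @param n_auto_probes Autosomal probes simulated for the array platform
#'   (default 200; enough for stable technical principal components while
#'   keeping repeated simulation cheap).
#' @param n_perm Permutations for the score test (default 1000).
#' @param cohort_args,noise_args Named lists of overrides passed to
#'   [cohort_spec()] / [platform_noise_spec()].
#' @return A list: `evaluation` (a `cn_eval`), `assoc` (the battery table),
#'   `estimates` (long per-sample estimates) and `cohort`.
#' @examples
#' \donttest{
#' sim <- simulate_method_comparison(seed = 1, n_individuals = 600)
#' tidy(sim$evaluation)
#' }
#' @export
simulate_method_comparison <- function(seed = 1L, n_individuals = 2000,
                                       n_auto_probes = 200, n_perm = 1000,
                                       cohort_args = list(),
                                       noise_args = list()) {
  spec <- do.call(cohort_spec,
                  utils::modifyList(list(n_individuals = n_individuals,
                                         seed = seed), cohort_args))
  noise <- do.call(platform_noise_spec,
                   utils::modifyList(list(seed = seed), noise_args))
  cohort <- generate_cohort(spec)

  qpcr_res <- qpcr_estimate(generate_qpcr_plates(cohort, noise))
  arr_raw <- generate_array_intensities(cohort, noise,
                                        n_auto_probes = n_auto_probes)
  arr_res <- array_estimate(arr_raw$lrr, arr_raw$genotypes, arr_raw$probes,
                            k = min(5, length(noise$batch_effect_loadings) + 3))
  wgs <- wgs_ratio(generate_read_counts(cohort, noise, "wgs"))

  estimates <- bind_rows(
    qpcr_res$estimates |> mutate(method = "qpcr") |>
      select("sample_id", "method", "estimate"),
    arr_res$estimates |> mutate(method = "array") |>
      select("sample_id", "method", estimate = "raw_estimate"),
    wgs |> mutate(method = "wgs") |>
      select("sample_id", "method", estimate = "ratio")
  )
  tech <- list(array = bind_cols(tibble(sample_id = rownames(arr_res$covariates)),
                                 as_tibble(arr_res$covariates)))
  assoc <- run_battery(estimates, cohort, tech = tech)
  ev <- evaluate_methods(assoc, n_perm = n_perm, seed = seed)
  list(evaluation = ev, assoc = assoc, estimates = estimates, cohort = cohort)
}

#' Forest plot of association-battery effect sizes
#'
#' Effect sizes (SD units for linear correlates, log hazard ratio for
#' incident CVD) with 95% confidence intervals, per method and correlate.
#'
#' @param assoc A [run_battery()] result.
#' @return A ggplot object.
#' @export
plot_battery <- function(assoc) {
  check_columns(assoc, c("method", "correlate", "estimate"), "`assoc`")
  d <- assoc |> filter(.data$usable)
  if ("cvd" %in% d$correlate) {
    # put the survival estimate on the log-HR scale alongside the betas
    d <- d |> mutate(
      conf_low = ifelse(.data$correlate == "cvd", log(.data$conf_low),
                        .data$conf_low),
      conf_high = ifelse(.data$correlate == "cvd", log(.data$conf_high),
                         .data$conf_high))
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$method)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf_low,
                                          xmax = .data$conf_high)) +
    ggplot2::facet_wrap(~correlate, scales = "free_x") +
    ggplot2::labs(x = "Effect per SD of mtDNA-CN (log HR for CVD)",
                  y = NULL) +
    ggplot2::theme_minimal()
}
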