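#' Generate a synthetic cohort with known true mtDNA copy number
#'
#' Draws one individual-level table from a [cohort_spec()]: demographics,
#' Duffy genotype, WBC (shifted by Duffy dosage, with values missing
#' completely at random), a latent true copy number on the log scale, and an
#' incident-CVD outcome with exponential event times censored
#' administratively at the follow-up horizon. All randomness flows from
#' `spec$seed` through a dedicated sub-stream, so regenerating with the same
#' spec is bit-identical and independent of any platform simulation.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with one row per individual: `id`, `age`, `sex`
#'   (male/female), `ethnicity` (White/Black), `center`, `wbc` (possibly
#'   `NA`), `duffy_dosage` (0/1/2), `followup_time` (years), `event` (0/1),
#'   and the latent `true_cn` (> 0), which no estimator sees but every
#'   simulation test can compare against.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_individuals = 200, seed = 7))
#' cor(log(cohort$true_cn), cohort$age)
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) {
    abort("`spec` must be created with cohort_spec().")
  }
  n <- spec$n_individuals
  withr::with_seed(substream_seed(spec$seed, 1L), {
    sex <- factor(ifelse(runif(n) < spec$fraction_female, "female", "male"),
                  levels = c("male", "female"))
    ethnicity <- factor(ifelse(runif(n) < spec$fraction_black, "Black", "White"),
                        levels = c("White", "Black"))
    center <- factor(sample(paste0("C", seq_len(spec$n_centers)), n, replace = TRUE))
    age <- rnorm(n, spec$age_mean, spec$age_sd)

    # Duffy-null allele is common in African-ancestry populations only.
    duffy_freq <- ifelse(ethnicity == "Black", spec$duffy_null_freq, 0.005)
    duffy_dosage <- rbinom(n, 2L, duffy_freq)

    # WBC: genotype shifts centered at the population-expected dosage so the
    # marginal mean stays at wbc_mean.
    expected_dosage <- 2 * (spec$duffy_null_freq * spec$fraction_black +
                              0.005 * (1 - spec$fraction_black))
    wbc <- spec$wbc_mean +
      spec$beta_duffy_on_wbc * (duffy_dosage - expected_dosage) +
      rnorm(n, 0, spec$wbc_sd)

    center_shift <- rnorm(spec$n_centers, 0, spec$center_effect_sd)
    log_cn <- spec$latent_mean +
      spec$beta_age * (age - spec$age_mean) +
      spec$beta_sex * (sex == "female") +
      spec$beta_wbc * (wbc - spec$wbc_mean) +
      spec$beta_duffy_direct * duffy_dosage +
      center_shift[as.integer(center)] +
      rnorm(n, 0, spec$latent_sd)

    # Exponential event times under a proportional-hazards model on the
    # within-cohort z-score of log copy number.
    cn_sd <- safe_sd(log_cn)
    z <- if (is.na(cn_sd) || cn_sd == 0) rep(0, n) else (log_cn - mean(log_cn)) / cn_sd
    hazard <- spec$baseline_hazard * exp(spec$gamma_cvd * z)
    t_event <- ifelse(hazard > 0, rexp(n, hazard), Inf)
    event <- as.integer(t_event <= spec$followup_horizon)
    followup_time <- pmin(t_event, spec$followup_horizon)

    wbc[runif(n) < spec$wbc_missing_rate] <- NA_real_

    tibble(
      id = sprintf("S%05d", seq_len(n)),
      age = age, sex = sex, ethnicity = ethnicity, center = center,
      wbc = wbc, duffy_dosage = duffy_dosage,
      followup_time = followup_time, event = event,
      true_cn = exp(log_cn)
    )
  })
}

#' Summarize one or more cohorts
#'
#' Computes participant-characteristics tables (counts, percentages and
#' mean +/- SD) per cohort, in the layout used for baseline "Table 1"
#' descriptions of epidemiological cohorts.
#'
#' @param cohorts A named list of cohort tibbles as returned by
#'   [generate_cohort()], or a single cohort tibble.
#' @return A tibble with one row per cohort: `n`, female and Black counts and
#'   percentages, age and WBC mean/SD, and incident-event counts.
#' @seealso [pool_cohort_summaries()] to combine rows into a pooled summary.
#' @export
summarize_cohort <- function(cohorts) {
  if (is.data.frame(cohorts)) cohorts <- list(cohort = cohorts)
  if (!is.list(cohorts) || length(cohorts) == 0) {
    abort("`cohorts` must be a cohort table or a non-empty named list of them.")
  }
  if (is.null(names(cohorts)) || any(names(cohorts) == "")) {
    names(cohorts) <- paste0("cohort", seq_along(cohorts))
  }
  rows <- imap(cohorts, function(d, label) {
    if (!is.data.frame(d) || nrow(d) == 0) {
      abort(sprintf("Cohort '%s' is empty.", label))
    }
    check_columns(d, c("age", "sex"), sprintf("cohort '%s'", label))
    n <- nrow(d)
    tibble(
      cohort = label,
      n = n,
      n_female = sum(d$sex == "female", na.rm = TRUE),
      pct_female = 100 * sum(d$sex == "female", na.rm = TRUE) / n,
      n_black = if ("ethnicity" %in% names(d))
        sum(d$ethnicity == "Black", na.rm = TRUE) else NA_integer_,
      pct_black = if ("ethnicity" %in% names(d))
        100 * sum(d$ethnicity == "Black", na.rm = TRUE) / n else NA_real_,
      age_mean = mean(d$age, na.rm = TRUE),
      age_sd = sd(d$age, na.rm = TRUE),
      wbc_mean = if ("wbc" %in% names(d)) mean(d$wbc, na.rm = TRUE) else NA_real_,
      wbc_sd = if ("wbc" %in% names(d)) sd(d$wbc, na.rm = TRUE) else NA_real_,
      n_events = if ("event" %in% names(d))
        sum(d$event, na.rm = TRUE) else NA_integer_,
      pct_events = if ("event" %in% names(d))
        100 * sum(d$event, na.rm = TRUE) / n else NA_real_
    )
  })
  list_rbind(unname(rows))
}

#' Pool per-cohort summaries into a combined summary
#'
#' Combines rows of a [summarize_cohort()] table (or any table with the same
#' naming convention) into one pooled row: `n_*` count columns are summed,
#' `pct_*` columns are recomputed from pooled counts where the matching count
#' column exists (otherwise sample-size weighted), `*_mean` columns are
#' sample-size weighted means, and `*_sd` columns are pooled total SDs
#' combining within- and between-cohort variance.
#'
#' @param summaries A tibble of per-cohort summaries with an `n` column.
#' @param label Label for the pooled row.
#' @return A one-row tibble with the same columns.
#' @examples
#' s <- tibble::tibble(cohort = c("A", "B"), n = c(1085, 3489),
#'                     age_mean = c(57.1, 62.7))
#' pool_cohort_summaries(s)$age_mean  # 61.4
#' @export
pool_cohort_summaries <- function(summaries, label = "pooled") {
  check_columns(summaries, "n", "`summaries`")
  if (nrow(summaries) == 0) abort("`summaries` has no rows.")
  n <- summaries$n
  N <- sum(n)
  out <- list(cohort = label, n = N)
  for (col in setdiff(names(summaries), c("cohort", "n"))) {
    x <- summaries[[col]]
    if (!is.numeric(x)) next
    if (startsWith(col, "n_")) {
      out[[col]] <- sum(x)
    } else if (startsWith(col, "pct_")) {
      count_col <- sub("^pct_", "n_", col)
      out[[col]] <- if (count_col %in% names(summaries)) {
        100 * sum(summaries[[count_col]]) / N
      } else {
        sum(n * x) / N
      }
    } else if (endsWith(col, "_mean")) {
      out[[col]] <- sum(n * x) / N
    } else if (endsWith(col, "_sd")) {
      mean_col <- sub("_sd$", "_mean", col)
      if (mean_col %in% names(summaries)) {
        m <- summaries[[mean_col]]
        pooled_mean <- sum(n * m) / N
        out[[col]] <- sqrt(sum(n * (x^2 + m^2)) / N - pooled_mean^2)
      } else {
        out[[col]] <- NA_real_
      }
    } else {
      out[[col]] <- sum(n * x) / N
    }
  }
  as_tibble(out)
}
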