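#' Run the correlate association battery for each estimation method
#'
#' Tests each platform's harmonized phenotype against the established
#' mtDNA-CN correlates, reproducing the design used to validate estimation
#' methods against one another:
#'
#' * **age, sex, WBC** — ordinary linear regression of the leave-one-out
#'   phenotype (the harmonization model minus the tested covariate) on the
#'   correlate, so effect sizes stay in SD units. The WBC association uses
#'   observed WBC values only.
#' * **Duffy locus** — single-SNP dosage regression restricted to Black
#'   participants, with the WBC-unadjusted phenotype as the dependent
#'   variable (the locus validates copy number through its WBC effect) and
#'   age, sex and collection center as covariates.
#' * **incident CVD** — Cox proportional-hazards regression of follow-up
#'   time and event status on the fully adjusted phenotype; results are
#'   flagged unusable when fewer than 2 events are available.
#'
#' @param estimates A tibble of raw per-sample estimates in long form:
#'   `sample_id`, `method`, `estimate`. Samples excluded by a platform's QC
#'   simply have no row (or `NA`).
#' @param cohort The cohort covariate table (`id`, `age`, `sex`, `center`,
#'   `wbc`, `duffy_dosage`, `ethnicity`, `followup_time`, `event`).
#' @param tech Optional named list (by method) of technical-covariate
#'   tables: a `sample_id` column plus numeric columns (e.g. array
#'   principal components).
#' @param wbc_available Include WBC in the harmonization model and in the
#'   battery (default: `TRUE` when the cohort has any observed WBC).
#' @return A tibble with one row per method x correlate: `method`,
#'   `correlate`, `estimate` (beta or log hazard ratio, SD units), `se`,
#'   `statistic`, `p`, `conf_low`, `conf_high` (hazard-ratio scale for
#'   CVD), `n`, `usable`.
#' @export
run_battery <- function(estimates, cohort, tech = NULL,
                        wbc_available = NULL) {
  check_columns(estimates, c("sample_id", "method", "estimate"), "`estimates`")
  check_columns(cohort, c("id", "age", "sex", "center"), "`cohort`")
  if (is.null(wbc_available)) {
    wbc_available <- "wbc" %in% names(cohort) && any(!is.na(cohort$wbc))
  }
  base_covs <- c("age", "sex", "center")
  full_covs <- if (wbc_available) c(base_covs, "wbc") else base_covs

  methods <- unique(estimates$method)
  rows <- list()
  for (m in methods) {
    d <- cohort |>
      left_join(estimates |> filter(.data$method == m) |>
                  select("sample_id", "estimate"),
                by = c(id = "sample_id"))
    tech_m <- NULL
    if (!is.null(tech) && m %in% names(tech)) {
      tm <- as.data.frame(tech[[m]])
      if (!"sample_id" %in% names(tm)) {
        abort(sprintf("Technical covariates for '%s' need a sample_id column.", m))
      }
      tm <- tm[match(d$id, tm$sample_id), setdiff(names(tm), "sample_id"),
               drop = FALSE]
      tech_m <- tm
    }
    pheno <- function(leave_out = NULL, with_wbc = wbc_available) {
      covs <- if (with_wbc) full_covs else base_covs
      standardize_residuals(d, raw = "estimate", covariates = covs,
                            leave_out = leave_out, tech = tech_m)$phenotype
    }
    lin <- function(correlate, ph, x) {
      ok <- !is.na(ph) & !is.na(x)
      fit <- lm(ph[ok] ~ x[ok])
      sm <- summary(fit)$coefficients
      tibble(method = m, correlate = correlate,
             estimate = sm[2, 1], se = sm[2, 2], statistic = sm[2, 3],
             p = sm[2, 4],
             conf_low = sm[2, 1] - 1.96 * sm[2, 2],
             conf_high = sm[2, 1] + 1.96 * sm[2, 2],
             n = sum(ok), usable = TRUE)
    }
    rows[[paste0(m, "_age")]] <- lin("age", pheno("age"), d$age)
    rows[[paste0(m, "_sex")]] <-
      lin("sex", pheno("sex"), as.numeric(d$sex == "female"))
    if (wbc_available) {
      rows[[paste0(m, "_wbc")]] <- lin("wbc", pheno("wbc"), d$wbc)
    }

    if (all(c("duffy_dosage", "ethnicity") %in% names(cohort))) {
      ph <- pheno(with_wbc = FALSE)
      db <- d |> mutate(.ph = ph) |>
        filter(.data$ethnicity == "Black", !is.na(.data$.ph))
      if (nrow(db) > 10 && var(db$duffy_dosage) > 0) {
        fit <- lm(.ph ~ duffy_dosage + age + sex + center, data = db)
        sm <- summary(fit)$coefficients
        rows[[paste0(m, "_duffy")]] <- tibble(
          method = m, correlate = "duffy",
          estimate = sm["duffy_dosage", 1], se = sm["duffy_dosage", 2],
          statistic = sm["duffy_dosage", 3], p = sm["duffy_dosage", 4],
          conf_low = sm["duffy_dosage", 1] - 1.96 * sm["duffy_dosage", 2],
          conf_high = sm["duffy_dosage", 1] + 1.96 * sm["duffy_dosage", 2],
          n = nrow(db), usable = TRUE)
      }
    }

    if (all(c("followup_time", "event") %in% names(cohort))) {
      ph <- pheno()
      ok <- !is.na(ph) & !is.na(d$followup_time) & !is.na(d$event)
      n_events <- sum(d$event[ok])
      if (n_events >= 2) {
        fit <- survival::coxph(
          survival::Surv(d$followup_time[ok], d$event[ok]) ~ ph[ok])
        sm <- summary(fit)
        rows[[paste0(m, "_cvd")]] <- tibble(
          method = m, correlate = "cvd",
          estimate = sm$coefficients[1, "coef"],
          se = sm$coefficients[1, "se(coef)"],
          statistic = sm$coefficients[1, "z"],
          p = sm$coefficients[1, "Pr(>|z|)"],
          conf_low = sm$conf.int[1, "lower .95"],
          conf_high = sm$conf.int[1, "upper .95"],
          n = sum(ok), usable = TRUE)
      } else {
        rows[[paste0(m, "_cvd")]] <- tibble(
          method = m, correlate = "cvd", estimate = NA_real_, se = NA_real_,
          statistic = NA_real_, p = NA_real_, conf_low = NA_real_,
          conf_high = NA_real_, n = sum(ok), usable = FALSE)
      }
    }
  }
  list_rbind(unname(rows))
}
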