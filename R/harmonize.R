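#' Mean imputation with a log
#'
#' Replaces missing entries by the mean of the observed entries. Used for
#' the white-blood-cell covariate so that samples with missing counts are
#' retained by the harmonization model rather than dropped.
#'
#' @param x Numeric vector, possibly with `NA`s.
#' @return A list: `values` (complete vector), `n_imputed`, `imputed_idx`.
#' @export
impute_mean <- function(x) {
  if (!is.numeric(x)) abort("`x` must be numeric.")
  idx <- which(is.na(x))
  if (length(idx) == length(x)) {
    abort("All values are missing; nothing to impute from.")
  }
  x[idx] <- mean(x, na.rm = TRUE)
  list(values = x, n_imputed = length(idx), imputed_idx = idx)
}

#' Harmonize a raw platform estimate into a standardized phenotype
#'
#' The cross-platform phenotype: standardized residuals from a linear model
#' of the raw copy-number estimate on age, sex, DNA-collection center,
#' technical covariates, and (where the cohort provides it) white blood
#' cell count. Residuals are divided by their standard deviation, so the
#' phenotype has mean 0 and SD 1 and downstream effect sizes are in SD
#' units; because residual standardization is invariant to positive affine
#' rescaling of the raw measure, phenotypes from different platforms are
#' directly comparable.
#'
#' When the phenotype is to be associated with a variable that is itself a
#' model covariate (age, sex, WBC), set `leave_out` to that covariate: the
#' model is then the full model minus the outcome variable, so the tested
#' effect is not regressed away.
#'
#' @param data A tibble containing the raw estimate and all covariates.
#' @param raw Name of the raw-estimate column.
#' @param covariates Character vector of covariate column names. Factor-like
#'   columns are expanded to indicators; numeric covariates with missing
#'   values are mean-imputed (with `impute = TRUE`).
#' @param leave_out Optional single covariate name to omit from the fit;
#'   must be an element of `covariates`.
#' @param tech Optional matrix or data frame of technical covariates
#'   (aligned to `data` rows), always included.
#' @param impute Mean-impute missing numeric covariates (default `TRUE`).
#' @return The input tibble with a `phenotype` column appended (rows with a
#'   missing raw estimate get `NA`).
#' @export
standardize_residuals <- function(data, raw = "estimate",
                                  covariates = c("age", "sex", "center"),
                                  leave_out = NULL, tech = NULL,
                                  impute = TRUE) {
  check_columns(data, c(raw, covariates), "`data`")
  if (!is.null(leave_out)) {
    if (length(leave_out) != 1 || !leave_out %in% covariates) {
      abort("`leave_out` must name one element of `covariates`.")
    }
    covariates <- setdiff(covariates, leave_out)
  }
  y <- data[[raw]]
  use <- !is.na(y)
  n <- sum(use)

  covs <- data[covariates]
  if (impute) {
    covs[] <- lapply(covs, function(v) {
      if (is.numeric(v) && anyNA(v)) impute_mean(v)$values else v
    })
  }
  if (!is.null(tech)) {
    tech <- as.data.frame(tech)
    if (nrow(tech) != nrow(data)) {
      abort("`tech` must have one row per row of `data`.")
    }
    names(tech) <- paste0("tech_", names(tech))
    covs <- bind_cols(covs, tech)
  }
  if (n <= ncol(covs) + 2) {
    abort("Too few non-missing estimates for the covariate model.")
  }
  mm <- model.matrix(~ ., data = covs[use, , drop = FALSE])
  qr_x <- qr(mm)
  if (qr_x$rank < ncol(mm)) {
    bad <- colnames(mm)[qr_x$pivot[-seq_len(qr_x$rank)]]
    abort(sprintf("Rank-deficient design: collinear column(s) %s.",
                  paste(bad, collapse = ", ")))
  }
  r <- lm.fit(mm, y[use])$residuals
  pheno <- rep(NA_real_, nrow(data))
  pheno[use] <- r / sd(r)
  data$phenotype <- pheno
  data
}
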