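#' Whole-genome sequencing read ratio
#'
#' The raw WGS copy-number estimate: mitochondrial reads divided by total
#' aligned reads. No metric adjustment is applied to WGS; its raw calls do
#' not show the large batch effects that exome capture introduces.
#'
#' @param readcounts A tibble with `mito_reads` and `total_aligned_reads`.
#' @return The input with a `ratio` column appended.
#' @export
wgs_ratio <- function(readcounts) {
  check_columns(readcounts, c("mito_reads", "total_aligned_reads"),
                "`readcounts`")
  if (any(readcounts$total_aligned_reads <= 0)) {
    abort("`total_aligned_reads` must be positive.")
  }
  if (any(readcounts$mito_reads < 0 |
            readcounts$mito_reads > readcounts$total_aligned_reads)) {
    abort("`mito_reads` must lie in [0, total_aligned_reads].")
  }
  readcounts |> mutate(ratio = .data$mito_reads / .data$total_aligned_reads)
}

#' Stepwise backward elimination of covariates
#'
#' Starting from the full linear model of `y` on all candidate metrics,
#' repeatedly removes the least significant metric whose coefficient
#' p-value exceeds `alpha_remove` (ties broken by column order, first
#' column removed) until every retained metric is significant, or no
#' metrics remain. Exactly collinear candidates are dropped up front with a
#' warning. An information-criterion mode (`criterion = "aic"`) removes the
#' metric whose deletion lowers AIC most, stopping when no deletion helps.
#'
#' @param y Numeric response vector.
#' @param candidates A data frame of numeric candidate metrics (a
#'   `sample_id` column, if present, is ignored).
#' @param alpha_remove Removal threshold on coefficient p-values
#'   (default 0.05).
#' @param criterion `"pvalue"` (default) or `"aic"`.
#' @return A list: `retained` (character vector of metric names, possibly
#'   empty) and `model` (the final `lm` fit, intercept-only when nothing
#'   is retained).
#' @export
backward_eliminate <- function(y, candidates, alpha_remove = 0.05,
                               criterion = c("pvalue", "aic")) {
  criterion <- match.arg(criterion)
  check_proportion(alpha_remove, "alpha_remove")
  cand <- as.data.frame(candidates)
  cand$sample_id <- NULL
  cand <- cand[vapply(cand, is.numeric, logical(1))]
  if (ncol(cand) > 0 && nrow(cand) != length(y)) {
    abort("`candidates` must have one row per element of `y`.")
  }
  if (ncol(cand) > 0) {
    if (length(y) <= ncol(cand) + 2) {
      abort("Need more samples than candidate metrics plus two.")
    }
    # drop exactly collinear columns before fitting
    X <- cbind(`(Intercept)` = 1, as.matrix(cand))
    qr_x <- qr(X)
    if (qr_x$rank < ncol(X)) {
      drop_cols <- setdiff(colnames(X)[qr_x$pivot[-seq_len(qr_x$rank)]],
                           "(Intercept)")
      warn(sprintf("Dropping collinear candidate(s): %s.",
                   paste(drop_cols, collapse = ", ")))
      cand <- cand[setdiff(names(cand), drop_cols)]
    }
  }
  current <- names(cand)
  fit_model <- function(vars) {
    if (length(vars) == 0) return(lm(y ~ 1))
    d <- data.frame(.y = y, cand[vars])
    lm(.y ~ ., data = d)
  }
  fit <- fit_model(current)
  if (criterion == "pvalue") {
    while (length(current) > 0) {
      cf <- summary(fit)$coefficients
      pv <- cf[-1, 4]
      names(pv) <- rownames(cf)[-1]
      pv <- pv[current]  # keep column order for deterministic ties
      pv[is.na(pv)] <- 0 # degenerate (perfect) fits count as significant
      worst <- which.max(pv)
      if (pv[worst] <= alpha_remove) break
      current <- current[-worst]
      fit <- fit_model(current)
    }
  } else {
    repeat {
      if (length(current) == 0) break
      aic_now <- stats::AIC(fit)
      aic_drop <- vapply(seq_along(current), function(i) {
        stats::AIC(fit_model(current[-i]))
      }, numeric(1))
      best <- which.min(aic_drop)
      if (aic_drop[best] >= aic_now) break
      current <- current[-best]
      fit <- fit_model(current)
    }
  }
  list(retained = current, model = fit)
}

#' Adjust WES ratios for sequencing-metric batch effects
#'
#' Exome capture efficiency and alignment quality distort the raw
#' mitochondrial read ratio. This regresses the ratio on the sequencing
#' metrics retained by [backward_eliminate()] and returns residuals plus
#' the grand mean, so the adjusted estimates keep the original mean. With
#' no retained metric the input is returned unchanged.
#'
#' @param ratios Numeric vector of raw WES ratios.
#' @param metrics A data frame of candidate sequencing metrics, one row per
#'   sample.
#' @param alpha_remove Removal threshold passed to [backward_eliminate()].
#' @param criterion Elimination criterion, see [backward_eliminate()].
#' @return A list: `adjusted` (numeric vector, same mean as input),
#'   `retained` (metric names), `model` (the final fit).
#' @export
wes_adjust <- function(ratios, metrics, alpha_remove = 0.05,
                       criterion = c("pvalue", "aic")) {
  be <- backward_eliminate(ratios, metrics, alpha_remove, criterion)
  adjusted <- if (length(be$retained) == 0) {
    ratios
  } else {
    as.numeric(residuals(be$model)) + mean(ratios)
  }
  list(adjusted = adjusted, retained = be$retained, model = be$model)
}

#' Read a samtools idxstats table into a read-count record
#'
#' Accepts the four-column `samtools idxstats` output (reference, length,
#' mapped, unmapped; no header) and returns the per-sample mitochondrial
#' and total aligned read counts: the mitochondrial row is matched by
#' reference name (`MT`, `chrM`, `chrMT`, or `M`) and the total sums mapped
#' reads over all references.
#'
#' @param path Path to an idxstats-shaped TSV.
#' @param sample_id Sample identifier to attach.
#' @return A one-row tibble: `sample_id`, `mito_reads`,
#'   `total_aligned_reads`.
#' @export
read_idxstats <- function(path, sample_id = basename(path)) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("reference", "length", "mapped",
                                       "unmapped"),
                         stringsAsFactors = FALSE)
  mito <- d$reference %in% c("MT", "chrM", "chrMT", "M")
  if (!any(mito)) abort("No mitochondrial reference (MT/chrM/chrMT/M) found.")
  tibble(sample_id = sample_id,
         mito_reads = sum(d$mapped[mito]),
         total_aligned_reads = sum(d$mapped))
}
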