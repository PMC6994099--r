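#' qPCR replicate quality-control thresholds
#'
#' Thresholds of the replicate-level filters applied to multiplexed qPCR
#' plates before a sample-level delta-Ct is formed: an absolute ceiling on
#' the mitochondrial-target Ct (late amplification means failed wells), and
#' plate-relative outlier rules for the nuclear-target Ct and the delta-Ct.
#'
#' @param nd1_ct_max Maximum acceptable ND1 Ct, cycles (default 28).
#' @param rpph1_sd_max RPPH1 Ct may deviate at most this many plate SDs from
#'   the plate mean (default 5).
#' @param dct_sd_max Delta-Ct may deviate at most this many plate SDs from
#'   the plate mean (default 3).
#' @param sample_dct_sd_max Maximum delta-Ct SD across a sample's replicates
#'   before outlier removal / sample exclusion kicks in (default 0.5).
#' @return An object of class `qpcr_qc_params`.
#' @export
qpcr_qc_params <- function(nd1_ct_max = 28, rpph1_sd_max = 5,
                           dct_sd_max = 3, sample_dct_sd_max = 0.5) {
  for (nm in c("nd1_ct_max", "rpph1_sd_max", "dct_sd_max", "sample_dct_sd_max")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v <= 0) {
      abort(sprintf("`%s` must be a single positive number.", nm))
    }
  }
  structure(list(nd1_ct_max = nd1_ct_max, rpph1_sd_max = rpph1_sd_max,
                 dct_sd_max = dct_sd_max, sample_dct_sd_max = sample_dct_sd_max),
            class = "qpcr_qc_params")
}

#' Compute per-replicate delta-Ct
#'
#' Adds the raw relative copy-number measure `dct = ct_rpph1 - ct_nd1` to a
#' replicate table. With this sign convention a larger delta-Ct means more
#' mitochondrial DNA (the mitochondrial target crosses threshold earlier the
#' more template is present), and a four-fold difference in copy number
#' moves delta-Ct by exactly 2 cycles. Replicates with a missing Ct get
#' `dct = NA` and `dct_missing = TRUE` rather than an error.
#'
#' @param replicates A tibble with columns `ct_nd1` and `ct_rpph1`.
#' @return The input with `dct` and `dct_missing` columns appended.
#' @export
delta_ct <- function(replicates) {
  check_columns(replicates, c("ct_nd1", "ct_rpph1"), "`replicates`")
  replicates |>
    mutate(dct = .data$ct_rpph1 - .data$ct_nd1,
           dct_missing = is.na(.data$dct))
}

#' Filter qPCR replicates by plate-level quality rules
#'
#' Applies the replicate filters sequentially, so each removed replicate
#' carries exactly one (first-failing) reason: missing Ct values
#' (`MISSING_CT`), ND1 Ct above the absolute ceiling (`ND1_CT_HIGH`), RPPH1
#' Ct more than `rpph1_sd_max` SDs from its plate mean (`RPPH1_OUTLIER`),
#' and delta-Ct more than `dct_sd_max` SDs from its plate mean
#' (`DCT_OUTLIER`). Each plate-relative rule recomputes the plate mean and
#' SD from the replicates that survived the earlier rules; a plate left with
#' fewer than two usable replicates skips the SD rules with a warning (the
#' absolute ND1 rule is always applied).
#'
#' @param replicates A replicate tibble with `sample_id`, `plate_id`,
#'   `ct_nd1`, `ct_rpph1` (a `dct` column is added if absent).
#' @param params A [qpcr_qc_params()].
#' @return A list: `kept` (surviving replicates) and `exclusions` (one row
#'   per removed replicate with its `reason`). Rows in `kept` plus
#'   `exclusions` account for every input row.
#' @export
filter_replicates <- function(replicates, params = qpcr_qc_params()) {
  check_columns(replicates, c("sample_id", "plate_id", "ct_nd1", "ct_rpph1"),
                "`replicates`")
  stopifnot(inherits(params, "qpcr_qc_params"))
  if (!"dct" %in% names(replicates)) replicates <- delta_ct(replicates)
  x <- replicates |> mutate(.row = dplyr::row_number(), .reason = NA_character_)

  flag <- function(x, cond, reason) {
    hit <- is.na(x$.reason) & cond
    x$.reason[hit] <- reason
    x
  }
  x <- flag(x, is.na(x$ct_nd1) | is.na(x$ct_rpph1), "MISSING_CT")
  x <- flag(x, !is.na(x$ct_nd1) & x$ct_nd1 > params$nd1_ct_max, "ND1_CT_HIGH")

  plate_rule <- function(x, col, k, reason) {
    stats <- x |>
      filter(is.na(.data$.reason)) |>
      group_by(.data$plate_id) |>
      summarize(.m = mean(.data[[col]]), .s = safe_sd(.data[[col]]),
                .n = dplyr::n(), .groups = "drop")
    small <- stats$plate_id[stats$.n < 2]
    if (length(small) > 0) {
      warn(sprintf("Plate(s) %s have < 2 usable replicates; %s rule skipped there.",
                   paste(small, collapse = ", "), reason))
    }
    x <- left_join(x, stats, by = "plate_id")
    cond <- is.na(x$.reason) & !is.na(x$.s) & x$.s > 0 &
      abs(x[[col]] - x$.m) > k * x$.s
    x$.reason[cond] <- reason
    x |> select(-".m", -".s", -".n")
  }
  x <- plate_rule(x, "ct_rpph1", params$rpph1_sd_max, "RPPH1_OUTLIER")
  x <- plate_rule(x, "dct", params$dct_sd_max, "DCT_OUTLIER")

  list(
    kept = x |> filter(is.na(.data$.reason)) |> select(-".row", -".reason"),
    exclusions = x |>
      filter(!is.na(.data$.reason)) |>
      select("sample_id", "plate_id", row = ".row", reason = ".reason")
  )
}

#' Correct delta-Ct for pipetting-order drift
#'
#' Multichannel pipetting introduces a slow linear drift of delta-Ct with
#' well position. This removes it by least squares at the replicate level,
#' before averaging: within each plate, delta-Ct is regressed on pipetting
#' order with sample intercepts, so the drift slope is identified from
#' within-sample variation only (samples occupy consecutive wells, and a
#' plain regression would confound real copy-number differences with the
#' drift). Each replicate is then corrected by subtracting
#' `slope * (order - mean order)`, which preserves sample and plate means.
#' When every sample contributes a single replicate, the within-sample
#' estimator is undefined and a plain regression of delta-Ct on order is
#' used instead. Plates with fewer than 3 usable replicates or no variation
#' in order are passed through unchanged.
#'
#' @param replicates A replicate tibble with `sample_id`, `plate_id`,
#'   `pipetting_order` and `dct`.
#' @return The input with `dct` replaced by its order-corrected value. The
#'   per-plate fitted slopes and their standard errors are attached as the
#'   `"slopes"` attribute (a tibble `plate_id`, `slope`, `slope_se`).
#' @export
pipetting_correction <- function(replicates) {
  check_columns(replicates, c("sample_id", "plate_id", "pipetting_order",
                              "dct"), "`replicates`")
  out <- replicates
  slopes <- list()
  for (pl in unique(out$plate_id)) {
    idx <- which(out$plate_id == pl & !is.na(out$dct))
    ord <- out$pipetting_order[idx]
    d <- out$dct[idx]
    sid <- out$sample_id[idx]
    if (length(idx) < 3 || length(unique(ord)) < 2) {
      slopes[[pl]] <- tibble(plate_id = pl, slope = NA_real_,
                             slope_se = NA_real_)
      next
    }
    within <- any(duplicated(sid))
    if (within) {
      o_c <- ord - ave(ord, sid, FUN = mean)
      d_c <- d - ave(d, sid, FUN = mean)
      sxx <- sum(o_c^2)
      if (sxx == 0) {
        slopes[[pl]] <- tibble(plate_id = pl, slope = NA_real_,
                               slope_se = NA_real_)
        next
      }
      slope <- sum(o_c * d_c) / sxx
      resid <- d_c - slope * o_c
      df <- length(idx) - length(unique(sid)) - 1L
      se <- if (df > 0) sqrt(sum(resid^2) / df / sxx) else NA_real_
    } else {
      fit <- lm(d ~ ord)
      slope <- coef(fit)[["ord"]]
      se <- summary(fit)$coefficients["ord", 2]
    }
    out$dct[idx] <- d - slope * (ord - mean(ord))
    slopes[[pl]] <- tibble(plate_id = pl, slope = slope, slope_se = se)
  }
  attr(out, "slopes") <- list_rbind(unname(slopes))
  out
}

#' Collapse replicates to one delta-Ct per sample
#'
#' Implements the sample-level outlier rule: if the SD of a sample's
#' delta-Ct replicates exceeds `sample_dct_sd_max`, the replicate farthest
#' from the sample median is dropped (first occurrence on ties) and the SD
#' re-tested, as long as at least two replicates would remain. A sample
#' whose SD stays above the threshold is excluded (`SAMPLE_DCT_SD`); a
#' sample with no surviving replicates is excluded (`NO_REPLICATES`).
#' Surviving samples get the mean delta-Ct of their retained replicates. A
#' single surviving replicate has no SD to test and is kept as is.
#'
#' @param replicates A filtered replicate tibble with `sample_id`,
#'   `plate_id` and `dct`.
#' @param sample_dct_sd_max SD threshold, cycles (default 0.5).
#' @return A list: `estimates` (tibble `sample_id`, `plate_id`, `dct`,
#'   `n_replicates_used`), `survivors` (the retained replicate rows, for
#'   further replicate-level processing), `dropped_replicates` (outlier
#'   replicates removed here), and `exclusions` (samples excluded outright,
#'   with reasons).
#' @export
resolve_samples <- function(replicates, sample_dct_sd_max = 0.5) {
  check_columns(replicates, c("sample_id", "plate_id", "dct"), "`replicates`")
  all_samples <- unique(replicates$sample_id)
  usable <- replicates |> filter(!is.na(.data$dct)) |>
    mutate(.rid = dplyr::row_number())
  summ <- usable |>
    group_by(.data$sample_id) |>
    summarize(plate_id = dplyr::first(.data$plate_id),
              dct_mean = mean(.data$dct), dct_sd = safe_sd(.data$dct),
              n_replicates_used = dplyr::n(), .groups = "drop")

  empty <- setdiff(all_samples, summ$sample_id)
  excl <- if (length(empty)) tibble(sample_id = empty, reason = "NO_REPLICATES") else
    tibble(sample_id = character(), reason = character())

  needs_work <- summ$sample_id[!is.na(summ$dct_sd) &
                                 summ$dct_sd > sample_dct_sd_max]
  dropped_rows <- usable[0, ]
  for (sid in needs_work) {
    rows <- usable[usable$sample_id == sid, ]
    x <- rows$dct
    keep <- rep(TRUE, length(x))
    while (sum(keep) >= 3 && safe_sd(x[keep]) > sample_dct_sd_max) {
      kept_idx <- which(keep)
      far <- kept_idx[which.max(abs(x[kept_idx] - median(x[kept_idx])))]
      keep[far] <- FALSE
    }
    s <- safe_sd(x[keep])
    i <- which(summ$sample_id == sid)
    if (!is.na(s) && s > sample_dct_sd_max) {
      excl <- bind_rows(excl, tibble(sample_id = sid, reason = "SAMPLE_DCT_SD"))
      summ <- summ[-i, ]
    } else {
      dropped_rows <- bind_rows(dropped_rows, rows[!keep, ])
      summ$dct_mean[i] <- mean(x[keep])
      summ$n_replicates_used[i] <- sum(keep)
    }
  }
  survivors <- usable |>
    filter(.data$sample_id %in% summ$sample_id,
           !.data$.rid %in% dropped_rows$.rid) |>
    select(-".rid")
  list(
    estimates = summ |>
      select("sample_id", "plate_id", dct = "dct_mean", "n_replicates_used"),
    survivors = survivors,
    dropped_replicates = dropped_rows |> select(-dplyr::any_of(".rid")),
    exclusions = excl
  )
}

#' Remove plate effects as a random intercept
#'
#' Subtracts shrunken plate means: plates are modeled as a random intercept
#' and each plate's deviation from the grand mean is shrunk by the
#' balanced-design best linear unbiased predictor (BLUP) weight
#' \eqn{w_j = \sigma_b^2 / (\sigma_b^2 + \sigma_e^2 / n_j)}, with variance
#' components estimated by the one-way ANOVA method of moments (equivalent
#' to REML in the balanced case). When any plate holds fewer than 3 values,
#' the method falls back to simple per-plate mean-centering with a warning.
#'
#' @param x Numeric vector of per-sample values.
#' @param plate Plate identifier vector, same length as `x`.
#' @param preserve_mean If `FALSE` (default, relative measures) the output
#'   is also grand-mean-centered; if `TRUE` (absolute measures) the grand
#'   mean is retained.
#' @return Numeric vector of plate-adjusted values.
#' @export
plate_adjust <- function(x, plate, preserve_mean = FALSE) {
  if (length(x) != length(plate)) abort("`x` and `plate` must have equal length.")
  ok <- !is.na(x)
  plate <- as.character(plate)
  grand <- mean(x[ok])
  n_j <- tapply(x[ok], plate[ok], length)
  m_j <- tapply(x[ok], plate[ok], mean)
  J <- length(n_j)
  out <- x
  if (J == 1L) {
    blup <- setNames(0, names(n_j))
  } else if (any(n_j < 3)) {
    warn("Plate(s) with < 3 values: falling back to simple plate mean-centering.")
    blup <- m_j - grand
  } else {
    N <- sum(n_j)
    ssw <- sum(tapply(x[ok], plate[ok], function(v) sum((v - mean(v))^2)))
    msw <- ssw / (N - J)
    ssb <- sum(n_j * (m_j - grand)^2)
    msb <- ssb / (J - 1)
    n0 <- (N - sum(n_j^2) / N) / (J - 1)
    sigma_b2 <- max(0, (msb - msw) / n0)
    w <- sigma_b2 / (sigma_b2 + msw / n_j)
    blup <- w * (m_j - grand)
  }
  out[ok] <- x[ok] - blup[plate[ok]]
  if (!preserve_mean) out[ok] <- out[ok] - mean(out[ok])
  out
}

#' Full qPCR estimation pipeline
#'
#' Chains the stages in the order the protocol applies them: delta-Ct
#' computation, replicate-level quality filters, sample-level outlier
#' resolution, pipetting-order correction of the surviving replicates,
#' averaging to one delta-Ct per sample, and random-intercept plate
#' adjustment — producing a raw relative copy-number estimate per
#' surviving sample (grand mean zero; on noise-free input it is an affine
#' function of log2 true copy number).
#'
#' @param replicates A replicate tibble (`sample_id`, `plate_id`,
#'   `pipetting_order`, `ct_nd1`, `ct_rpph1`).
#' @param params A [qpcr_qc_params()].
#' @return A list: `estimates` (tibble `sample_id`, `plate_id`, `estimate`,
#'   `n_replicates_used`) and `exclusions` (replicate- and sample-level
#'   exclusion log with `level` and `reason`).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_individuals = 40, seed = 3))
#' reps <- generate_qpcr_plates(cohort, platform_noise_spec(seed = 3))
#' res <- qpcr_estimate(reps)
#' head(res$estimates)
#' @export
qpcr_estimate <- function(replicates, params = qpcr_qc_params()) {
  filt <- replicates |> delta_ct() |> filter_replicates(params)
  resolved <- resolve_samples(filt$kept, params$sample_dct_sd_max)
  corrected <- pipetting_correction(resolved$survivors)
  est <- corrected |>
    group_by(.data$sample_id) |>
    summarize(plate_id = dplyr::first(.data$plate_id),
              dct = mean(.data$dct),
              n_replicates_used = dplyr::n(), .groups = "drop")
  est$estimate <- plate_adjust(est$dct, est$plate_id, preserve_mean = FALSE)
  exclusions <- bind_rows(
    filt$exclusions |> mutate(level = "replicate") |>
      select("sample_id", "reason", "level"),
    resolved$dropped_replicates |>
      mutate(level = "replicate", reason = "SAMPLE_SD_OUTLIER") |>
      select("sample_id", "reason", "level"),
    resolved$exclusions |> mutate(level = "sample")
  )
  list(estimates = est |> select("sample_id", "plate_id", "estimate",
                                 "n_replicates_used"),
       exclusions = exclusions)
}
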