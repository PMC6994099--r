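#' Array autosomal-probe quality filters
#'
#' Thresholds for selecting the autosomal SNP probes whose intensities feed
#' the technical-covariate analysis: per-probe call rate, Hardy-Weinberg
#' equilibrium, non-random missingness ("mishap") with respect to flanking
#' genotypes, association with sex, pairwise linkage-disequilibrium
#' pruning, and position-based thinning.
#'
#' @param call_rate_min Minimum call rate (default 0.98).
#' @param hwe_p_min Minimum exact Hardy-Weinberg p-value (default 1e-5).
#' @param mishap_p_min Minimum p-value for the missingness-vs-flanking
#'   genotype contingency test (default 1e-4).
#' @param sex_assoc_p_min Minimum p-value for genotype-sex association
#'   (default 1e-5).
#' @param ld_r2_max Maximum allowed squared correlation with an
#'   already-kept probe on the same chromosome (default 0.30).
#' @param spacing_bp Thinning window in base pairs (default 41,700): after
#'   LD pruning at most one probe is kept per window, walking each
#'   chromosome left to right.
#' @return An object of class `array_qc_params`.
#' @export
array_qc_params <- function(call_rate_min = 0.98, hwe_p_min = 1e-5,
                            mishap_p_min = 1e-4, sex_assoc_p_min = 1e-5,
                            ld_r2_max = 0.30, spacing_bp = 41700) {
  check_proportion(call_rate_min, "call_rate_min")
  check_proportion(hwe_p_min, "hwe_p_min")
  check_proportion(mishap_p_min, "mishap_p_min")
  check_proportion(sex_assoc_p_min, "sex_assoc_p_min")
  if (ld_r2_max <= 0 || ld_r2_max >= 1) abort("`ld_r2_max` must be in (0, 1).")
  check_nonneg(spacing_bp, "spacing_bp")
  structure(list(call_rate_min = call_rate_min, hwe_p_min = hwe_p_min,
                 mishap_p_min = mishap_p_min, sex_assoc_p_min = sex_assoc_p_min,
                 ld_r2_max = ld_r2_max, spacing_bp = spacing_bp),
            class = "array_qc_params")
}

# Exact Hardy-Weinberg equilibrium test (two-sided, summing genotype
# configurations no more probable than the observed one). Standard exact
# formulation on heterozygote counts given the minor-allele count.
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_rare <- 2 * min(n_aa, n_bb) + n_ab
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  # unnormalized log-probabilities of each possible heterozygote count
  logp <- vapply(hets, function(h) {
    rare_hom <- (n_rare - h) / 2
    common_hom <- n - h - rare_hom
    lgamma(n + 1) - lgamma(h + 1) - lgamma(rare_hom + 1) -
      lgamma(common_hom + 1) + h * log(2)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- which(hets == n_ab)
  sum(p[p <= p[obs] + 1e-12])
}

contingency_p <- function(tab) {
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) return(1)
  # too few observations in the rarer row to assess non-randomness
  if (min(rowSums(tab)) < 5) return(1)
  suppressWarnings(chisq.test(tab)$p.value)
}

#' Select autosomal probes by sequential quality filters
#'
#' Applies the quality filters in a fixed order, each probe receiving the
#' first reason for which it fails: `CALL_RATE`, `HWE` (exact test),
#' `MISHAP` (chi-square of the probe's missingness against each physically
#' adjacent probe's genotype, minimum p over flanks), `SEX_ASSOC`
#' (chi-square of genotype counts by sex, skipped when `sex` is `NULL`),
#' `LD_PRUNE` (greedy left-to-right within chromosome: a probe is dropped
#' when its squared genotype correlation with any already-kept probe on the
#' chromosome reaches `ld_r2_max`), and `SPACING` (at most one kept probe
#' per `spacing_bp` window, walking left to right). Mitochondrial and other
#' non-autosomal probes are ignored.
#'
#' @param genotypes A samples-by-probes matrix coded 0/1/2 with `NA` for
#'   missing calls; column names are probe ids.
#' @param annotations Probe annotation tibble with `probe_id`, `chromosome`,
#'   `position`, `is_mito`.
#' @param params An [array_qc_params()].
#' @param sex Optional factor of sample sex for the sex-association filter.
#' @return A list: `kept` (character vector of probe ids) and `log` (tibble
#'   `probe_id`, `kept`, `reason`; kept and removed probes partition the
#'   autosomal input).
#' @export
select_autosomal_snps <- function(genotypes, annotations,
                                  params = array_qc_params(), sex = NULL) {
  if (is.null(dim(genotypes)) || nrow(genotypes) == 0 || ncol(genotypes) == 0) {
    abort("`genotypes` must be a non-empty samples-by-probes matrix.")
  }
  check_columns(annotations, c("probe_id", "chromosome", "position"),
                "`annotations`")
  auto <- annotations |>
    filter(!.data$chromosome %in% c("MT", "M", "chrM", "X", "Y"),
           if ("is_mito" %in% names(annotations)) !.data$is_mito else TRUE) |>
    arrange(.data$chromosome, .data$position)
  auto <- auto |> filter(.data$probe_id %in% colnames(genotypes))
  if (nrow(auto) == 0) abort("No autosomal probes found in `genotypes`.")
  g <- genotypes[, auto$probe_id, drop = FALSE]
  n_probe <- ncol(g)
  reason <- setNames(rep(NA_character_, n_probe), auto$probe_id)

  call_rate <- colMeans(!is.na(g))
  reason[is.na(reason) & call_rate < params$call_rate_min] <- "CALL_RATE"

  for (j in which(is.na(reason))) {
    counts <- tabulate(g[, j] + 1L, nbins = 3L)
    if (hwe_exact_p(counts[1], counts[2], counts[3]) <= params$hwe_p_min) {
      reason[j] <- "HWE"
    }
  }

  # mishap: missingness of probe j vs genotype at the flanking probes
  has_missing <- colSums(is.na(g)) > 0
  for (j in which(is.na(reason) & has_missing)) {
    flanks <- c(j - 1L, j + 1L)
    flanks <- flanks[flanks >= 1 & flanks <= n_probe &
                       auto$chromosome[pmax(pmin(flanks, n_probe), 1)] ==
                       auto$chromosome[j]]
    if (length(flanks) == 0) next
    miss <- factor(is.na(g[, j]), levels = c(FALSE, TRUE))
    p_fl <- vapply(flanks, function(f) {
      contingency_p(table(miss, factor(g[, f], levels = 0:2)))
    }, numeric(1))
    if (min(p_fl) <= params$mishap_p_min) reason[j] <- "MISHAP"
  }

  if (!is.null(sex)) {
    for (j in which(is.na(reason))) {
      p <- contingency_p(table(factor(g[, j], levels = 0:2), sex))
      if (p <= params$sex_assoc_p_min) reason[j] <- "SEX_ASSOC"
    }
  }

  # greedy LD pruning, left to right within chromosome
  for (chr in unique(auto$chromosome)) {
    idx <- which(auto$chromosome == chr & is.na(reason))
    kept_idx <- integer(0)
    for (j in idx) {
      if (length(kept_idx) > 0) {
        r2 <- suppressWarnings(
          cor(g[, j], g[, kept_idx, drop = FALSE],
              use = "pairwise.complete.obs"))^2
        if (any(r2 >= params$ld_r2_max, na.rm = TRUE)) {
          reason[j] <- "LD_PRUNE"
          next
        }
      }
      kept_idx <- c(kept_idx, j)
    }
  }

  # position thinning after pruning
  if (params$spacing_bp > 0) {
    for (chr in unique(auto$chromosome)) {
      idx <- which(auto$chromosome == chr & is.na(reason))
      last_pos <- -Inf
      for (j in idx) {
        if (auto$position[j] - last_pos < params$spacing_bp) {
          reason[j] <- "SPACING"
        } else {
          last_pos <- auto$position[j]
        }
      }
    }
  }

  log <- tibble(probe_id = auto$probe_id, kept = is.na(reason),
                reason = unname(reason))
  list(kept = auto$probe_id[is.na(reason)], log = log)
}

#' Median homozygous mitochondrial log R ratio
#'
#' The raw array copy-number estimate: per sample, the median LRR across
#' mitochondrial probes at which that sample's genotype call is homozygous
#' (heterozygous calls indicate cross-hybridization or contamination and
#' are masked; missing calls are masked too). Samples with no homozygous
#' mitochondrial call get `NA` and are flagged.
#'
#' @param lrr Samples-by-probes LRR matrix.
#' @param genotypes Matching genotype matrix (0/1/2/NA).
#' @param annotations Probe annotation tibble with `probe_id` and `is_mito`.
#' @return A tibble: `sample_id`, `raw_estimate`, `n_probes_used`,
#'   `no_homozygous_calls`.
#' @export
mito_raw_estimate <- function(lrr, genotypes, annotations) {
  check_columns(annotations, c("probe_id", "is_mito"), "`annotations`")
  mito <- intersect(annotations$probe_id[annotations$is_mito], colnames(lrr))
  if (length(mito) == 0) abort("No mitochondrial probes present in `lrr`.")
  lm_ <- lrr[, mito, drop = FALSE]
  gm <- genotypes[, mito, drop = FALSE]
  hom <- !is.na(gm) & (gm == 0 | gm == 2)
  vals <- lm_
  vals[!hom] <- NA
  est <- apply(vals, 1, median, na.rm = TRUE)
  n_used <- rowSums(!is.na(vals))
  tibble(
    sample_id = rownames(lrr) %||% as.character(seq_len(nrow(lrr))),
    raw_estimate = unname(ifelse(n_used > 0, est, NA_real_)),
    n_probes_used = unname(n_used),
    no_homozygous_calls = unname(n_used == 0)
  )
}

#' GC-content correction
#'
#' Removes GC-dependent intensity waves by quadratic least squares: values
#' are regressed on GC fraction and its square, and replaced by the
#' residuals plus the original mean. Used per sample across probes (the
#' wave is a sample-level artifact of whole-genome amplification); a
#' sample-level variant regresses per-sample summary estimates on a
#' per-sample mean GC exposure. Degenerate GC (constant) passes values
#' through unchanged.
#'
#' @param values Numeric vector.
#' @param gc_fraction GC fractions in \[0, 1\], same length.
#' @return Corrected numeric vector with the same mean.
#' @export
gc_correct <- function(values, gc_fraction) {
  if (length(values) != length(gc_fraction)) {
    abort("`values` and `gc_fraction` must have equal length.")
  }
  ok <- !is.na(values) & !is.na(gc_fraction)
  if (sum(ok) < 3 || length(unique(gc_fraction[ok])) < 3) return(values)
  fit <- lm(values[ok] ~ gc_fraction[ok] + I(gc_fraction[ok]^2))
  out <- values
  out[ok] <- residuals(fit) + mean(values[ok])
  out
}

# GC-correct each sample (row) of an LRR matrix, with wave coefficients
# estimated on a reference set of probes (typically autosomal, so the
# mitochondrial copy-number signal cannot leak into the fit) and the fitted
# wave subtracted from all probes.
gc_correct_matrix <- function(lrr, gc_fraction, fit_probes = NULL) {
  stopifnot(ncol(lrr) == length(gc_fraction))
  fit_idx <- if (is.null(fit_probes)) seq_len(ncol(lrr)) else fit_probes
  gcc <- gc_fraction - mean(gc_fraction[fit_idx])
  X <- cbind(1, gcc[fit_idx], gcc[fit_idx]^2)
  # per-sample coefficients in one pass: solve (X'X) B = X'Y
  B <- solve(crossprod(X), crossprod(X, t(lrr[, fit_idx, drop = FALSE])))
  wave <- t(rbind(0, gcc, gcc^2)) %*% B  # intercept stays with the sample
  lrr - t(wave)
}

#' Technical covariates by principal component analysis
#'
#' Captures shared technical structure (DNA quality and quantity,
#' hybridization efficiency, batch) as the first `k` principal components
#' of the samples-by-probes autosomal LRR matrix. Columns (probes) are
#' mean-centered; scores are unit-norm left singular vectors with a
#' deterministic sign convention (the largest-magnitude probe loading of
#' each component is positive).
#'
#' @param lrr Samples-by-probes LRR matrix of quality-filtered autosomal
#'   probes.
#' @param k Number of components (0 gives an empty matrix).
#' @return A samples-by-`k` matrix of scores (columns `PC1`..`PCk`), with
#'   probe loadings in the `"loadings"` attribute.
#' @export
technical_covariates <- function(lrr, k = 10) {
  check_count(k, "k", min = 0L)
  n <- nrow(lrr)
  if (k == 0) {
    return(matrix(numeric(0), nrow = n, ncol = 0,
                  dimnames = list(rownames(lrr), NULL)))
  }
  x <- scale(lrr, center = TRUE, scale = FALSE)
  s <- svd(x, nu = min(n, ncol(x)), nv = min(n, ncol(x)))
  rank <- sum(s$d > s$d[1] * 1e-10)
  if (k > rank) {
    abort(sprintf("k = %d exceeds the rank (%d) of the centered LRR matrix.",
                  k, rank))
  }
  u <- s$u[, seq_len(k), drop = FALSE]
  v <- s$v[, seq_len(k), drop = FALSE]
  for (i in seq_len(k)) {
    j <- which.max(abs(v[, i]))
    if (v[j, i] < 0) {
      u[, i] <- -u[, i]
      v[, i] <- -v[, i]
    }
  }
  dimnames(u) <- list(rownames(lrr), paste0("PC", seq_len(k)))
  attr(u, "loadings") <- v
  u
}

#' Full array estimation pipeline
#'
#' Chains the array stages: per-sample GC-wave correction (wave fitted on
#' autosomal probes, subtracted everywhere), the median homozygous
#' mitochondrial LRR as the raw estimate, sequential autosomal probe
#' selection, and principal-component technical covariates from the kept
#' autosomal probes.
#'
#' @param lrr Samples-by-probes LRR matrix.
#' @param genotypes Matching genotype matrix.
#' @param annotations Probe annotation tibble (`probe_id`, `chromosome`,
#'   `position`, `gc_fraction`, `is_mito`).
#' @param params An [array_qc_params()].
#' @param k Number of technical principal components (default 10, capped at
#'   the available rank).
#' @param sex Optional sample sex factor for the sex-association filter.
#' @return A list: `estimates` (tibble from [mito_raw_estimate()]),
#'   `covariates` (samples x k PC matrix), `probe_log` (selection log).
#' @export
array_estimate <- function(lrr, genotypes, annotations,
                           params = array_qc_params(), k = 10, sex = NULL) {
  check_columns(annotations, c("probe_id", "chromosome", "position",
                               "gc_fraction", "is_mito"), "`annotations`")
  ann <- annotations |> filter(.data$probe_id %in% colnames(lrr))
  lrr <- lrr[, ann$probe_id, drop = FALSE]
  auto_idx <- which(!ann$is_mito)
  lrr_gc <- gc_correct_matrix(lrr, ann$gc_fraction, fit_probes = auto_idx)
  est <- mito_raw_estimate(lrr_gc, genotypes, ann)
  sel <- select_autosomal_snps(genotypes, ann, params, sex = sex)
  kept_lrr <- lrr_gc[, sel$kept, drop = FALSE]
  # cap the component count at the numerical rank of the centered matrix
  centered <- scale(kept_lrr, center = TRUE, scale = FALSE)
  rank <- if (length(centered) == 0) 0L else qr(centered)$rank
  k_eff <- max(0L, min(k, rank, length(sel$kept) - 1L, nrow(lrr) - 1L))
  covs <- technical_covariates(kept_lrr, k = k_eff)
  list(estimates = est, covariates = covs, probe_log = sel$log)
}
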