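#' Center values to zero mean within each plate
#'
#' Subtracts each plate's mean, removing run/plate intercepts so that
#' replicate values measured on different plates become comparable.
#'
#' @param data A tibble with a value column and a plate column.
#' @param value,plate Column names (defaults `value`, `plate_id`).
#' @return The input with the value column centered within plate.
#' @export
plate_mean_zero <- function(data, value = "value", plate = "plate_id") {
  check_columns(data, c(value, plate), "`data`")
  data[[value]] <- data[[value]] -
    ave(data[[value]], data[[plate]], FUN = mean)
  data
}

#' Average replicate measurements across runs
#'
#' Collapses the run dimension: one value per method x replicate, the mean
#' over that replicate's runs. Replicates with missing runs are averaged
#' over the runs available, with a warning.
#'
#' @param data A tibble with `method`, `replicate_id`, `run_id`, `value`.
#' @return A tibble `method`, `replicate_id`, `value`, `n_runs`.
#' @export
average_runs <- function(data) {
  check_columns(data, c("method", "replicate_id", "run_id", "value"), "`data`")
  out <- data |>
    filter(!is.na(.data$value)) |>
    group_by(.data$method, .data$replicate_id) |>
    summarize(value = mean(.data$value), n_runs = dplyr::n(), .groups = "drop")
  expected <- length(unique(data$run_id))
  if (any(out$n_runs < expected)) {
    warn(sprintf("%d replicate(s) averaged over fewer than %d runs.",
                 sum(out$n_runs < expected), expected))
  }
  out
}

#' Two-sided variance-ratio F-test
#'
#' Tests the null hypothesis that two extraction methods produce equally
#' variable copy-number estimates: `F = var(x) / var(y)` on
#' `(n_x - 1, n_y - 1)` degrees of freedom, with the two-sided p-value
#' twice the smaller tail probability (capped at 1). Swapping `x` and `y`
#' inverts F but leaves the p-value unchanged.
#'
#' @param x,y Numeric vectors with at least 2 values each.
#' @return A one-row tibble: `f`, `df1`, `df2`, `p_value`, `conf_low`,
#'   `conf_high` (95% CI for the variance ratio).
#' @export
var_f_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    abort("Each group needs at least 2 values.")
  }
  if (var(y) == 0) abort("Zero variance in the denominator group.")
  ht <- var.test(x, y, alternative = "two.sided")
  tibble(f = unname(ht$statistic),
         df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2]),
         p_value = ht$p.value,
         conf_low = ht$conf.int[1], conf_high = ht$conf.int[2])
}

#' Welch two-sample test of mean difference
#'
#' Tests whether two extraction methods yield different mean copy-number
#' estimates. Welch's unequal-variance t-test is used because the groups
#' being compared demonstrably differ in variance.
#'
#' @param x,y Numeric vectors.
#' @return A one-row tibble: `t`, `df`, `p_value`, `mean_diff`, `conf_low`,
#'   `conf_high`.
#' @export
mean_diff_test <- function(x, y) {
  ht <- t.test(x, y)
  tibble(t = unname(ht$statistic), df = unname(ht$parameter),
         p_value = ht$p.value,
         mean_diff = unname(ht$estimate[1] - ht$estimate[2]),
         conf_low = ht$conf.int[1], conf_high = ht$conf.int[2])
}

#' Compare DNA-extraction methods for reproducibility
#'
#' The full extraction-comparison pipeline: plate mean-zeroing, run
#' averaging, per-method variance of the replicate values, and all pairwise
#' variance F-tests and Welch mean-difference tests.
#'
#' @param data A replicate tibble as from
#'   [generate_extraction_replicates()]: `method`, `replicate_id`,
#'   `run_id`, `plate_id`, `value`.
#' @return An object of class `extraction_comparison`: a list with
#'   `method_stats` (per-method n, mean, variance), `pairwise` (per method
#'   pair: F, p, t, p), and `replicate_values` (the processed values). Use
#'   [tidy()] / [glance()] / [autoplot()].
#' @export
compare_extractions <- function(data) {
  check_columns(data, c("method", "replicate_id", "run_id", "plate_id",
                        "value"), "`data`")
  vals <- data |> plate_mean_zero() |> average_runs()
  stats_tbl <- vals |>
    group_by(.data$method) |>
    summarize(n = dplyr::n(), mean = mean(.data$value),
              variance = var(.data$value), .groups = "drop")
  methods <- stats_tbl$method
  pairs <- if (length(methods) >= 2) {
    combn(methods, 2, simplify = FALSE)
  } else list()
  pairwise <- list_rbind(map(pairs, function(pr) {
    x <- vals$value[vals$method == pr[1]]
    y <- vals$value[vals$method == pr[2]]
    ft <- var_f_test(x, y)
    tt <- mean_diff_test(x, y)
    tibble(method_a = pr[1], method_b = pr[2],
           f = ft$f, f_p = ft$p_value,
           t = tt$t, t_p = tt$p_value, mean_diff = tt$mean_diff)
  }))
  structure(list(method_stats = stats_tbl, pairwise = pairwise,
                 replicate_values = vals),
            class = "extraction_comparison")
}

#' @export
print.extraction_comparison <- function(x, ...) {
  cat("<extraction_comparison>", nrow(x$method_stats), "methods,",
      sum(x$method_stats$n), "replicates\n")
  print(x$method_stats)
  print(x$pairwise)
  invisible(x)
}

#' @rdname compare_extractions
#' @param x An `extraction_comparison` object.
#' @param ... Unused.
#' @export
tidy.extraction_comparison <- function(x, ...) x$pairwise

#' @rdname compare_extractions
#' @export
glance.extraction_comparison <- function(x, ...) {
  tibble(n_methods = nrow(x$method_stats),
         n_replicates = sum(x$method_stats$n),
         min_variance = min(x$method_stats$variance),
         max_variance = max(x$method_stats$variance))
}

#' @rdname compare_extractions
#' @param object An `extraction_comparison` object.
#' @export
autoplot.extraction_comparison <- function(object, ...) {
  ggplot2::ggplot(object$replicate_values,
                  ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.7) +
    ggplot2::labs(x = "DNA extraction method",
                  y = "Plate-centered mtDNA-CN (run-averaged)",
                  title = "Reproducibility across DNA extraction methods") +
    ggplot2::theme_minimal()
}
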