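# Method-comparison machinery: rank aggregation, concordance, standardized
# -log10 p scores, permutation tests.

# Coerce a p-value input (long tibble method/correlate/p, or a
# methods x correlates matrix) to a named matrix.
as_p_matrix <- function(x) {
  if (is.matrix(x)) {
    if (is.null(rownames(x))) rownames(x) <- paste0("method", seq_len(nrow(x)))
    return(x)
  }
  check_columns(x, c("method", "correlate", "p"), "p-value input")
  wide <- x |>
    select("method", "correlate", "p") |>
    tidyr::pivot_wider(names_from = "correlate", values_from = "p")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$method
  m
}

#' Rank methods within each correlate by p-value
#'
#' Within each correlate, the method with the smallest p-value receives
#' rank 1; tied p-values receive the average of the tied ranks. The mean
#' rank per method averages over the correlates for which the method has a
#' p-value (missing correlates are ignored).
#'
#' @param p A long tibble (`method`, `correlate`, `p`) such as
#'   [run_battery()] output, or a methods-by-correlates p-value matrix.
#' @return A list: `ranks` (methods x correlates matrix) and `mean_ranks`
#'   (tibble `method`, `mean_rank` in input method order).
#' @examples
#' p <- matrix(c(1e-8, 1e-3, 1e-5, 1e-2), 2, 2,
#'             dimnames = list(c("wgs", "qpcr"), c("age", "sex")))
#' rank_methods(p)$mean_ranks
#' @export
rank_methods <- function(p) {
  pm <- as_p_matrix(p)
  ranks <- apply(pm, 2, function(col) rank(col, ties.method = "average",
                                           na.last = "keep"))
  ranks <- matrix(ranks, nrow = nrow(pm), dimnames = dimnames(pm))
  list(
    ranks = ranks,
    mean_ranks = tibble(method = rownames(pm),
                        mean_rank = unname(rowMeans(ranks, na.rm = TRUE)))
  )
}

#' Kendall's coefficient of concordance (W)
#'
#' Agreement of several rankings of the same objects, here the agreement of
#' per-correlate method rankings. With `m` judges (correlates) ranking `n`
#' objects (methods),
#' \deqn{W = \frac{12 S}{m^2 (n^3 - n) - m \sum T}}
#' where `S` is the sum of squared deviations of the object rank sums from
#' their mean and \eqn{T = \sum (t^3 - t)} over each judge's tie groups
#' (the tie correction; `tie_correct = FALSE` sets T = 0). W is 1 for
#' identical rankings and 0 for no agreement. Significance is approximated
#' by \eqn{\chi^2 = m (n - 1) W} on `n - 1` degrees of freedom.
#'
#' @param ranks A judges-by-objects matrix of (possibly tied) rankings.
#' @param tie_correct Apply the tie correction (default `TRUE`).
#' @return A one-row tibble: `w`, `chisq`, `df`, `p_value`, `n_judges`,
#'   `n_objects`.
#' @export
kendalls_w <- function(ranks, tie_correct = TRUE) {
  ranks <- as.matrix(ranks)
  m <- nrow(ranks)
  n <- ncol(ranks)
  if (n < 2) abort("Need at least 2 objects to measure concordance.")
  if (m < 1) abort("Need at least 1 judge.")
  rank_sums <- colSums(ranks)
  s <- sum((rank_sums - m * (n + 1) / 2)^2)
  tie_term <- if (tie_correct) {
    sum(apply(ranks, 1, function(r) {
      t <- table(r)
      sum(t^3 - t)
    }))
  } else 0
  denom <- m^2 * (n^3 - n) - m * tie_term
  w <- 12 * s / denom
  chisq <- m * (n - 1) * w
  tibble(w = w, chisq = chisq, df = n - 1,
         p_value = pchisq(chisq, n - 1, lower.tail = FALSE),
         n_judges = m, n_objects = n)
}

#' Standardized -log10 p scores
#'
#' Scores each method on each correlate as its -log10 p-value divided by
#' the -log10 p-value of the least significant method for that correlate
#' (ratio standardization: the weakest method scores exactly 1, a method
#' two orders of magnitude more significant scores accordingly higher). A
#' subtraction mode (`mode = "difference"`) instead subtracts the weakest
#' method's -log10 p, so the weakest method scores 0. A correlate whose
#' weakest p-value is 1 cannot be ratio-standardized and is dropped with a
#' warning.
#'
#' @param p A long tibble (`method`, `correlate`, `p`) or a
#'   methods-by-correlates p matrix.
#' @param mode `"ratio"` (default) or `"difference"`.
#' @return A list: `scores` (methods x correlates matrix) and `summary`
#'   (tibble with per-method `score_sum`, `score_mean`, `score_median`
#'   across correlates).
#' @export
score_methods <- function(p, mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  pm <- as_p_matrix(p)
  if (any(pm <= 0 | pm > 1, na.rm = TRUE)) {
    abort("p-values must lie in (0, 1].")
  }
  nlp <- -log10(pm)
  scores <- matrix(NA_real_, nrow(pm), ncol(pm), dimnames = dimnames(pm))
  drop_cols <- character(0)
  for (j in seq_len(ncol(pm))) {
    ref <- min(nlp[, j], na.rm = TRUE)
    if (mode == "ratio") {
      if (ref == 0) {
        drop_cols <- c(drop_cols, colnames(pm)[j])
        next
      }
      scores[, j] <- nlp[, j] / ref
    } else {
      scores[, j] <- nlp[, j] - ref
    }
  }
  if (length(drop_cols) > 0) {
    warn(sprintf(
      "Correlate(s) %s dropped: least significant method has p = 1, ratio standardization undefined.",
      paste(drop_cols, collapse = ", ")))
    scores <- scores[, setdiff(colnames(scores), drop_cols), drop = FALSE]
  }
  list(
    scores = scores,
    summary = tibble(
      method = rownames(scores),
      score_sum = unname(rowSums(scores, na.rm = TRUE)),
      score_mean = unname(rowMeans(scores, na.rm = TRUE)),
      score_median = unname(apply(scores, 1, median, na.rm = TRUE))
    )
  )
}

#' Permutation test for per-method summed scores
#'
#' Compares each method's summed standardized score to a null distribution
#' obtained by shuffling the scores across methods independently within
#' each correlate (`scheme = "shuffle"`, sampling without replacement; a
#' bootstrap mode resamples within correlate with replacement). The
#' empirical p-value is `(1 + #(null > observed)) / (1 + n_perm)`: strictly
#' greater, so a method that holds the maximum score on every correlate
#' attains the floor `1 / (n_perm + 1)` because no rearrangement can exceed
#' its observed sum.
#'
#' @param scores A methods-by-correlates score matrix (see
#'   [score_methods()]).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed; results are reproducible for a fixed seed.
#' @param scheme `"shuffle"` (default) or `"bootstrap"`.
#' @param statistic Summary compared against the null: `"sum"` (default)
#'   or `"mean"` over correlates.
#' @return A tibble: `method`, `observed`, `perm_p`.
#' @export
permutation_test <- function(scores, n_perm = 1000, seed = 1L,
                             scheme = c("shuffle", "bootstrap"),
                             statistic = c("sum", "mean")) {
  scheme <- match.arg(scheme)
  statistic <- match.arg(statistic)
  check_count(n_perm, "n_perm")
  scores <- as.matrix(scores)
  m <- nrow(scores)
  stat <- function(x) if (statistic == "sum") rowSums(x, na.rm = TRUE) else
    rowMeans(x, na.rm = TRUE)
  observed <- stat(scores)
  exceed <- numeric(m)
  withr::with_seed(substream_seed(seed, 8L), {
    for (b in seq_len(n_perm)) {
      null <- apply(scores, 2, function(col) {
        if (scheme == "shuffle") sample(col) else
          sample(col, length(col), replace = TRUE)
      })
      exceed <- exceed + (stat(null) > observed)
    }
  })
  tibble(method = rownames(scores) %||% paste0("method", seq_len(m)),
         observed = unname(observed),
         perm_p = unname((1 + exceed) / (1 + n_perm)))
}

#' Head-to-head p-value comparison of two methods
#'
#' The mean, over shared correlates, of `log10(p_b) - log10(p_a)`: how many
#' orders of magnitude more significant method `a` is than method `b` on
#' average (positive values favor `a`).
#'
#' @param p A long tibble (`method`, `correlate`, `p`) or p matrix.
#' @param method_a,method_b Method names to compare.
#' @return A single number: mean orders-of-magnitude advantage of `a`.
#' @export
head_to_head <- function(p, method_a, method_b) {
  pm <- as_p_matrix(p)
  if (!all(c(method_a, method_b) %in% rownames(pm))) {
    abort("Both methods must be present in the p-value input.")
  }
  diff <- log10(pm[method_b, ]) - log10(pm[method_a, ])
  mean(diff, na.rm = TRUE)
}

#' Evaluate and compare estimation methods
#'
#' Bundles the full method-comparison analysis of an association-battery
#' result: per-correlate p-value rankings with mean ranks, Kendall's W
#' across correlates, standardized -log10 p scores with per-method
#' summaries, and the within-correlate permutation test of the summed
#' scores. Correlates with missing p-values for any method (e.g. an
#' unusable survival fit) are excluded from the concordance and score
#' stages.
#'
#' @param assoc A [run_battery()] result (or any long tibble with `method`,
#'   `correlate`, `p`).
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed for the permutation draws.
#' @param mode Score standardization mode, see [score_methods()].
#' @return An object of class `cn_eval` with components `p_matrix`,
#'   `ranks`, `mean_ranks`, `concordance`, `scores`, `score_summary`,
#'   `permutation`. Use [tidy()] for a per-method table, [glance()] for the
#'   concordance row, and [autoplot()] for a score plot.
#' @examples
#' p <- matrix(10^-c(8, 3, 2, 6, 4, 1), 3, 2,
#'             dimnames = list(c("wgs", "array", "qpcr"), c("age", "sex")))
#' ev <- evaluate_methods(p, n_perm = 200, seed = 1)
#' tidy(ev)
#' @export
evaluate_methods <- function(assoc, n_perm = 1000, seed = 1L,
                             mode = c("ratio", "difference")) {
  mode <- match.arg(mode)
  pm <- as_p_matrix(assoc)
  complete_cols <- colSums(is.na(pm)) == 0
  pm_c <- pm[, complete_cols, drop = FALSE]
  rk <- rank_methods(pm_c)
  w <- kendalls_w(t(rk$ranks))
  sc <- score_methods(pm_c, mode = mode)
  perm <- permutation_test(sc$scores, n_perm = n_perm, seed = seed)
  structure(
    list(p_matrix = pm, ranks = rk$ranks, mean_ranks = rk$mean_ranks,
         concordance = w, scores = sc$scores, score_summary = sc$summary,
         permutation = perm, n_perm = n_perm),
    class = "cn_eval"
  )
}

#' @export
print.cn_eval <- function(x, ...) {
  cat("<cn_eval>", nrow(x$p_matrix), "methods,", ncol(x$p_matrix),
      "correlates\n")
  cat(sprintf("Kendall's W = %.3f (chi-square p = %.3g)\n",
              x$concordance$w, x$concordance$p_value))
  print(tidy(x))
  invisible(x)
}

#' @rdname evaluate_methods
#' @param x A `cn_eval` object.
#' @param ... Unused.
#' @export
tidy.cn_eval <- function(x, ...) {
  x$mean_ranks |>
    left_join(x$score_summary, by = "method") |>
    left_join(x$permutation |> select("method", "perm_p"), by = "method")
}

#' @rdname evaluate_methods
#' @export
glance.cn_eval <- function(x, ...) {
  x$concordance |> mutate(n_perm = x$n_perm)
}

#' @rdname evaluate_methods
#' @param object A `cn_eval` object.
#' @export
autoplot.cn_eval <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$method,
                                                     -.data$score_mean),
                                  y = .data$score_mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("rank %.2f", .data$mean_rank)), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL,
                  y = "Mean standardized -log10 p (1 = weakest method)",
                  title = "Relative performance of mtDNA-CN estimation methods") +
    ggplot2::theme_minimal()
}
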