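# Internal helpers shared across modules.

# Derive a reproducible sub-stream seed from a master seed. Every generator
# draws from its own sub-stream so that adding a platform to a simulation
# never perturbs the draws of another. Constants are Lehmer multipliers;
# the product stays below 2^53 for any seed < 2^31 so arithmetic is exact.
substream_seed <- function(seed, stream) {
  (((as.double(seed) %% 2147483647) * 48271) + 30269 * as.double(stream)) %% 2147483647
}

check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single proportion in [0, 1], got %s.",
                  name, deparse(substitute(x))))
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    abort(sprintf("`%s` must be a single non-negative number.", name))
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be an integer >= %d.", name, min))
  }
  invisible(x)
}

check_columns <- function(data, cols, what = "input") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s.",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(data)
}

# Sample standard deviation that returns NA (not an error) for length-1 input.
safe_sd <- function(x) if (length(x) < 2L) NA_real_ else sd(x)
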