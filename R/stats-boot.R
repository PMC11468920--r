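## Group-level inference by participant resampling, plus the small
## correlation helper used by the behavioral analyses.

#' Participant bootstrap test against a null value
#'
#' Resamples participants with replacement, recomputes the group mean per
#' iterate, and reports the 95% percentile CI of the resampled mean plus a
#' two-tailed, +1-corrected p-value:
#' `p = 2 * min(#{mean* <= null} + 1, #{mean* >= null} + 1) / (n_boot + 1)`,
#' capped at 1.
#'
#' @param values Per-participant scalars (length >= 2).
#' @param n_boot Bootstrap iterations (default 10000).
#' @param seed Integer seed.
#' @param null_value Null hypothesis value (default 0).
#' @return List of class `group_stat`: `observed_mean`, `ci_low`, `ci_high`,
#'   `p_two_tailed`, `n_boot`, `seed`, `n`.
#' @export
bootstrap_test <- function(values, n_boot = 10000, seed = 1L,
                           null_value = 0) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stopf("bootstrap_test needs >= 2 participants")
  if (length(unique(values)) < 2) {
    warnf("fewer than 2 distinct values: degenerate CI")
  }
  means <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
    colMeans(matrix(values[idx], n, n_boot))
  })
  ci <- unname(stats::quantile(means, c(0.025, 0.975), type = 7))
  p <- 2 * min(sum(means <= null_value) + 1, sum(means >= null_value) + 1) /
    (n_boot + 1)
  structure(list(observed_mean = mean(values), ci_low = ci[1],
                 ci_high = ci[2], p_two_tailed = min(p, 1),
                 n_boot = n_boot, seed = seed, n = n),
            class = "group_stat")
}

#' Pearson correlation with a t-based p-value
#'
#' Sample Pearson r, with a two-sided p from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors, length >= 3, finite, non-constant.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (n < 3 || length(y) != n) stopf("need paired vectors of length >= 3")
  if (!all(is.finite(x)) || !all(is.finite(y))) stopf("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("zero variance in x or y")
  }
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(r = r, p = p, n = n)
}
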