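# Test statistics and distribution summaries used by the tile
# comparisons and the retention-index analysis.

#' Wilcoxon/Mann-Whitney rank-sum test
#'
#' Two-sided rank-sum test with midrank tie handling.  The exact null
#' distribution is enumerated when both samples have at most 8
#' observations and there are no ties; otherwise the normal approximation
#' with tie correction and continuity correction is used.  The two-sided
#' p doubles the smaller tail, capped at 1.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return List with `U` (the Mann-Whitney statistic of `sample_a`,
#'   i.e. the number of (a, b) pairs with a > b, counting ties as 1/2)
#'   and `p` (two-sided).
#' @export
rank_sum_test <- function(sample_a, sample_b) {
  if (length(sample_a) == 0L || length(sample_b) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  pooled <- c(sample_a, sample_b)
  if (length(unique(pooled)) == 1L) {
    # fully tied: no evidence either way
    return(list(U = length(sample_a) * length(sample_b) / 2, p = 1))
  }
  exact <- length(sample_a) <= 8L && length(sample_b) <= 8L &&
    !any(duplicated(pooled))
  ht <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, exact = exact, correct = TRUE))
  # with midranks, wilcox.test's W equals the tie-counting U statistic
  r <- rank(pooled)[seq_along(sample_a)]
  u <- sum(r) - length(sample_a) * (length(sample_a) + 1) / 2
  list(U = u, p = min(1, ht$p.value))
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value.
#'
#' @param sample_a,sample_b Numeric vectors, each with at least 2 values
#'   and nonzero variance in at least one.
#' @return List with `t`, `df` and `p`.
#' @export
welch_t_test <- function(sample_a, sample_b) {
  if (length(sample_a) < 2L || length(sample_b) < 2L)
    stop("each sample needs at least 2 observations", call. = FALSE)
  if (stats::var(sample_a) == 0 && stats::var(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b))
      return(list(t = 0, df = length(sample_a) + length(sample_b) - 2,
                  p = 1))
    stop("both samples have zero variance; the Welch statistic is ",
         "undefined", call. = FALSE)
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Box-plot summary of a distribution
#'
#' Quartiles by linear interpolation (type-7 quantiles).  Whiskers either
#' in the Tukey convention (most extreme data points within 1.5 IQR of
#' the quartiles) or as the 10th/90th percentiles.
#'
#' @param values Non-empty numeric vector.
#' @param whiskers `"tukey"` or `"percentile"`.
#' @return Named list: `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`.
#' @export
summarize_boxplot <- function(values, whiskers = c("tukey", "percentile")) {
  whiskers <- match.arg(whiskers)
  if (length(values) == 0L || any(is.na(values)))
    stop("values must be non-empty and free of NAs", call. = FALSE)
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  if (whiskers == "tukey") {
    iqr <- q[3] - q[1]
    lo <- min(values[values >= q[1] - 1.5 * iqr])
    hi <- max(values[values <= q[3] + 1.5 * iqr])
  } else {
    p <- unname(quantile(values, c(0.1, 0.9), type = 7))
    lo <- p[1]; hi <- p[2]
  }
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = lo, whisker_high = hi)
}
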