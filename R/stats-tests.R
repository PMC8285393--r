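# Nonparametric two-sample machinery used for the condition contrasts:
# Wilcoxon signed-rank on paired per-transcript pause scores and
# Mann-Whitney U on RRTS distributions. Both tests carry an exact
# small-sample mode (full enumeration of the permutation null) and a
# tie-corrected, continuity-corrected normal approximation for larger n.

comparison_result <- function(test_name, statistic, p_value, alternative,
                              n, n2 = NA_integer_, direction, mode,
                              n_zero_dropped = 0L) {
  structure(
    list(test_name = test_name, statistic = statistic, p_value = p_value,
         alternative = alternative, n = n, n2 = n2, direction = direction,
         mode = mode, n_zero_dropped = n_zero_dropped),
    class = "comparison_result"
  )
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %g, p = %g (%s, %s mode, n = %d%s)\n",
              x$test_name, x$statistic, x$p_value, x$alternative, x$mode,
              x$n, if (!is.na(x$n2)) sprintf(", n2 = %d", x$n2) else ""))
  invisible(x)
}

# one- and two-sided p from lower/upper tail probabilities; the
# two-sided p is 2*min(tails) capped at 1
p_from_tails <- function(p_less, p_greater, alternative) {
  switch(alternative,
         less = p_less,
         greater = p_greater,
         two.sided = min(1, 2 * min(p_less, p_greater)))
}

#' Wilcoxon signed-rank test on paired observations
#'
#' Tests whether paired differences `x - y` are symmetrically
#' distributed about zero. Zero differences are dropped (Wilcoxon's
#' original convention) and counted. Absolute differences are ranked
#' with average ranks for ties; the statistic W is the sum of ranks of
#' the positive differences. For `n <= exact_max_n` nonzero pairs the
#' null is enumerated over all `2^n` sign assignments of the observed
#' rank vector (exact even under ties); otherwise a normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x numeric vector; paired differences if `y` is `NULL`.
#' @param y optional numeric vector paired with `x`.
#' @param alternative `"two.sided"`, `"less"` or `"greater"` (direction
#'   of `x` relative to `y`).
#' @param exact_max_n largest n for the exact enumeration mode.
#' @return A `comparison_result`: statistic W, p-value, mode
#'   (`"exact"`/`"approx"`), direction (sign of the median difference),
#'   and the number of zero differences dropped.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 alternative = c("two.sided", "less", "greater"),
                                 exact_max_n = 12L) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) as.numeric(x) else {
    stopifnot(length(x) == length(y))
    as.numeric(x) - as.numeric(y)
  }
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("degenerate test: all differences are zero", call. = FALSE)

  r <- rank(abs(d))
  W <- sum(r[d > 0])

  if (n <= exact_max_n) {
    eps <- 1e-9
    all_w <- signed_rank_null(r)
    p_less <- mean(all_w <= W + eps)
    p_greater <- mean(all_w >= W - eps)
    mode <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    sigma <- sqrt(sigma2)
    # continuity correction: shrink the observed deviation by 1/2
    p_less <- pnorm((W - mu + 0.5) / sigma)
    p_greater <- pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE)
    mode <- "approx"
  }
  comparison_result("wilcoxon_signed_rank", W,
                    p_from_tails(p_less, p_greater, alternative),
                    alternative, n, direction = sign(stats::median(d)),
                    mode = mode, n_zero_dropped = n_zero)
}

# W for every sign assignment of the observed ranks (2^n vectors)
signed_rank_null <- function(r) {
  n <- length(r)
  w <- 0
  for (i in seq_len(n)) {
    w <- c(w, w + r[i])  # doubling construction over subsets
  }
  w
}

#' Mann-Whitney U test on two independent samples
#'
#' Tests for a location shift between two samples by ranking the pooled
#' values (average ranks for ties). The statistic is
#' `U = R1 - n1(n1+1)/2`, the number of (x, y) pairs with x above y
#' counting ties as 1/2. For `n1 + n2 <= exact_max_n` the null is
#' enumerated over all `choose(n1+n2, n1)` relabelings of the observed
#' pooled values (exact even under ties); otherwise a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"`, `"less"` (x shifted below y) or
#'   `"greater"` (x shifted above y).
#' @param exact_max_n largest pooled size for exact enumeration.
#' @return A `comparison_result` with statistic U (for `x`), p-value,
#'   sizes `n` and `n2`, direction (sign of `median(x) - median(y)`),
#'   and mode.
#' @export
mann_whitney_u <- function(x, y,
                           alternative = c("two.sided", "less", "greater"),
                           exact_max_n = 12L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("both samples must be nonempty", call. = FALSE)
  pooled <- c(x, y)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (n1 + n2 <= exact_max_n) {
    eps <- 1e-9
    combos <- utils::combn(n1 + n2, n1)
    all_u <- colSums(matrix(r[combos], nrow = n1)) - n1 * (n1 + 1) / 2
    p_less <- mean(all_u <= U + eps)
    p_greater <- mean(all_u >= U - eps)
    mode <- "exact"
  } else {
    N <- n1 + n2
    mu <- n1 * n2 / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    sigma <- sqrt(sigma2)
    p_less <- pnorm((U - mu + 0.5) / sigma)
    p_greater <- pnorm((U - mu - 0.5) / sigma, lower.tail = FALSE)
    mode <- "approx"
  }
  comparison_result("mann_whitney_u", U,
                    p_from_tails(p_less, p_greater, alternative),
                    alternative, n1, n2 = n2,
                    direction = sign(stats::median(x) - stats::median(y)),
                    mode = mode)
}

#' Empirical cumulative distribution points
#'
#' Right-continuous step-function points of the empirical CDF, used for
#' cumulative-histogram comparisons of score distributions. Duplicated
#' values collapse into a single step of proportionally larger height;
#' the final cumulative fraction is exactly 1.
#'
#' @param values nonempty numeric vector.
#' @return data.table with columns `value` (sorted unique values) and
#'   `fraction` (cumulative fraction of observations `<=` value).
#' @export
ecdf_points <- function(values) {
  stopifnot(length(values) >= 1)
  tab <- table(sort(values))
  data.table::data.table(
    value = as.numeric(names(tab)),
    fraction = cumsum(as.numeric(tab)) / length(values)
  )
}

#' Box-and-whisker summary statistics
#'
#' Quartiles use linear interpolation between order statistics
#' (`quantile` type 7). Notches are `median +/- 1.57 * IQR / sqrt(n)`
#' (McGill's 95 percent comparison interval); whiskers extend to the
#' most extreme data point within 1.5 IQR of the nearer quartile, so
#' they always sit at actual data values (or at the quartile itself when
#' no point lies beyond it).
#'
#' @param values nonempty numeric vector.
#' @return list of class `box_stats`: `median`, `q1`, `q3`, `iqr`,
#'   `notch_low`, `notch_high`, `whisker_low`, `whisker_high`, `n`.
#' @export
box_stats <- function(values) {
  stopifnot(length(values) >= 1)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  half_notch <- 1.57 * iqr / sqrt(length(values))
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  in_lo <- values[values >= lo_fence]
  in_hi <- values[values <= hi_fence]
  structure(
    list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
         notch_low = q[2] - half_notch, notch_high = q[2] + half_notch,
         whisker_low = if (length(in_lo)) min(in_lo) else q[1],
         whisker_high = if (length(in_hi)) max(in_hi) else q[3],
         n = length(values)),
    class = "box_stats"
  )
}

#' @export
print.box_stats <- function(x, ...) {
  cat(sprintf("<box_stats> n=%d median=%g [q1=%g, q3=%g] whiskers [%g, %g]\n",
              x$n, x$median, x$q1, x$q3, x$whisker_low, x$whisker_high))
  invisible(x)
}
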