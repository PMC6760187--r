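# Statistical assessment: normality screen, robust summaries, and the two
# nonparametric comparisons (unpaired rank-sum, paired signed-rank).

.test_result <- function(statistic, p_value, test_name, null_hypothesis, n,
                         ...) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(c(list(statistic = unname(statistic), p_value = unname(p_value),
                   test_name = test_name, null_hypothesis = null_hypothesis,
                   n = n), list(...)),
            class = "wormstim_test")
}

#' @export
print.wormstim_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g %s (n = %s)\n  H0: %s\n",
              x$test_name, x$statistic, x$p_value, sig_stars(x$p_value),
              paste(x$n, collapse = "/"), x$null_hypothesis))
  invisible(x)
}

#' Significance stars
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, `ns` otherwise.
#'
#' @param p P-value(s).
#' @return Character vector of markers.
#' @export
sig_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "ns")))
}

#' Robust group summary
#'
#' Median and quartiles (linear interpolation between order statistics,
#' i.e. `stats::quantile` type 7), the convention used for all reported
#' latency summaries (Median \[Q1-Q3\]).
#'
#' @param values Numeric vector, n >= 1 (NAs dropped).
#' @return List of class `group_summary` with `median`, `q1`, `q3`, `n`.
#' @export
summarize_group <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("summarize_group needs at least one value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(median = q[2], q1 = q[1], q3 = q[3], n = length(values)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat(sprintf("%.4g [%.4g-%.4g] (n = %d)\n", x$median, x$q1, x$q3, x$n))
  invisible(x)
}

#' Jarque-Bera normality screen
#'
#' Statistic JB = n/6 (S^2 + (K - 3)^2 / 4) from the sample skewness S and
#' kurtosis K (population moment estimators), referred to its asymptotic
#' chi-square(2) distribution. The chi-square reference is anti-conservative
#' at small n; a caveat is attached below n = 50.
#'
#' @param values Numeric vector, n >= 8.
#' @return A test result with `statistic`, `p_value`, `skewness`,
#'   `kurtosis`, and `small_n_caveat`.
#' @export
normality_screen <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 8) stop("normality_screen requires at least 8 values")
  m <- values - mean(values)
  m2 <- mean(m^2); m3 <- mean(m^3); m4 <- mean(m^4)
  if (m2 == 0) stop("normality_screen: zero variance")
  s <- m3 / m2^1.5
  k <- m4 / m2^2
  jb <- n / 6 * (s^2 + (k - 3)^2 / 4)
  .test_result(jb, stats::pchisq(jb, df = 2, lower.tail = FALSE),
               "Jarque-Bera", "the sample is drawn from a normal distribution",
               n, skewness = s, kurtosis = k, small_n_caveat = n < 50)
}

# Tie-corrected normal approximation for the Mann-Whitney U statistic.
.u_approx_p <- function(u, n1, n2, tie_counts, correct = TRUE) {
  n <- n1 + n2
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 *
    ((n + 1) - sum(tie_counts^3 - tie_counts) / (n * (n - 1)))
  if (sigma2 <= 0) return(list(p = 1, degenerate = TRUE))
  cc <- if (correct) sign(u - mu) * 0.5 else 0
  z <- (u - mu - cc) / sqrt(sigma2)
  list(p = min(2 * stats::pnorm(-abs(z)), 1), degenerate = FALSE)
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided unpaired comparison of two groups (H0: both samples come from
#' the same distribution), as used to compare MStim and UStim TOG
#' distributions and per-PRF AP counts. The statistic is the Mann-Whitney U
#' of the first group. The exact permutation distribution is used when both
#' groups have at most `exact_max` observations and there are no ties;
#' otherwise the tie-corrected normal approximation with continuity
#' correction.
#'
#' @param group_a,group_b Numeric vectors, both non-empty.
#' @param exact_max Exact-enumeration size limit per group.
#' @return A test result with `statistic` (U), `p_value`, `method`
#'   (`"exact"` or `"normal_approx"`) and `degenerate` flag.
#' @export
rank_sum_test <- function(group_a, group_b, exact_max = 12) {
  group_a <- group_a[!is.na(group_a)]; group_b <- group_b[!is.na(group_b)]
  n1 <- length(group_a); n2 <- length(group_b)
  if (!n1 || !n2) stop("both groups must be non-empty")
  r <- rank(c(group_a, group_b))
  ties <- table(r)   # tie counts on ranks, not on floating-point values
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  exact <- n1 <= exact_max && n2 <= exact_max && all(ties == 1)
  if (exact) {
    p <- if (u > n1 * n2 / 2)
      stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    else stats::pwilcox(u, n1, n2)
    p <- min(2 * p, 1)
    degenerate <- FALSE
  } else {
    ap <- .u_approx_p(u, n1, n2, as.numeric(ties))
    p <- ap$p; degenerate <- ap$degenerate
  }
  .test_result(u, p, "Wilcoxon-Mann-Whitney",
               "the distributions of the two groups are the same",
               c(n1, n2), method = if (exact) "exact" else "normal_approx",
               degenerate = degenerate)
}

# Exact two-sided sign-permutation p for the signed-rank statistic v with
# (possibly tied, average) ranks r. Doubled ranks make the DP integral.
.signrank_exact_p <- function(r, v) {
  r2 <- as.integer(round(2 * r))
  counts <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), counts)
    counts <- c(counts, numeric(ri)) + shifted
  }
  total <- sum(counts)
  v2 <- as.integer(round(2 * v))
  p_le <- sum(counts[seq_len(v2 + 1L)]) / total
  p_ge <- sum(counts[seq.int(v2 + 1L, length(counts))]) / total
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' The paired analogue used for the per-trial success-rate comparison (H0:
#' the difference between the paired measurements is symmetric about zero).
#' Zero differences are dropped (their count is recorded). For at most
#' `exact_max` non-zero differences the exact sign-permutation distribution
#' is enumerated (ties in the absolute differences are handled by average
#' ranks); otherwise the tie-corrected normal approximation with continuity
#' correction is used.
#'
#' @param values_a,values_b Equal-length numeric vectors of paired
#'   measurements.
#' @param exact_max Exact-distribution size limit.
#' @return A test result with `statistic` (V, the positive-rank sum),
#'   `p_value`, `method`, `n_zero_dropped` and `degenerate` flag (all
#'   differences zero).
#' @export
paired_rank_test <- function(values_a, values_b, exact_max = 15) {
  if (length(values_a) != length(values_b))
    stop("paired samples must have equal length")
  keep <- !(is.na(values_a) | is.na(values_b))
  d <- values_a[keep] - values_b[keep]
  if (length(d) < 2) stop("need at least 2 pairs")
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  if (!length(d))
    return(.test_result(0, 1, "Wilcoxon signed-rank",
                        "the paired differences are symmetric about zero",
                        0, method = "degenerate", n_zero_dropped = n_zero,
                        degenerate = TRUE))
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  exact <- n <= exact_max
  if (exact) {
    p <- .signrank_exact_p(r, v)
    degenerate <- FALSE
  } else {
    mu <- n * (n + 1) / 4
    tie_counts <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_counts^3 - tie_counts) / 48
    if (sigma2 <= 0) { p <- 1; degenerate <- TRUE }
    else {
      z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
      p <- min(2 * stats::pnorm(-abs(z)), 1)
      degenerate <- FALSE
    }
  }
  .test_result(v, p, "Wilcoxon signed-rank",
               "the paired differences are symmetric about zero",
               n, method = if (exact) "exact" else "normal_approx",
               n_zero_dropped = n_zero, degenerate = degenerate)
}
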