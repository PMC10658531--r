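# Clinical outcome statistics in the conventions of mainstream clinical
# statistics software: weighted-average (n+1)p quantiles, paired/two-sample
# t tests, and the zero-drop tie-corrected normal-approximation Wilcoxon
# signed-rank. Exact enumeration modes are provided for the nonparametric
# tests as small-sample oracles.

#' Weighted-average quantile at position (n+1)p
#'
#' The percentile estimator interpolating between order statistics at
#' fractional position h = (n+1)p (clamped to the extremes): with h = k + g,
#' the result is x(k) + g (x(k+1) - x(k)) on the sorted values. This is the
#' rule that reproduces the printed clinical medians and interquartile
#' ranges.
#'
#' @param x numeric vector.
#' @param p probabilities in [0, 1].
#' @return quantiles.
#' @export
quantile_np1 <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  vapply(p, function(pp) {
    h <- (n + 1) * pp
    if (h <= 1) return(x[1])
    if (h >= n) return(x[n])
    k <- floor(h); g <- h - k
    x[k] + g * (x[k + 1] - x[k])
  }, 0)
}

#' Descriptive summary of a numeric variable
#'
#' Mean, n-1 standard deviation, and median/quartiles by the weighted
#' (n+1)p rule. The display recommendation follows the clinical convention:
#' mean +/- sd for symmetric (Shapiro-Wilk p >= 0.05) variables, median and
#' interquartile range otherwise.
#'
#' @param values numeric vector (missing values dropped), n >= 1.
#' @param quantile_rule quantile estimator; only `"weighted_np1"` is
#'   implemented.
#' @return object of class `describe_summary` with fields `n`, `mean`, `sd`,
#'   `median`, `p25`, `p75`, `display`.
#' @export
describe <- function(values, quantile_rule = "weighted_np1") {
  quantile_rule <- match.arg(quantile_rule, "weighted_np1")
  values <- values[!is.na(values)]
  if (length(values) < 1) stop_with("stats_error", "no non-missing values")
  q <- quantile_np1(values, c(0.25, 0.5, 0.75))
  s <- if (length(values) > 1) stats::sd(values) else 0
  display <- "mean_sd"
  if (length(values) >= 3 && length(values) < 50 && s > 0) {
    if (stats::shapiro.test(values)$p.value < 0.05) display <- "median_iqr"
  }
  structure(list(n = length(values), mean = mean(values), sd = s,
                 median = q[2], p25 = q[1], p75 = q[3], display = display),
            class = "describe_summary")
}

#' @export
print.describe_summary <- function(x, ...) {
  cat(sprintf("n=%d  mean %.2f +/- %.2f  median %.2f (%.2f-%.2f)  [%s]\n",
              x$n, x$mean, x$sd, x$median, x$p25, x$p75, x$display))
  invisible(x)
}

test_result <- function(test, statistic, df = NA_real_, z = NA_real_, p,
                        n = NA_integer_, degenerate = FALSE) {
  structure(list(test = test, statistic = statistic, df = df, z = z,
                 p = p, n = n, degenerate = degenerate),
            class = "eaf_test_result")
}

#' @export
print.eaf_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4f%s%s, p = %.4g%s\n", x$test, x$statistic,
              if (!is.na(x$df)) sprintf(", df %g", x$df) else "",
              if (!is.na(x$z)) sprintf(", z %.3f", x$z) else "",
              x$p, if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

#' Paired Student t test
#'
#' t on the paired differences, df = n - 1, two-tailed. Pairs with a missing
#' member are dropped. A zero-variance difference vector is flagged
#' degenerate and reported with p = 1.
#'
#' @param before,after equal-length numeric vectors.
#' @return an `eaf_test_result`.
#' @export
paired_t <- function(before, after) {
  if (length(before) != length(after))
    stop_with("stats_error", "before/after lengths differ")
  ok <- !is.na(before) & !is.na(after)
  b <- before[ok]; a <- after[ok]
  if (length(b) < 2) stop_with("stats_error", "need >= 2 complete pairs")
  d <- b - a
  if (stats::sd(d) == 0)
    return(test_result("paired t", 0, df = length(d) - 1, p = 1,
                       n = length(d), degenerate = TRUE))
  tt <- stats::t.test(b, a, paired = TRUE)
  test_result("paired t", unname(tt$statistic), df = unname(tt$parameter),
              p = tt$p.value, n = length(d))
}

#' Two-sample t test
#'
#' @param a,b numeric vectors (n >= 2 each).
#' @param variant `"pooled"` (equal variances, the clinical reporting
#'   default) or `"welch"`.
#' @return an `eaf_test_result`.
#' @export
two_sample_t <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2)
    stop_with("stats_error", "need >= 2 values per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop_with("stats_error", "degenerate variance in both groups")
  tt <- stats::t.test(a, b, var.equal = variant == "pooled")
  test_result(paste0("two-sample t (", variant, ")"),
              unname(tt$statistic), df = unname(tt$parameter),
              p = tt$p.value, n = length(a) + length(b))
}

# Midrank signed-rank machinery shared by asymptotic and exact modes.
signed_rank_stat <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  list(n = n, ranks = r, t_pos = sum(r[d > 0]))
}

#' Wilcoxon signed-rank test (zero-drop, tie-corrected normal)
#'
#' The paired nonparametric test in the convention of mainstream clinical
#' software: zero differences dropped, absolute differences midranked,
#' z = (T - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24 - sum(t^3 - t)/48) with T the
#' positive-rank sum, two-tailed normal p without continuity correction.
#' `exact = TRUE` instead enumerates all 2^n sign assignments (n <= 20) and
#' returns P(|T - mu| >= |t - mu|).
#'
#' @param before,after equal-length numeric vectors.
#' @param exact use the exact enumeration null distribution.
#' @return an `eaf_test_result`.
#' @export
wilcoxon_signed_rank <- function(before, after, exact = FALSE) {
  if (length(before) != length(after))
    stop_with("stats_error", "before/after lengths differ")
  ok <- !is.na(before) & !is.na(after)
  d <- after[ok] - before[ok]
  st <- signed_rank_stat(d)
  n <- st$n
  if (n == 0)
    return(test_result("wilcoxon signed-rank", 0, p = 1, n = 0,
                       degenerate = TRUE))
  mu <- n * (n + 1) / 4
  if (exact) {
    if (n > 20) stop_with("stats_error", "exact enumeration limited to n <= 20")
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    t_all <- as.vector(signs %*% st$ranks)
    p <- mean(abs(t_all - mu) >= abs(st$t_pos - mu) - 1e-9)
    return(test_result("wilcoxon signed-rank (exact)", st$t_pos, p = p, n = n))
  }
  ties <- table(st$ranks)
  sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  if (sig2 <= 0)
    return(test_result("wilcoxon signed-rank", st$t_pos, p = 1, n = n,
                       degenerate = TRUE))
  z <- (st$t_pos - mu) / sqrt(sig2)
  test_result("wilcoxon signed-rank", st$t_pos, z = z,
              p = 2 * stats::pnorm(-abs(z)), n = n)
}

#' Mann-Whitney U test
#'
#' U from midranks with tie-corrected normal z (no continuity correction),
#' two-tailed. `exact = TRUE` enumerates all group assignments
#' (n_a + n_b <= 12) and returns P(|U - mu| >= |u - mu|).
#'
#' @param a,b numeric vectors.
#' @param exact use the exact enumeration null distribution.
#' @return an `eaf_test_result`.
#' @export
mann_whitney <- function(a, b, exact = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  na <- length(a); nb <- length(b)
  if (na < 1 || nb < 1) stop_with("stats_error", "need >= 1 value per group")
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  mu <- na * nb / 2
  if (exact) {
    if (na + nb > 12)
      stop_with("stats_error", "exact enumeration limited to n_a + n_b <= 12")
    combs <- utils::combn(na + nb, na)
    u_all <- apply(combs, 2, function(idx)
      sum(r[idx]) - na * (na + 1) / 2)
    p <- mean(abs(u_all - mu) >= abs(u - mu) - 1e-9)
    return(test_result("mann-whitney U (exact)", u, p = p, n = na + nb))
  }
  nn <- na + nb
  ties <- table(r)
  sig2 <- na * nb / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  if (sig2 <= 0)
    return(test_result("mann-whitney U", u, p = 1, n = nn, degenerate = TRUE))
  z <- (u - mu) / sqrt(sig2)
  test_result("mann-whitney U", u, z = z, p = 2 * stats::pnorm(-abs(z)),
              n = nn)
}

#' Shapiro-Wilk normality test
#'
#' Small-sample normality gate (3 <= n < 50), via the standard algorithm.
#'
#' @param values numeric vector.
#' @return an `eaf_test_result` with the W statistic.
#' @export
shapiro_wilk <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n >= 50)
    stop_with("stats_error", "Shapiro-Wilk gate requires 3 <= n < 50")
  sw <- stats::shapiro.test(values)
  test_result("shapiro-wilk", unname(sw$statistic), p = sw$p.value, n = n)
}
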