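# Clinical statistics conventions, checked against independent oracles
# (stats:: implementations and exact enumeration).

test_that("quantile_np1 equals the type-6 estimator", {
  set.seed(31)
  for (k in 1:20) {
    x <- round(rnorm(sample(4:30, 1), 50, 20), sample(0:2, 1))
    p <- c(0.1, 0.25, 0.5, 0.75, 0.9)
    expect_equal(quantile_np1(x, p),
                 unname(stats::quantile(x, p, type = 6)), tolerance = 1e-12)
  }
  # clamping at the extremes
  expect_equal(quantile_np1(1:4, c(0, 1)), c(1, 4))
})

test_that("describe reports mean, n-1 sd and weighted quantiles", {
  x <- c(2, 4, 4, 4, 5, 5, 7, 9)
  d <- describe(x)
  expect_equal(d$n, 8)
  expect_equal(d$mean, mean(x))
  expect_equal(d$sd, stats::sd(x))
  expect_equal(c(d$p25, d$median, d$p75),
               unname(stats::quantile(x, c(0.25, 0.5, 0.75), type = 6)))
  expect_equal(describe(c(1, 2, 3, 4, 5, 6, 7))$display, "mean_sd")
  expect_equal(describe(c(1, 1, 1, 1, 2, 10, 50))$display, "median_iqr")
  expect_error(describe(c(NA_real_, NA_real_)), class = "stats_error")
})

test_that("paired t matches the stats oracle and handles degeneracy", {
  set.seed(7)
  b <- rnorm(10, 10); a <- b - rnorm(10, 1)
  r <- paired_t(b, a)
  o <- stats::t.test(b, a, paired = TRUE)
  expect_equal(r$statistic, unname(o$statistic))
  expect_equal(r$p, o$p.value)
  expect_equal(r$df, 9)
  same <- paired_t(b, b)
  expect_true(same$degenerate)
  expect_equal(same$p, 1)
  expect_error(paired_t(1:3, 1:4), class = "stats_error")
})

test_that("pooled two-sample t matches the hand formula", {
  a <- c(3, 5, 8, 9, 12); b <- c(4, 4, 6, 7)
  r <- two_sample_t(a, b, "pooled")
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(r$statistic, t_hand)
  expect_equal(r$df, length(a) + length(b) - 2)
  expect_equal(r$p, 2 * stats::pt(-abs(t_hand), r$df))
  w <- two_sample_t(a, b, "welch")
  expect_equal(w$p, stats::t.test(a, b)$p.value)
})

test_that("wilcoxon matches wilcox.test without continuity correction", {
  set.seed(12)
  for (k in 1:5) {
    b <- round(rnorm(12, 10, 3), 1)
    a <- round(b - rnorm(12, 0.8, 2), 1)
    r <- wilcoxon_signed_rank(b, a)
    o <- suppressWarnings(stats::wilcox.test(b, a, paired = TRUE,
                                             exact = FALSE, correct = FALSE))
    expect_equal(r$p, o$p.value, tolerance = 1e-10)
  }
})

test_that("wilcoxon drops zero differences and flags all-zero input", {
  b <- c(5, 5, 7, 9, 11)
  a <- c(5, 6, 6, 7, 14)   # one zero difference
  r <- wilcoxon_signed_rank(b, a)
  expect_equal(r$n, 4)
  z <- wilcoxon_signed_rank(b, b)
  expect_true(z$degenerate)
  expect_equal(z$p, 1)
})

test_that("exact enumeration matches wilcox.test's exact p on tie-free data", {
  # (the +/- 0.01 asymptotic-vs-exact bracket on the clinical fixtures is
  # asserted in the acceptance suite)
  set.seed(21)
  for (k in 1:6) {
    n <- sample(6:12, 1)
    b <- rnorm(n, 10, 3)
    a <- b - rnorm(n, 1.5, 1.5)   # continuous: no ties, no zeros
    pe <- wilcoxon_signed_rank(b, a, exact = TRUE)$p
    po <- stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value
    expect_equal(pe, po, tolerance = 1e-12)
  }
})

test_that("exact mann-whitney matches wilcox.test's exact p on tie-free data", {
  set.seed(23)
  for (k in 1:6) {
    a <- rnorm(sample(3:6, 1), 10)
    b <- rnorm(sample(3:6, 1), 11.5)
    pe <- mann_whitney(a, b, exact = TRUE)$p
    po <- stats::wilcox.test(a, b, exact = TRUE)$p.value
    expect_equal(pe, po, tolerance = 1e-12)
  }
})

test_that("mann-whitney U: extremes, exact enumeration and tie handling", {
  r <- mann_whitney(c(1, 2, 3), c(10, 11, 12))
  expect_equal(r$statistic, 0)
  ex <- mann_whitney(c(1, 2, 3), c(10, 11, 12), exact = TRUE)
  expect_equal(ex$p, 2 / choose(6, 3))      # only U = 0 and U = 9 qualify
  set.seed(5)
  a <- round(rnorm(5, 10), 1); b <- round(rnorm(5, 12), 1)
  expect_equal(mann_whitney(a, b)$p,
               suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                                   correct = FALSE))$p.value,
               tolerance = 1e-10)
  expect_lt(abs(mann_whitney(a, b)$p - mann_whitney(a, b, exact = TRUE)$p),
            0.05)
})

test_that("tests are invariant to input ordering", {
  set.seed(17)
  b <- rnorm(9, 10); a <- b - rnorm(9, 1)
  perm <- sample(9)
  expect_equal(paired_t(b, a)$p, paired_t(b[perm], a[perm])$p)
  expect_equal(wilcoxon_signed_rank(b, a)$p,
               wilcoxon_signed_rank(b[perm], a[perm])$p)
  expect_equal(mann_whitney(b, a)$p, mann_whitney(b[sample(9)], a[sample(9)])$p)
  expect_equal(two_sample_t(b, a)$p, two_sample_t(b[perm], a[perm])$p)
})

test_that("shapiro-wilk gate enforces 3 <= n < 50", {
  expect_error(shapiro_wilk(c(1, 2)), class = "stats_error")
  expect_error(shapiro_wilk(rnorm(50)), class = "stats_error")
  r <- shapiro_wilk(c(1, 2, 3, 4, 100))
  expect_lt(r$p, 0.05)
})

test_that("missing values are excluded pairwise with n reported", {
  b <- c(1, 2, NA, 4, 5); a <- c(0, 1, 3, NA, 2)
  expect_equal(paired_t(b, a)$n, 3)
  expect_equal(wilcoxon_signed_rank(b, a)$n, 3)
})

test_that("round_half_up rounds .5 away from zero", {
  expect_equal(round_half_up(23.625, 2), 23.63)   # banker's would give 23.62
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(1.005, 2), 1.01)
})
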