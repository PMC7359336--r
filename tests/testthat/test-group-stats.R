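test_that("one-sample t matches the textbook formula and the d = t/sqrt(n) identity", {
  set.seed(61)
  x <- rnorm(10, 5, 2)
  res <- one_sample_t(x, mu = 3, alternative = "greater")
  n <- 10
  t_oracle <- (mean(x) - 3) / (sd(x) / sqrt(n))
  expect_equal(res$statistic, t_oracle, tolerance = 1e-12)
  expect_equal(res$p.value, pt(t_oracle, 9, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(res$cohens_d, res$statistic / sqrt(n), tolerance = 1e-12)
  expect_equal(res$statistic,
               unname(t.test(x, mu = 3)$statistic), tolerance = 1e-12)

  sym <- c(-3, -1, 1, 3)
  res0 <- one_sample_t(sym, alternative = "two.sided")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p.value, 1)
  expect_error(one_sample_t(rep(2, 5)), "Zero standard deviation")
})

test_that("summary-based t equals raw-data t", {
  set.seed(62)
  x <- rnorm(25, -10, 4)
  a <- one_sample_t(x, alternative = "less")
  b <- t_from_summary(mean(x), sd(x), 25, alternative = "less")
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("one-way ANOVA: two-group F equals t-squared, eta identity holds", {
  set.seed(63)
  vals <- c(rnorm(12, 0), rnorm(15, 0.8))
  g <- rep(c("a", "b"), c(12, 15))
  av <- oneway_anova(vals, g)
  tt <- t.test(vals ~ g, var.equal = TRUE)
  expect_equal(av$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(
    av$eta_sq_partial,
    av$statistic * av$df_between /
      (av$statistic * av$df_between + av$df_within),
    tolerance = 1e-12
  )
  # identical group means: F and eta_p^2 exactly 0
  flat <- oneway_anova(rep(c(1, 2, 3), 4), rep(c("a", "b"), 6))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$eta_sq_partial, 0)
  expect_error(oneway_anova(1:5, c("a", "a", "a", "a", "b")), "n >= 2")
})

test_that("JZS t-test BF matches a brute-force trapezoid quadrature", {
  trapz_bf <- function(t, n, r = sqrt(2) / 2, lo = -30, hi = 30,
                       pts = 1e6) {
    nu <- n - 1
    d <- seq(lo, hi, length.out = pts)
    f <- suppressWarnings(dt(t, nu, ncp = d * sqrt(n))) *
      dcauchy(d, 0, r)
    num <- sum((f[-1] + f[-pts]) / 2) * (d[2] - d[1])
    num / dt(t, nu, ncp = 0)
  }
  for (case in list(c(2.5, 30), c(0.8, 12), c(-4, 20))) {
    expect_equal(jzs_ttest_bf(case[1], case[2]),
                 trapz_bf(case[1], case[2]), tolerance = 1e-4)
  }
  # one-sided via truncated prior: half-line quadrature
  trapz_neg <- function(t, n, r = sqrt(2) / 2, pts = 1e6) {
    nu <- n - 1
    d <- seq(-30, 0, length.out = pts)
    f <- suppressWarnings(dt(t, nu, ncp = d * sqrt(n))) * 2 *
      dcauchy(d, 0, r)
    sum((f[-1] + f[-pts]) / 2) * (d[2] - d[1]) / dt(t, nu, ncp = 0)
  }
  expect_equal(jzs_ttest_bf(-3, 25, direction = "negative"),
               trapz_neg(-3, 25), tolerance = 1e-4)
})

test_that("JZS BF sidedness and null behaviour are coherent", {
  expect_lt(jzs_ttest_bf(0, 50), 1)
  # two-sided BF = prior-mass-weighted average of the two one-sided BFs
  bf2 <- jzs_ttest_bf(2.2, 40)
  bfp <- jzs_ttest_bf(2.2, 40, direction = "positive")
  bfn <- jzs_ttest_bf(2.2, 40, direction = "negative")
  expect_equal(bf2, (bfp + bfn) / 2, tolerance = 1e-6)
  expect_gt(bfp, bfn)
})

test_that("ANOVA BF favours the null under the null and the effect under an effect", {
  set.seed(64)
  null_vals <- rnorm(200)
  null_groups <- rep(c("a", "b"), 100)
  expect_lt(jzs_anova_bf(null_vals, null_groups), 1)

  shifted <- c(rnorm(50, 0), rnorm(50, 1))
  g <- rep(c("a", "b"), c(50, 50))
  expect_gt(jzs_anova_bf(shifted, g), 10)
  # location invariance
  expect_equal(jzs_anova_bf(shifted, g), jzs_anova_bf(shifted + 100, g),
               tolerance = 1e-6)
})

test_that("Fisher r x c agrees with a hand-rolled 2x2 hypergeometric oracle", {
  fisher_2x2_oracle <- function(m) {
    # condition on margins; sum P(table) over tables no more probable
    r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
    ks <- max(0, r1 + c1 - n):min(r1, c1)
    probs <- dhyper(ks, c1, n - c1, r1)
    p_obs <- dhyper(m[1, 1], c1, n - c1, r1)
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  set.seed(65)
  for (i in 1:5) {
    m <- matrix(rpois(4, 8) + 1, 2, 2)
    expect_equal(fisher_exact_rxc(m)$p.value, fisher_2x2_oracle(m),
                 tolerance = 1e-7)
  }
  prop <- matrix(c(10, 20, 5, 10), 2, 2, byrow = TRUE)  # proportional rows
  expect_equal(fisher_exact_rxc(prop)$p.value, 1)
})

test_that("Monte-Carlo Fisher agrees with enumeration within 3 SE", {
  m <- matrix(c(6, 2, 3, 3, 7, 1, 4, 4, 2), 3, 3)
  exact <- fisher_exact_rxc(m)$p.value
  mc <- fisher_exact_rxc(m, method = "montecarlo", n_mc = 2e4, seed = 1)
  expect_lt(abs(mc$p.value - exact), 3 * mc$mc_se + 1e-4)
})

test_that("the summary table is fully populated and percentages conserve", {
  sim <- simulate_experiment(sim_config(n_per_group = c(A = 5, B = 5)),
                             seed = 77)
  pp <- preprocess_trials(sim$trials)
  sl <- fit_effects(pp$trials)
  cls <- classify_participants(pp$trials, sl, n_iter = 300, seed = 77)
  tab <- table1_report(sl, cls)
  expect_setequal(unique(tab$group), c("A", "B", "Overall"))
  expect_false(anyNA(tab$bf10))
  expect_false(anyNA(tab$statistic))
  pct_sum <- tab$pct_reliable + tab$pct_reverse + tab$pct_not_reliable
  expect_true(all(abs(pct_sum - 100) <= 2))  # integer rounding slack

  cmp <- compare_groups(sl, "nde_slope")
  expect_equal(cmp$df_between, 1)
  expect_gt(cmp$bf, 0)
})
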