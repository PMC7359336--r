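test_that("a constant RT pool yields an exactly zero null distribution", {
  boot <- h0_bootstrap(rep(500, 100), n_iter = 50, seed = 1)
  expect_equal(boot$nde_slope, rep(0, 50))
  expect_equal(boot$nse_slope, rep(0, 50))
})

test_that("the bootstrap is deterministic given a seed and refuses tiny pools", {
  pool <- rnorm(200, 500, 90)
  b1 <- h0_bootstrap(pool, n_iter = 100, seed = 7)
  b2 <- h0_bootstrap(pool, n_iter = 100, seed = 7)
  expect_identical(b1, b2)
  expect_error(h0_bootstrap(rnorm(20, 500, 90), seed = 1), "too small")
})

test_that("bootstrap slopes match an independently coded resampling oracle", {
  set.seed(55)
  pool <- rnorm(300, 520, 80)
  n_iter <- 50
  boot <- h0_bootstrap(pool, n_iter = n_iter, set_size = 60, seed = 99)

  # second implementation: per-iteration draws, slope via lm on set means
  oracle <- withr::with_seed(99L, {
    t(vapply(seq_len(n_iter), function(i) {
      x <- sample(pool, 8 * 60, replace = TRUE)
      mns <- colMeans(matrix(x, nrow = 60))
      f <- lm(mns ~ I(abs(mag_digits - 5)) + mag_digits)
      coef(f)[2:3]
    }, numeric(2)))
  })
  expect_equal(boot$nde_slope, unname(oracle[, 1]), tolerance = 1e-12)
  expect_equal(boot$nse_slope, unname(oracle[, 2]), tolerance = 1e-12)
})

test_that("classification follows the sign and 90% CI rules", {
  set.seed(3)
  null_sym <- rnorm(5000, 0, 2)
  expect_equal(classify_slope(0, null_sym, "nde")$label, "not_reliable")

  null_narrow <- runif(5000, -5, 5)
  expect_equal(classify_slope(-40, null_narrow, "nde")$label,
               "reliable_typical")
  expect_equal(classify_slope(40, null_narrow, "nde")$label,
               "reliable_reverse")
  # sign conventions flip for the size effect
  expect_equal(classify_slope(-40, null_narrow, "nse")$label,
               "reliable_reverse")
  expect_equal(classify_slope(40, null_narrow, "nse")$label,
               "reliable_typical")

  # a slope exactly on a bound counts as inside
  cls <- classify_slope(-40, null_narrow, "nde")
  on_bound <- classify_slope(cls$ci_lo, null_narrow, "nde")
  expect_equal(on_bound$label, "not_reliable")
})

test_that("the 90% interval brackets ~5% of the null mass on each side", {
  set.seed(17)
  null <- rnorm(1000)
  cls <- classify_slope(0, null, "nde")
  expect_gt(mean(null < cls$ci_lo), 0.04)
  expect_lt(mean(null < cls$ci_lo), 0.06)
  expect_gt(mean(null > cls$ci_hi), 0.04)
  expect_lt(mean(null > cls$ci_hi), 0.06)
})

test_that("prevalence tables count, conserve and round as reported", {
  cls <- tibble::tibble(
    participant_id = sprintf("p%02d", 1:98),
    group = rep(c("A", "B"), c(49, 49)),
    effect = "nde",
    empirical_slope = -10,
    ci_lo = -5, ci_hi = 5,
    label = c(rep("reliable_typical", 89), rep("not_reliable", 9))
  )
  tab <- prevalence_table(cls)
  overall <- dplyr::filter(tab, group == "Overall")
  expect_equal(overall$pct_reliable, 91)  # 89 / 98
  expect_equal(tab$n_reliable + tab$n_reverse + tab$n_not_reliable, tab$n)

  all_null <- dplyr::mutate(cls, label = "not_reliable")
  t2 <- dplyr::filter(prevalence_table(all_null), group == "Overall")
  expect_equal(c(t2$pct_reliable, t2$pct_reverse, t2$pct_not_reliable),
               c(0, 0, 100))

  m <- prevalence_matrix(cls, "nde")
  expect_equal(dim(m), c(2, 2))  # zero 'reverse' column dropped
  expect_equal(sum(m), 98)
})

test_that("classification power rises with the size of the true distance effect", {
  frac_reliable <- vapply(c(0, -15), function(b) {
    sim <- simulate_experiment(
      sim_config(n_per_group = c(G = 25), intercept = c(500, 0),
                 b_dist = c(b, 0), b_size = c(0, 0),
                 noise = c(0, 60, 65), error_base = 0.03,
                 anticipation_rate = 0),
      seed = 71
    )
    pp <- preprocess_trials(sim$trials)
    cls <- classify_participants(pp$trials, n_iter = 500, seed = 71)
    nde <- dplyr::filter(cls, effect == "nde")
    mean(nde$label == "reliable_typical")
  }, numeric(1))
  expect_lt(frac_reliable[1], 0.3)
  expect_gt(frac_reliable[2], frac_reliable[1])
  expect_gt(frac_reliable[2], 0.8)
})
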