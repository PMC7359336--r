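test_that("participants at ~50% errors are excluded, ordinary ones kept", {
  good <- make_trials("ok", mag_digits, 500,
                      correct = rep(c(TRUE, TRUE, TRUE, TRUE, TRUE,
                                      TRUE, TRUE, FALSE), 5))  # 12.5% err
  confused <- make_trials("bad", mag_digits, 500,
                          correct = rep(c(TRUE, FALSE), 20))   # 50% err
  res <- exclude_by_error_rate(dplyr::bind_rows(good, confused), 0.40)
  expect_equal(res$excluded$participant_id, "bad")
  expect_setequal(unique(res$trials$participant_id), "ok")

  none <- exclude_by_error_rate(dplyr::bind_rows(good, confused), 1.0)
  expect_equal(nrow(none$excluded), 0)
})

test_that("arcsine accuracy transform hits its closed-form values", {
  expect_equal(arcsine_accuracy(0), 0)
  expect_equal(arcsine_accuracy(0.25), pi / 3)
  expect_equal(arcsine_accuracy(1), pi)
  expect_error(arcsine_accuracy(1.2), "\\[0, 1\\]")
})

test_that("anticipation filter removes correct sub-200 ms trials, strictly", {
  tr <- make_trials("p", c(1, 2, 3, 4), c(150, 200, 199, 500))
  res <- filter_anticipations(tr)
  expect_equal(res$n_removed, 2)
  expect_setequal(res$trials$rt_ms, c(200, 500))

  tr2 <- make_trials("p", mag_digits, 500)
  res2 <- filter_anticipations(tr2)
  expect_equal(res2$n_removed, 0)
  expect_identical(res2$trials, tr2)
})

test_that("trimming removes the hand-computed outlier and only it", {
  # 59 RTs at 500 plus one at 2000: mean 525, SD 193.6, bound 1105.9
  tr <- make_trials("p", mag_digits, c(rep(500, 59), 2000))
  res <- trim_sd(tr, k = 3)
  expect_equal(res$n_trimmed$n_trimmed, 1)
  expect_false(2000 %in% res$trials$rt_ms)

  # all identical: SD 0, nothing lies strictly outside +/- 0
  same <- trim_sd(make_trials("p", mag_digits, 500), k = 3)
  expect_equal(nrow(same$n_trimmed), 0)
})

test_that("recursive trimming matches an independent oracle and dominates single-pass", {
  rts <- c(rep(500, 17), 680, 900, 2000)
  tr <- make_trials("p", mag_digits, rts)

  oracle <- function(x, k = 3, once = FALSE) {
    repeat {
      m <- mean(x); s <- sd(x)
      out <- abs(x - m) > k * s
      if (!any(out)) return(x)
      x <- x[!out]
      if (once) return(x)
    }
  }
  rec <- trim_sd(tr, k = 3, mode = "recursive")
  single <- trim_sd(tr, k = 3, mode = "single_pass")
  expect_setequal(rec$trials$rt_ms, oracle(rts))
  expect_setequal(single$trials$rt_ms, oracle(rts, once = TRUE))
  expect_lte(nrow(rec$trials), nrow(single$trials))

  # idempotence: re-trimming a recursively trimmed set removes nothing
  again <- trim_sd(rec$trials, k = 3, mode = "recursive")
  expect_equal(nrow(again$trials), nrow(rec$trials))
})

test_that("trial accounting identity holds exactly on noisy synthetic data", {
  sim <- simulate_experiment(
    sim_config(n_per_group = c(A = 4), anticipation_rate = 0.02),
    seed = 21
  )
  pp <- preprocess_trials(sim$trials)
  acct <- pp$per_participant
  expect_equal(
    acct$n_retained + acct$n_anticipations + acct$n_trimmed + acct$n_errors,
    acct$n_trials_total
  )
  expect_gte(pp$proportion_rt_retained, 0)
  expect_lte(pp$proportion_rt_retained, 1)
  expect_equal(sum(acct$n_retained), nrow(pp$trials))
})

test_that("single-pass 3 SD trimming removes ~0.27% of pure Gaussian RTs", {
  sim <- simulate_experiment(
    sim_config(n_per_group = c(A = 50), intercept = c(600, 40),
               noise = c(0, 90, 0), error_base = 0,
               anticipation_rate = 0),
    seed = 31
  )
  pp <- preprocess_trials(sim$trials, trim_mode = "single_pass")
  frac <- sum(pp$per_participant$n_trimmed) /
    sum(pp$per_participant$n_trials_total)
  expect_gt(frac, 0.0010)
  expect_lt(frac, 0.0045)
})
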