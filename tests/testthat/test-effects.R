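test_that("distance and magnitude predictors are exactly orthogonal", {
  d <- abs(mag_digits - 5)
  m <- mag_digits
  expect_identical(sum((d - mean(d)) * (m - mean(m))), 0)
})

test_that("fit_distance_size matches the normal-equations oracle on random means", {
  set.seed(101)
  for (i in 1:5) {
    y <- rnorm(8, 500, 40)
    means <- make_means(function(d) y)
    fit <- fit_distance_size(means)
    oracle <- ols_oracle(y, abs(mag_digits - 5), mag_digits)
    expect_equal(fit$intercept, oracle[1], tolerance = 1e-10)
    expect_equal(fit$nde_slope, oracle[2], tolerance = 1e-10)
    expect_equal(fit$nse_slope, oracle[3], tolerance = 1e-10)

    # orthogonality => multiple regression == the two simple regressions
    dd <- abs(mag_digits - 5)
    expect_equal(fit$nde_slope, cov(dd, y) / var(dd), tolerance = 1e-10)
    expect_equal(fit$nse_slope, cov(mag_digits, y) / var(mag_digits),
                 tolerance = 1e-10)
  }
})

test_that("exact and degenerate digit means give exact slopes", {
  exact <- fit_distance_size(
    make_means(function(d) 500 - 5 * abs(d - 5) + 2 * d)
  )
  expect_equal(exact$nde_slope, -5, tolerance = 1e-10)
  expect_equal(exact$nse_slope, 2, tolerance = 1e-10)
  expect_equal(exact$r_squared, 1, tolerance = 1e-10)

  flat <- fit_distance_size(make_means(function(d) rep(500, 8)))
  expect_equal(flat$nde_slope, 0)
  expect_equal(flat$nse_slope, 0)
  expect_equal(flat$r_squared, 0)
})

test_that("digit means aggregate correctly and missing digits are named", {
  tr <- make_trials("p", c(7, 7, 3), c(480, 520, 400))
  m <- aggregate_digit_means(tr, min_cell = 1) |>
    expect_error("Missing digit")
  full <- make_trials("p", rep(mag_digits, 2), rep(500, 16))
  full$rt_ms[full$number == 7] <- c(480, 520)
  m <- aggregate_digit_means(full, min_cell = 1)
  expect_equal(m$mean_rt[m$number == 7], 500)
  expect_true(all(m$n == 2))
  expect_true(all(aggregate_digit_means(full, min_cell = 5)$low_n))
})

test_that("ratio slope equals the simple-regression oracle", {
  r <- digit_ratio(mag_digits)
  expect_equal(fit_ratio(make_means(function(d) 100 * digit_ratio(d)))$ratio_slope,
               100, tolerance = 1e-10)
  expect_equal(fit_ratio(make_means(function(d) rep(500, 8)))$ratio_slope, 0)

  set.seed(7)
  y <- rnorm(8, 500, 30)
  expect_equal(fit_ratio(make_means(function(d) y))$ratio_slope,
               cov(r, y) / var(r), tolerance = 1e-10)
})

test_that("SNARC slope recovers constructed right-minus-left differences", {
  # dRT(d) = 10 - 2 d: right RT = 500 + (10 - 2 d)/... build directly
  both <- dplyr::bind_rows(
    make_trials("p", mag_digits, 500, response_side = "left", block = 1L),
    make_trials("p", mag_digits, 500 + 10 - 2 * mag_digits,
                response_side = "right", block = 2L)
  )
  expect_equal(fit_snarc(both)$snarc_slope, -2, tolerance = 1e-10)

  sym <- dplyr::bind_rows(
    make_trials("p", mag_digits, 500, response_side = "left"),
    make_trials("p", mag_digits, 500, response_side = "right")
  )
  expect_equal(fit_snarc(sym)$snarc_slope, 0)

  onesided <- make_trials("p", mag_digits, 500, response_side = "right")
  expect_error(fit_snarc(onesided), "both response sides")
})

test_that("standardized slopes equal the correlation closed form", {
  set.seed(13)
  y <- rnorm(8, 500, 25)
  std <- standardize_slopes(make_means(function(d) y))
  # orthogonal predictors: standardized multiple-regression slope = r(y, x)
  expect_equal(std$std_nde_slope, cor(y, abs(mag_digits - 5)),
               tolerance = 1e-10)
  expect_equal(std$std_nse_slope, cor(y, mag_digits), tolerance = 1e-10)

  raw <- fit_distance_size(make_means(function(d) y))
  expect_equal(sign(std$std_nde_slope), sign(raw$nde_slope))

  no_size <- standardize_slopes(
    make_means(function(d) 500 - 5 * abs(d - 5))
  )
  expect_equal(no_size$std_nse_slope, 0, tolerance = 1e-10)
})
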