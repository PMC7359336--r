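#' Configuration of a synthetic magnitude-classification experiment
#'
#' Builds the full generative specification used by
#' [simulate_experiment()]: the between-participant distribution of
#' baseline speed and of each effect slope, the within-participant
#' (trial-level) noise model, and the contamination processes.
#'
#' The defaults describe a cohort typical of adult magnitude-classification
#' studies with the 2 x 240-trial design: four groups of 13/14/15/56
#' participants, an overall mean RT near 504 ms with a between-participant
#' SD near 79 ms, a distance slope distributed N(-13.08, 7.90) ms per
#' distance unit, a size slope N(1.20, 3.16) ms per magnitude unit, and
#' ex-Gaussian trial noise with SD sqrt(sigma^2 + tau^2) ~ 90 ms, the
#' typical intraindividual RT variability in this task. Error probability
#' decays exponentially with distance so that overall accuracy sits near
#' 97%.
#'
#' @param n_per_group Named integer vector: participants per group.
#' @param intercept Length-2 numeric `(mean, sd)` in ms of the
#'   per-participant baseline RT (the regression intercept).
#' @param b_dist `(mean, sd)` of the per-participant distance slope, in ms
#'   per unit of |digit - 5|. Negative means the typical distance effect.
#' @param b_size `(mean, sd)` of the size slope, in ms per unit of digit
#'   magnitude. Positive means the typical size effect.
#' @param b_snarc `(mean, sd)` of the SNARC slope, in ms per magnitude
#'   unit of the right-minus-left RT difference. Negative means the
#'   typical SNARC effect. The default switches the effect off.
#' @param noise Length-3 numeric `(mu, sigma, tau)` in ms: ex-Gaussian
#'   trial noise, Normal(mu, sigma) + Exponential(tau).
#' @param error_base Baseline per-trial error probability at distance 0.
#' @param error_distance_decay Nonnegative rate at which error probability
#'   shrinks with distance: p(error) = error_base * exp(-decay * distance).
#' @param anticipation_rate Probability that a trial is replaced by an
#'   anticipation: an RT drawn uniformly in (80, 200) ms with a random
#'   response, removable downstream by the < 200 ms filter.
#' @param rt_ceiling_ms Response deadline in ms; trials reaching it are
#'   recorded as timeouts (incorrect, missing RT).
#' @param trials_per_digit Presentations of each digit per block.
#' @param seed Default RNG seed carried to [simulate_experiment()].
#'
#' @return A list with class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_per_group = c(A = 5), seed = 1)
#' cfg$b_dist
#' @export
sim_config <- function(n_per_group = c(M = 13, E = 14, S = 15, R = 56),
                       intercept = c(466, 75),
                       b_dist = c(-13.08, 7.90),
                       b_size = c(1.20, 3.16),
                       b_snarc = c(0, 0),
                       noise = c(mu = 0, sigma = 60, tau = 65),
                       error_base = 0.06,
                       error_distance_decay = 0.3,
                       anticipation_rate = 0.0005,
                       rt_ceiling_ms = 2000,
                       trials_per_digit = 30,
                       seed = NULL) {
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group)))) {
    abort("`n_per_group` must be a named vector of group sizes.")
  }
  if (any(n_per_group < 1)) abort("Group sizes must be >= 1.")
  for (nm in c("intercept", "b_dist", "b_size", "b_snarc")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 2 || anyNA(v)) {
      abort(sprintf("`%s` must be a numeric (mean, sd) pair.", nm))
    }
    if (v[2] < 0) abort(sprintf("`%s` sd must be nonnegative.", nm))
  }
  if (!is.numeric(noise) || length(noise) != 3 || anyNA(noise)) {
    abort("`noise` must be a numeric (mu, sigma, tau) triple.")
  }
  if (noise[2] < 0 || noise[3] < 0) abort("`sigma` and `tau` must be >= 0.")
  assert_prob(error_base, "error_base")
  assert_prob(anticipation_rate, "anticipation_rate")
  if (error_distance_decay < 0) abort("`error_distance_decay` must be >= 0.")
  if (rt_ceiling_ms <= 200) abort("`rt_ceiling_ms` must exceed 200 ms.")
  if (trials_per_digit < 1) abort("`trials_per_digit` must be >= 1.")

  structure(
    list(
      n_per_group = n_per_group,
      intercept = unname(intercept),
      b_dist = unname(b_dist),
      b_size = unname(b_size),
      b_snarc = unname(b_snarc),
      noise = setNames(unname(noise), c("mu", "sigma", "tau")),
      error_base = error_base,
      error_distance_decay = error_distance_decay,
      anticipation_rate = anticipation_rate,
      rt_ceiling_ms = rt_ceiling_ms,
      trials_per_digit = trials_per_digit,
      seed = seed
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  groups:       ",
      paste(sprintf("%s=%d", names(x$n_per_group), x$n_per_group),
            collapse = ", "), "\n")
  cat(sprintf("  intercept:     N(%g, %g) ms\n", x$intercept[1], x$intercept[2]))
  cat(sprintf("  b_dist:        N(%g, %g) ms/unit\n", x$b_dist[1], x$b_dist[2]))
  cat(sprintf("  b_size:        N(%g, %g) ms/unit\n", x$b_size[1], x$b_size[2]))
  cat(sprintf("  b_snarc:       N(%g, %g) ms/unit\n", x$b_snarc[1], x$b_snarc[2]))
  cat(sprintf("  noise:         exGauss(mu=%g, sigma=%g, tau=%g) ms\n",
              x$noise[1], x$noise[2], x$noise[3]))
  cat(sprintf("  errors:        %g * exp(-%g * distance)\n",
              x$error_base, x$error_distance_decay))
  cat(sprintf("  anticipations: rate %g\n", x$anticipation_rate))
  cat(sprintf("  deadline:      %g ms; %d trials/digit/block\n",
              x$rt_ceiling_ms, x$trials_per_digit))
  invisible(x)
}
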