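# Group-level inference on the per-participant slopes: one-sided
# one-sample t-tests with Cohen's d, one-way ANOVA with partial
# eta-squared, default-prior (JZS) Bayes factors, and exact r x c Fisher
# tests on prevalence tables.

#' One-sample t-test with Cohen's d
#'
#' Tests a vector of per-participant slopes against `mu`
#' (`t = (mean - mu) / (SD / sqrt(n))`) with the stated tail, and reports
#' the standardized effect size `d = (mean - mu) / SD`, so that
#' `d = t / sqrt(n)` exactly.
#'
#' @param values Numeric vector, `n >= 2`, nonzero SD.
#' @param mu Null value.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return Tibble with `estimate` (mean), `sd`, `n`, `statistic`, `df`,
#'   `p.value`, `cohens_d`, `alternative`.
#' @export
one_sample_t <- function(values, mu = 0,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) abort("Need at least 2 finite values.")
  s <- sd(values)
  if (s == 0) abort("Zero standard deviation; t undefined.")
  t_from_summary(mean(values), s, n, mu = mu, alternative = alternative)
}

#' One-sample t statistics from summary values
#'
#' The closed-form arithmetic of [one_sample_t()] applied directly to a
#' printed mean, SD and n, as needed when re-deriving test statistics
#' from a published summary table.
#'
#' @param mean,sd,n Sample mean, SD and size.
#' @inheritParams one_sample_t
#' @return Same one-row tibble as [one_sample_t()].
#' @examples
#' t_from_summary(-13.08, 7.90, 98, alternative = "less")
#' @export
t_from_summary <- function(mean, sd, n, mu = 0,
                           alternative = c("two.sided", "less",
                                           "greater")) {
  alternative <- match.arg(alternative)
  if (n < 2 || sd <= 0) abort("Need n >= 2 and sd > 0.")
  stat <- (mean - mu) / (sd / sqrt(n))
  df <- n - 1
  p <- switch(alternative,
    two.sided = 2 * pt(-abs(stat), df),
    less = pt(stat, df),
    greater = pt(stat, df, lower.tail = FALSE)
  )
  tibble::tibble(
    estimate = mean, sd = sd, n = as.integer(n),
    statistic = stat, df = df, p.value = p,
    cohens_d = (mean - mu) / sd, alternative = alternative
  )
}

#' One-way between-participants ANOVA with partial eta-squared
#'
#' Standard fixed-effects decomposition of `values` over `groups`, with
#' `eta_p^2 = SS_between / (SS_between + SS_within)`.
#'
#' @param values Numeric vector.
#' @param groups Group labels, same length; at least two groups with at
#'   least two observations each.
#' @return Tibble with `statistic` (F), `df_between`, `df_within`,
#'   `p.value`, `eta_sq_partial`.
#' @export
oneway_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) abort("Need at least two groups.")
  if (any(table(groups) < 2)) abort("Every group needs n >= 2.")
  fit <- lm(values ~ groups)
  a <- anova(fit)
  ss_b <- a$`Sum Sq`[1]
  ss_w <- a$`Sum Sq`[2]
  tibble::tibble(
    statistic = a$`F value`[1],
    df_between = a$Df[1],
    df_within = a$Df[2],
    p.value = a$`Pr(>F)`[1],
    eta_sq_partial = ss_b / (ss_b + ss_w)
  )
}

#' JZS Bayes factor for a one-sample t-test
#'
#' Default-prior Bayes factor for the presence of a standardized effect
#' delta: under H1, delta follows a Cauchy(0, `rscale`) prior; under H0,
#' delta = 0. The marginal likelihood under H1 is the noncentral-t
#' likelihood of the observed `t` averaged over the prior by adaptive
#' 1-D quadrature, so
#' `BF10 = integral dt(t; df, delta sqrt(n)) dCauchy(delta) / dt(t; df, 0)`.
#' One-sided (order-restricted) variants truncate and renormalise the
#' prior to the predicted half-line.
#'
#' @param t Observed t statistic.
#' @param n Sample size (df = n - 1).
#' @param rscale Cauchy prior scale; sqrt(2)/2 is the conventional
#'   default for t-tests.
#' @param direction `"two_sided"`, or the predicted sign of the effect:
#'   `"positive"` / `"negative"`.
#' @param rel_tol Relative integration tolerance.
#' @return `BF10`, a single positive number (evidence for H1 over H0).
#' @examples
#' jzs_ttest_bf(-5.06, 13, direction = "negative") # ~ 236
#' @export
jzs_ttest_bf <- function(t, n, rscale = sqrt(2) / 2,
                         direction = c("two_sided", "positive",
                                       "negative"),
                         rel_tol = 1e-6) {
  direction <- match.arg(direction)
  if (n < 2) abort("Need n >= 2.")
  if (rscale <= 0) abort("`rscale` must be positive.")
  nu <- n - 1
  # dt() warns about reduced tail precision at large ncp, where the
  # density is effectively zero; harmless for the integral
  lik <- function(delta) suppressWarnings(dt(t, nu, ncp = delta * sqrt(n)))
  bounds <- switch(direction,
    two_sided = c(-Inf, Inf),
    positive = c(0, Inf),
    negative = c(-Inf, 0)
  )
  prior_mass <- if (direction == "two_sided") 1 else 0.5
  num <- tryCatch(
    integrate(function(d) lik(d) * dcauchy(d, 0, rscale) / prior_mass,
              bounds[1], bounds[2], rel.tol = rel_tol,
              stop.on.error = TRUE),
    error = function(e) abort(paste0("BF integration failed: ",
                                     conditionMessage(e)))
  )
  if (num$message != "OK") abort("BF integration did not converge.")
  num$value / dt(t, nu, ncp = 0)
}

#' Default-prior Bayes factor for a one-way ANOVA
#'
#' Bayes factor comparing the one-way fixed-effects model (group effects
#' iid Normal(0, g sigma^2) with a scaled inverse-chi-squared mixing
#' prior on g, scale `rscale_fixed`) against the grand-mean-only null,
#' computed by 1-D quadrature over g after integrating the location and
#' scale analytically. This is an independent implementation of the
#' standard default-prior ANOVA Bayes factor; agreement with reference
#' implementations is expected to a few percent.
#'
#' @param values Numeric response vector.
#' @param groups Group labels.
#' @param rscale_fixed Prior scale for the fixed effects (conventional
#'   default 0.5).
#' @param rel_tol Relative integration tolerance.
#' @return `BF10` for the group-effects model over the null.
#' @export
jzs_anova_bf <- function(values, groups, rscale_fixed = 0.5,
                         rel_tol = 1e-6) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) abort("Need at least two groups.")
  if (any(table(groups) < 2)) abort("Every group needs n >= 2.")
  n <- length(values)
  z <- stats::model.matrix(~ groups - 1)
  zc <- scale(z, center = TRUE, scale = FALSE)
  yc <- values - mean(values)
  s_tot <- sum(yc^2)
  if (s_tot == 0) abort("Zero variance in `values`.")
  ztz <- crossprod(zc)
  zty <- crossprod(zc, yc)
  a <- ncol(z)

  log_m <- function(g) {
    # marginal likelihood ratio at fixed g (location/scale integrated out)
    vapply(g, function(gi) {
      m <- diag(a) + gi * ztz
      q <- crossprod(zty, solve(ztz + diag(a) / gi, zty))[1, 1]
      -0.5 * determinant(m, logarithm = TRUE)$modulus -
        ((n - 1) / 2) * log1p(-q / s_tot)
    }, numeric(1))
  }
  r <- rscale_fixed
  integrand <- function(g) {
    exp(log_m(g) + 0.5 * log(r^2 / 2) - lgamma(0.5) -
          1.5 * log(g) - r^2 / (2 * g))
  }
  res <- tryCatch(
    integrate(integrand, 0, Inf, rel.tol = rel_tol, stop.on.error = TRUE),
    error = function(e) abort(paste0("BF integration failed: ",
                                     conditionMessage(e)))
  )
  res$value
}

#' Exact Fisher test for an r x c prevalence table
#'
#' Exact conditional test of independence for a contingency table of
#' label counts by group: the p-value sums the multivariate
#' hypergeometric probabilities (margins fixed) of every table no more
#' probable than the observed one. `"enumerate"` computes the exact sum
#' over all feasible tables; `"montecarlo"` estimates it from `n_mc`
#' tables sampled conditionally on the margins and also reports the
#' standard error of the estimate.
#'
#' @param counts Nonnegative integer matrix (groups x labels).
#' @param method `"enumerate"` (exact) or `"montecarlo"`.
#' @param n_mc Monte-Carlo sample size.
#' @param seed RNG seed for `"montecarlo"`.
#' @return Tibble with `p.value`, `method`, and `mc_se` (NA for the
#'   exact method).
#' @examples
#' tab <- matrix(c(12, 1, 13, 1, 11, 4, 53, 3), nrow = 4, byrow = TRUE)
#' fisher_exact_rxc(tab) # p ~ 0.086
#' @export
fisher_exact_rxc <- function(counts, method = c("enumerate", "montecarlo"),
                             n_mc = 1e6, seed = NULL) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be nonnegative integers.")
  }
  if (method == "enumerate") {
    p <- fisher.test(counts, workspace = 2e7)$p.value
    tibble::tibble(p.value = p, method = "enumerate", mc_se = NA_real_)
  } else {
    p <- with_seed_opt(seed,
      fisher.test(counts, simulate.p.value = TRUE, B = n_mc)$p.value
    )
    tibble::tibble(
      p.value = p, method = "montecarlo",
      mc_se = sqrt(p * (1 - p) / n_mc)
    )
  }
}

#' Group-by-effect summary table
#'
#' Assembles the canonical results table of a magnitude-classification
#' study: for each effect and each group (plus an overall row), the mean
#' and SD of the per-participant slopes, the one-sided one-sample t-test
#' in the effect's typical direction, Cohen's d, the matching
#' order-restricted JZS Bayes factor, and the prevalence percentages from
#' the bootstrap classification.
#'
#' @param slopes Output of [fit_effects()].
#' @param classifications Output of [classify_participants()] (optional;
#'   prevalence columns are omitted without it).
#' @param effects Effects to summarise; the typical direction is
#'   `"negative"` for the NDE and `"positive"` for the NSE.
#' @param rscale Cauchy prior scale for the Bayes factors.
#' @return Tibble of class `"mag_table1"`, one row per effect x group.
#' @export
table1_report <- function(slopes, classifications = NULL,
                          effects = c("nde", "nse"),
                          rscale = sqrt(2) / 2) {
  assert_cols(slopes, c("participant_id"), "slope table")
  has_group <- "group" %in% names(slopes) && !all(is.na(slopes$group))
  grp <- if (has_group) slopes$group else rep("all", nrow(slopes))

  rows <- purrr::map_dfr(effects, function(eff) {
    col <- paste0(eff, "_slope")
    assert_cols(slopes, col, "slope table")
    direction <- if (eff == "nde") "negative" else "positive"
    alt <- if (eff == "nde") "less" else "greater"
    summarise_cell <- function(vals, label) {
      tt <- one_sample_t(vals, alternative = alt)
      dplyr::mutate(
        tt,
        effect = eff, group = label,
        bf10 = jzs_ttest_bf(tt$statistic, tt$n, rscale = rscale,
                            direction = direction),
        .before = 1
      )
    }
    out <- purrr::map_dfr(
      unique(grp), function(g) summarise_cell(slopes[[col]][grp == g], g)
    )
    dplyr::bind_rows(out, summarise_cell(slopes[[col]], "Overall"))
  })

  if (!is.null(classifications)) {
    prev <- prevalence_table(classifications) |>
      dplyr::select("group", "effect", "pct_reliable", "pct_reverse",
                    "pct_not_reliable")
    if (!has_group) {
      prev <- dplyr::filter(prev, .data$group == "Overall")
      rows <- rows |>
        dplyr::select(-"group") |>
        dplyr::left_join(dplyr::select(prev, -"group"), by = "effect") |>
        dplyr::mutate(group = "Overall")
    } else {
      rows <- dplyr::left_join(rows, prev, by = c("group", "effect"))
    }
  }
  class(rows) <- c("mag_table1", class(rows))
  rows
}

#' Between-group comparison of a slope measure
#'
#' One-way ANOVA across groups plus the default-prior ANOVA Bayes
#' factor, for any per-participant column of a slope table.
#'
#' @param slopes Output of [fit_effects()] with a `group` column.
#' @param measure Column to compare (e.g. `"nde_slope"`, `"mean_rt"`).
#' @param rscale_fixed Prior scale for [jzs_anova_bf()].
#' @return One-row tibble: ANOVA statistics plus `bf`.
#' @export
compare_groups <- function(slopes, measure, rscale_fixed = 0.5) {
  assert_cols(slopes, c("group", measure), "slope table")
  av <- oneway_anova(slopes[[measure]], slopes$group)
  dplyr::mutate(
    av, measure = measure,
    bf = jzs_anova_bf(slopes[[measure]], slopes$group,
                      rscale_fixed = rscale_fixed),
    .before = 1
  )
}
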