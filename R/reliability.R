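# Split-half reliability of the slope measures, plus the correlation
# machinery used alongside it (Spearman-Brown projection, correction for
# attenuation, partial correlation).

#' Spearman-Brown correction for double test length
#'
#' Projects a half-test correlation to the reliability of the full-length
#' test: `2 r / (1 + r)`. Monotone increasing on (-1, 1].
#'
#' @param r Half-test correlation(s), each > -1.
#' @return Corrected reliability estimate(s).
#' @examples
#' spearman_brown(0.5) # 2/3
#' @export
spearman_brown <- function(r) {
  if (any(r <= -1, na.rm = TRUE)) {
    abort("Spearman-Brown is undefined for r <= -1.")
  }
  2 * r / (1 + r)
}

#' Correction of a correlation for attenuation
#'
#' Divides an observed correlation by the geometric mean of the two
#' measures' reliabilities, `r / sqrt(rel_x * rel_y)`, estimating the
#' correlation between the error-free constructs. Results outside
#' \[-1, 1\] (possible when reliabilities are underestimated) are clipped
#' with a warning.
#'
#' @param r_xy Observed correlation.
#' @param rel_x,rel_y Reliabilities in (0, 1].
#' @return Disattenuated correlation in \[-1, 1\].
#' @export
disattenuate <- function(r_xy, rel_x, rel_y) {
  if (any(c(rel_x, rel_y) <= 0) || any(c(rel_x, rel_y) > 1)) {
    abort("Reliabilities must lie in (0, 1].")
  }
  out <- r_xy / sqrt(rel_x * rel_y)
  if (any(abs(out) > 1)) {
    warn("Disattenuated correlation exceeded |1|; clipped.")
    out <- pmin(1, pmax(-1, out))
  }
  out
}

#' Partial correlation controlling for a third variable
#'
#' First-order partial correlation
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`, equivalent to
#' correlating the OLS residuals of `x` on `z` with those of `y` on `z`,
#' with a t-based p-value on `n - 3` degrees of freedom.
#'
#' @param x,y,z Equal-length numeric vectors, `n >= 4`, each with
#'   positive variance; `z` must not be collinear with `x` or `y`.
#' @return Tibble with `estimate`, `statistic`, `df`, `p.value`.
#' @export
partial_correlation <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) abort("Vectors must match in length.")
  if (n < 4) abort("Partial correlation needs n >= 4.")
  if (sd(x) == 0 || sd(y) == 0 || sd(z) == 0) {
    abort("Degenerate (zero-variance) input.")
  }
  r_xy <- cor(x, y); r_xz <- cor(x, z); r_yz <- cor(y, z)
  denom <- (1 - r_xz^2) * (1 - r_yz^2)
  if (denom <= 1e-12) {
    abort("`z` is collinear with `x` or `y`; partial correlation undefined.")
  }
  est <- (r_xy - r_xz * r_yz) / sqrt(denom)
  df <- n - 3
  stat <- est * sqrt(df / (1 - est^2))
  tibble::tibble(
    estimate = est, statistic = stat, df = df,
    p.value = 2 * pt(-abs(stat), df)
  )
}

# Random half assignment within each (participant, digit, block) cell.
# Returns an integer vector of 1s and 2s aligned with `trials` rows: each
# cell is split as evenly as possible, the odd trial landing in a random
# half. Stratifying by digit and block keeps both halves faithful to the
# 8-point design.
split_halves <- function(cell_id, n) {
  u <- runif(n)
  ord <- order(cell_id, u)
  sizes <- tabulate(cell_id[ord])
  sizes <- sizes[sizes > 0]
  half <- integer(n)
  half[ord] <- unlist(lapply(sizes, function(k) {
    h <- rep_len(c(1L, 2L), k)
    if (k %% 2 == 1 && runif(1) < 0.5) h <- 3L - h
    h
  }), use.names = FALSE)
  half
}

#' Split-half reliability of an effect slope
#'
#' Estimates how stable a per-participant slope measure is: on each of
#' `n_splits` random splits, every participant's trials are divided into
#' two halves (stratified within participant x digit x block cells so
#' each half preserves the design), the slope is fitted on each half, and
#' the two half-slopes are correlated across participants. The mean
#' correlation over splits is then Spearman-Brown corrected to full test
#' length.
#'
#' @param trials Preprocessed trial table (retained RT set).
#' @param effect One of `"nde"`, `"nse"`, `"ratio"`, `"snarc"`.
#' @param n_splits Number of random splits to average over.
#' @param seed RNG seed for the splits.
#' @param fisher_z Average correlations on the Fisher-z scale instead of
#'   the raw r scale.
#'
#' @return Tibble with one row: `effect`, `r_half` (mean split
#'   correlation), `r_sb` (Spearman-Brown corrected), `n_splits`,
#'   `n_participants`.
#' @examples
#' sim <- simulate_experiment(sim_config(n_per_group = c(A = 8), seed = 2))
#' pp <- preprocess_trials(sim$trials)
#' split_half_reliability(pp$trials, "nde", n_splits = 20, seed = 1)
#' @export
split_half_reliability <- function(trials,
                                   effect = c("nde", "nse", "ratio",
                                              "snarc"),
                                   n_splits = 1000, seed = NULL,
                                   fisher_z = FALSE) {
  effect <- match.arg(effect)
  assert_cols(trials, c("participant_id", "number", "rt_ms"))
  cell_keys <- c("participant_id", "number",
                 if ("block" %in% names(trials)) "block",
                 if (effect == "snarc") "response_side")
  cell_id <- as.integer(interaction(trials[cell_keys], drop = TRUE))
  n <- nrow(trials)

  half_slopes <- function(df) {
    s <- switch(effect,
      nde = fit_distance_size(aggregate_digit_means(df, min_cell = 1)) |>
        dplyr::select("participant_id", slope = "nde_slope"),
      nse = fit_distance_size(aggregate_digit_means(df, min_cell = 1)) |>
        dplyr::select("participant_id", slope = "nse_slope"),
      ratio = fit_ratio(aggregate_digit_means(df, min_cell = 1)) |>
        dplyr::select("participant_id", slope = "ratio_slope"),
      snarc = fit_snarc(df) |>
        dplyr::select("participant_id", slope = "snarc_slope")
    )
    s
  }

  rs <- with_seed_opt(seed, {
    vapply(seq_len(n_splits), function(s) {
      half <- split_halves(cell_id, n)
      # a split can strand a 1-trial digit cell in one half only; such
      # splits cannot be scored and are dropped from the average
      tryCatch({
        s1 <- half_slopes(trials[half == 1L, , drop = FALSE])
        s2 <- half_slopes(trials[half == 2L, , drop = FALSE])
        both <- dplyr::inner_join(s1, s2, by = "participant_id",
                                  suffix = c("_1", "_2"))
        if (sd(both$slope_1) == 0 || sd(both$slope_2) == 0) NA_real_
        else cor(both$slope_1, both$slope_2)
      }, error = function(e) NA_real_)
    }, numeric(1))
  })
  if (all(is.na(rs))) abort("No split could be scored; too few trials per digit.")

  r_half <- if (fisher_z) tanh(mean(atanh(pmin(pmax(rs, -0.999999),
                                               0.999999)), na.rm = TRUE))
            else mean(rs, na.rm = TRUE)
  tibble::tibble(
    effect = effect,
    r_half = r_half,
    r_sb = spearman_brown(r_half),
    n_splits = n_splits,
    n_participants = dplyr::n_distinct(trials$participant_id)
  )
}
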