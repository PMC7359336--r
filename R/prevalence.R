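# H0 bootstrap classification of individual effects.
#
# The null hypothesis for one participant is that their RTs do not depend
# on the presented digit. Resampling the participant's pooled retained RTs
# into 8 arbitrary "digit" sets destroys any digit-RT association while
# preserving the RT distribution, so the slopes fitted to those resampled
# sets trace out the distribution of slopes expected under H0 for that
# very participant.

# Slope-extraction weights for the fixed 8-digit design: rows of
# (X'X)^{-1} X' for X = [1, |d-5|, d], so that slopes are a linear map of
# the 8 set means. Identical to fit_distance_size() on the same means.
slope_weights <- function() {
  x <- cbind(1, abs(mag_digits - 5), mag_digits)
  b <- solve(crossprod(x), t(x))
  list(nde = b[2, ], nse = b[3, ])
}

#' Per-participant H0 bootstrap of distance and size slopes
#'
#' Draws, `n_iter` times, 8 sets of `set_size` RTs with replacement from
#' one participant's pooled retained RTs, labels the sets with the digits
#' 1, 2, 3, 4, 6, 7, 8, 9 (and their distances from 5), averages each
#' set, and fits the distance/size regression to the 8 set means. The
#' collected slopes form the participant's null distribution for both
#' effects.
#'
#' @param rts Numeric vector: the participant's retained correct RTs,
#'   pooled over digits and blocks.
#' @param n_iter Number of bootstrap iterations.
#' @param set_size RTs per resampled digit set (60 mirrors the paradigm's
#'   30 presentations per digit x 2 blocks).
#' @param seed Optional RNG seed; identical seeds give identical draws.
#' @param min_pool Smallest RT pool accepted.
#'
#' @return Tibble with columns `iter`, `nde_slope`, `nse_slope`.
#' @examples
#' boot <- h0_bootstrap(rnorm(400, 500, 90), n_iter = 200, seed = 1)
#' quantile(boot$nde_slope, c(0.05, 0.95))
#' @export
h0_bootstrap <- function(rts, n_iter = 5000, set_size = 60, seed = NULL,
                         min_pool = 50) {
  rts <- rts[!is.na(rts)]
  if (length(rts) < min_pool) {
    abort(sprintf(
      "RT pool too small for a stable null distribution: %d < %d.",
      length(rts), min_pool
    ))
  }
  w <- slope_weights()
  with_seed_opt(seed, {
    draws <- sample(rts, n_iter * length(mag_digits) * set_size,
                    replace = TRUE)
    set_means <- rowMeans(matrix(draws, ncol = set_size, byrow = TRUE))
    mm <- matrix(set_means, ncol = length(mag_digits), byrow = TRUE)
    tibble::tibble(
      iter = seq_len(n_iter),
      nde_slope = as.numeric(mm %*% w$nde),
      nse_slope = as.numeric(mm %*% w$nse)
    )
  })
}

#' Classify one empirical slope against its H0 null distribution
#'
#' Computes the central `ci` interval of the bootstrap null slopes
#' (type-7 percentiles) and labels the participant:
#' `reliable_typical` if the empirical slope has the typical sign
#' (negative for the NDE, positive for the NSE) and lies strictly outside
#' the interval; `reliable_reverse` if it has the opposite sign and lies
#' strictly outside; `not_reliable` otherwise. A slope exactly on a bound
#' counts as inside.
#'
#' @param empirical_slope The participant's fitted slope.
#' @param null_slopes Numeric vector of bootstrap slopes.
#' @param effect `"nde"` or `"nse"` (fixes the typical sign).
#' @param ci Central null-interval mass (default 0.90).
#'
#' @return Tibble with `ci_lo`, `ci_hi`, `label`.
#' @export
classify_slope <- function(empirical_slope, null_slopes,
                           effect = c("nde", "nse"), ci = 0.90) {
  effect <- match.arg(effect)
  if (!is.finite(empirical_slope)) abort("Empirical slope must be finite.")
  if (length(null_slopes) == 0) abort("Empty null distribution.")
  assert_prob(ci, "ci")
  q <- quantile(null_slopes, c((1 - ci) / 2, (1 + ci) / 2),
                type = 7, names = FALSE)
  outside <- empirical_slope < q[1] || empirical_slope > q[2]
  typical_sign <- if (effect == "nde") -1 else 1
  label <- if (!outside) {
    "not_reliable"
  } else if (sign(empirical_slope) == typical_sign) {
    "reliable_typical"
  } else {
    "reliable_reverse"
  }
  tibble::tibble(ci_lo = q[1], ci_hi = q[2], label = label)
}

#' H0 bootstrap classification of every participant
#'
#' Runs [h0_bootstrap()] and [classify_slope()] for each participant,
#' for both the distance and the size effect. Each participant gets an
#' independent RNG stream derived from `seed` and the participant id, so
#' results do not depend on processing order.
#'
#' @param trials Preprocessed trial table (retained RT set).
#' @param slopes Per-participant slopes from [fit_effects()]; computed
#'   from `trials` if omitted.
#' @param n_iter,set_size,min_pool Passed to [h0_bootstrap()].
#' @param ci Passed to [classify_slope()].
#' @param seed Master seed for the per-participant streams.
#'
#' @return Tibble of class `"mag_classification"`, one row per
#'   participant x effect: `participant_id`, `group`, `effect`,
#'   `empirical_slope`, `ci_lo`, `ci_hi`, `label`.
#' @examples
#' sim <- simulate_experiment(sim_config(n_per_group = c(A = 3), seed = 1))
#' cls <- classify_participants(preprocess_trials(sim$trials)$trials,
#'                              n_iter = 200, seed = 1)
#' prevalence_table(cls)
#' @export
classify_participants <- function(trials, slopes = NULL, n_iter = 5000,
                                  set_size = 60, ci = 0.90, seed = NULL,
                                  min_pool = 50) {
  if (is.null(slopes)) slopes <- fit_effects(trials)
  assert_cols(slopes, c("participant_id", "nde_slope", "nse_slope"),
              "slope table")
  out <- purrr::map_dfr(seq_len(nrow(slopes)), function(i) {
    pid <- slopes$participant_id[i]
    pool <- trials$rt_ms[trials$participant_id == pid]
    boot <- h0_bootstrap(
      pool, n_iter = n_iter, set_size = set_size,
      seed = if (is.null(seed)) NULL else derive_seed(seed, pid),
      min_pool = min_pool
    )
    purrr::map_dfr(c("nde", "nse"), function(eff) {
      emp <- slopes[[paste0(eff, "_slope")]][i]
      cls <- classify_slope(emp, boot[[paste0(eff, "_slope")]],
                            effect = eff, ci = ci)
      tibble::tibble(
        participant_id = pid,
        group = if ("group" %in% names(slopes)) slopes$group[i]
                else NA_character_,
        effect = eff,
        empirical_slope = emp,
        cls
      )
    })
  })
  class(out) <- c("mag_classification", class(out))
  out
}

#' Prevalence of reliable effects by group
#'
#' Tabulates the bootstrap labels into counts and integer percentages per
#' group and overall, the summary underlying statements like "91% of
#' participants had a reliable distance effect".
#'
#' @param classifications Output of [classify_participants()].
#'
#' @return Tibble: one row per effect x group (plus an `"Overall"` row
#'   per effect) with `n`, counts `n_reliable`, `n_reverse`,
#'   `n_not_reliable`, and percentages `pct_reliable`, `pct_reverse`,
#'   `pct_not_reliable` rounded to integers.
#' @export
prevalence_table <- function(classifications) {
  assert_cols(classifications, c("participant_id", "effect", "label"),
              "classification table")
  cls <- classifications
  if (!"group" %in% names(cls) || all(is.na(cls$group))) cls$group <- "all"
  one <- function(df, grp) {
    df |>
      dplyr::group_by(.data$effect) |>
      dplyr::summarise(
        group = grp,
        n = dplyr::n(),
        n_reliable = sum(.data$label == "reliable_typical"),
        n_reverse = sum(.data$label == "reliable_reverse"),
        n_not_reliable = sum(.data$label == "not_reliable"),
        .groups = "drop"
      )
  }
  per_group <- cls |>
    dplyr::group_split(.data$group) |>
    purrr::map_dfr(function(df) one(df, df$group[1]))
  overall <- one(cls, "Overall")
  dplyr::bind_rows(per_group, overall) |>
    dplyr::mutate(
      pct_reliable = round(100 * .data$n_reliable / .data$n),
      pct_reverse = round(100 * .data$n_reverse / .data$n),
      pct_not_reliable = round(100 * .data$n_not_reliable / .data$n)
    ) |>
    dplyr::relocate("group")
}

#' Prevalence counts as a matrix for exact tests
#'
#' Reshapes one effect's per-group label counts into the r x c count
#' matrix consumed by [fisher_exact_rxc()]. All-zero columns (e.g. no
#' reverse effects anywhere) are dropped, matching how such tables are
#' reported.
#'
#' @param classifications Output of [classify_participants()].
#' @param effect `"nde"` or `"nse"`.
#' @return Integer matrix, groups x labels.
#' @export
prevalence_matrix <- function(classifications, effect) {
  tab <- prevalence_table(classifications) |>
    dplyr::filter(.data$effect == .env$effect, .data$group != "Overall")
  m <- as.matrix(tab[, c("n_reliable", "n_reverse", "n_not_reliable")])
  rownames(m) <- tab$group
  m[, colSums(m) > 0, drop = FALSE]
}
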