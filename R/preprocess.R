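#' Exclude participants with excessive error rates
#'
#' Participants whose overall error rate reaches `threshold` are dropped
#' from the trial table entirely, the usual screen for respondents who
#' confused the response mapping (such participants sit near 50% errors,
#' far above ordinary performance). Timeouts and other trials without a
#' response count as errors.
#'
#' @param trials A trial table.
#' @param threshold Error-rate cutoff in (0, 1]; participants with
#'   error rate `>= threshold` are excluded.
#'
#' @return A list with `trials` (the remaining rows) and `excluded`
#'   (a tibble of excluded participants with their error rates).
#' @export
exclude_by_error_rate <- function(trials, threshold = 0.40) {
  assert_cols(trials, c("participant_id", "correct"))
  if (nrow(trials) == 0) abort("Empty trial table.")
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    abort("`threshold` must lie in (0, 1].")
  }
  rates <- trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      error_rate = mean(!.data$correct | is.na(.data$rt_ms)),
      .groups = "drop"
    )
  excluded <- dplyr::filter(rates, .data$error_rate >= threshold)
  list(
    trials = dplyr::filter(
      trials, !.data$participant_id %in% excluded$participant_id
    ),
    excluded = excluded
  )
}

#' Variance-stabilising transform for accuracy
#'
#' `2 * asin(sqrt(p))`, the classical arcsine-square-root transform
#' applied to proportions correct before ANOVA.
#'
#' @param p Proportion(s) correct in \[0, 1\].
#' @return The transformed value(s), in radians (range \[0, pi\]).
#' @examples
#' arcsine_accuracy(c(0, 0.25, 1)) # 0, pi/3, pi
#' @export
arcsine_accuracy <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("`p` must be proportion(s) in [0, 1].")
  }
  2 * asin(sqrt(p))
}

#' Remove anticipations from the RT-analysis set
#'
#' Correct responses faster than `min_rt_ms` are treated as anticipations
#' (guesses initiated before the stimulus could be processed) and removed.
#' The comparison is strict (`rt < min_rt_ms`); a 200 ms response is kept.
#'
#' @param trials A trial table restricted or not to correct trials; only
#'   correct rows can be flagged.
#' @param min_rt_ms Anticipation bound in ms.
#'
#' @return A list with `trials` (rows kept) and `n_removed`.
#' @export
filter_anticipations <- function(trials, min_rt_ms = 200) {
  assert_cols(trials, c("correct", "rt_ms"))
  is_antic <- trials$correct & !is.na(trials$rt_ms) &
    trials$rt_ms < min_rt_ms
  list(trials = trials[!is_antic, , drop = FALSE],
       n_removed = sum(is_antic))
}

#' Per-participant mean +/- k SD trimming of RTs
#'
#' Removes, separately for each participant, RTs lying strictly outside
#' the participant's mean +/- `k` SD. In `"recursive"` mode (sequential
#' trimming) the mean and SD are recomputed after each pass and passes
#' repeat until no RT is removed; `"single_pass"` performs one pass.
#' Participants with fewer than 3 RTs are left untouched.
#'
#' @param trials Trial table already reduced to the correct,
#'   non-anticipation RT set.
#' @param k Number of SDs; default 3.
#' @param mode `"recursive"` or `"single_pass"`.
#'
#' @return A list with `trials` (rows kept) and `n_trimmed` (tibble of
#'   per-participant removal counts).
#' @export
trim_sd <- function(trials, k = 3, mode = c("recursive", "single_pass")) {
  mode <- match.arg(mode)
  assert_cols(trials, c("participant_id", "rt_ms"))
  keep <- rep(TRUE, nrow(trials))
  for (pid in unique(trials$participant_id)) {
    idx <- which(trials$participant_id == pid & !is.na(trials$rt_ms))
    repeat {
      live <- idx[keep[idx]]
      if (length(live) < 3) break
      m <- mean(trials$rt_ms[live])
      s <- sd(trials$rt_ms[live])
      out <- abs(trials$rt_ms[live] - m) > k * s
      if (!any(out)) break
      keep[live[out]] <- FALSE
      if (mode == "single_pass") break
    }
  }
  n_trimmed <- trials[!keep, , drop = FALSE] |>
    dplyr::count(.data$participant_id, name = "n_trimmed")
  list(trials = trials[keep, , drop = FALSE], n_trimmed = n_trimmed)
}

#' Preprocess a magnitude-classification trial table
#'
#' The full screening sequence applied before any RT analysis:
#' 1. participants with error rate `>= error_rate_threshold` are excluded;
#' 2. accuracy is summarised per participant (with the arcsine transform);
#' 3. correct responses faster than `min_rt_ms` are removed as
#'    anticipations;
#' 4. remaining correct RTs are trimmed per participant at
#'    mean +/- `trim_k` SD ([trim_sd()]), sequentially by default.
#'
#' Error trials (including timeouts, which carry no RT) never enter the
#' RT set. The global retention proportion uses all experimental trials of
#' the non-excluded participants as denominator, so errors, anticipations
#' and trimmed trials all count as lost.
#'
#' @param trials A trial table (see [simulate_experiment()] or
#'   [read_trials()]).
#' @param error_rate_threshold Participant exclusion cutoff.
#' @param min_rt_ms Anticipation bound (strict `<`).
#' @param trim_k SD multiplier for trimming.
#' @param trim_mode `"recursive"` (sequential) or `"single_pass"`.
#'
#' @return An object of class `"mag_preprocess"`: a list with
#'   * `trials` — the retained RT-analysis set (correct, non-anticipation,
#'     untrimmed trials of non-excluded participants);
#'   * `per_participant` — tibble of per-participant accounting
#'     (`n_trials_total`, `n_errors`, `error_rate`, `accuracy`,
#'     `accuracy_transformed`, `n_anticipations`, `n_trimmed`,
#'     `n_retained`);
#'   * `excluded` — excluded participants and their error rates;
#'   * `proportion_rt_retained`, `overall_accuracy` — global summaries.
#' @examples
#' sim <- simulate_experiment(sim_config(n_per_group = c(A = 3), seed = 1))
#' pp <- preprocess_trials(sim$trials)
#' glance(pp)
#' @export
preprocess_trials <- function(trials,
                              error_rate_threshold = 0.40,
                              min_rt_ms = 200,
                              trim_k = 3,
                              trim_mode = c("recursive", "single_pass")) {
  trim_mode <- match.arg(trim_mode)
  assert_cols(trials, c("participant_id", "correct", "rt_ms"))

  scr <- exclude_by_error_rate(trials, error_rate_threshold)
  kept <- scr$trials
  if (nrow(kept) == 0) abort("All participants were excluded.")

  acc <- kept |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      group = if ("group" %in% names(kept)) dplyr::first(.data$group)
              else NA_character_,
      n_trials_total = dplyr::n(),
      n_errors = sum(!.data$correct | is.na(.data$rt_ms)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      error_rate = .data$n_errors / .data$n_trials_total,
      accuracy = 1 - .data$error_rate,
      accuracy_transformed = arcsine_accuracy(.data$accuracy)
    )

  correct_rt <- dplyr::filter(kept, .data$correct & !is.na(.data$rt_ms))
  antic <- filter_anticipations(correct_rt, min_rt_ms)
  n_antic <- correct_rt |>
    dplyr::filter(.data$rt_ms < min_rt_ms) |>
    dplyr::count(.data$participant_id, name = "n_anticipations")

  trim <- trim_sd(antic$trials, k = trim_k, mode = trim_mode)

  per_participant <- acc |>
    dplyr::left_join(n_antic, by = "participant_id") |>
    dplyr::left_join(trim$n_trimmed, by = "participant_id") |>
    dplyr::mutate(
      n_anticipations = dplyr::coalesce(.data$n_anticipations, 0L),
      n_trimmed = dplyr::coalesce(.data$n_trimmed, 0L),
      n_retained = .data$n_trials_total - .data$n_errors -
        .data$n_anticipations - .data$n_trimmed
    )

  structure(
    list(
      trials = trim$trials,
      per_participant = per_participant,
      excluded = scr$excluded,
      proportion_rt_retained =
        sum(per_participant$n_retained) / sum(per_participant$n_trials_total),
      overall_accuracy =
        1 - sum(per_participant$n_errors) / sum(per_participant$n_trials_total),
      params = list(
        error_rate_threshold = error_rate_threshold,
        min_rt_ms = min_rt_ms, trim_k = trim_k, trim_mode = trim_mode
      )
    ),
    class = "mag_preprocess"
  )
}

#' @export
print.mag_preprocess <- function(x, ...) {
  cat("<mag_preprocess>\n")
  cat(sprintf("  participants retained: %d (excluded: %d)\n",
              nrow(x$per_participant), nrow(x$excluded)))
  cat(sprintf("  overall accuracy:      %.1f%%\n", 100 * x$overall_accuracy))
  cat(sprintf("  RT data retained:      %.1f%%\n",
              100 * x$proportion_rt_retained))
  invisible(x)
}

#' @describeIn preprocess_trials Per-participant accounting as a tibble.
#' @param x A `mag_preprocess` object.
#' @param ... Unused.
#' @export
tidy.mag_preprocess <- function(x, ...) x$per_participant

#' @describeIn preprocess_trials One-row global summary.
#' @export
glance.mag_preprocess <- function(x, ...) {
  tibble::tibble(
    n_participants = nrow(x$per_participant),
    n_excluded = nrow(x$excluded),
    overall_accuracy = x$overall_accuracy,
    proportion_rt_retained = x$proportion_rt_retained
  )
}
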