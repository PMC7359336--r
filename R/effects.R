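# Per-participant quantification of the numerical distance (NDE), size
# (NSE), ratio and SNARC effects by OLS regression on digit-level mean RTs.
#
# Over the digit set {1,2,3,4,6,7,8,9} the distance predictor |d - 5| and
# the magnitude predictor d are exactly orthogonal (their centred dot
# product is 0), so the multiple regression slopes coincide with the two
# simple-regression slopes and there is no collinearity.

#' Mean RT per digit per participant
#'
#' Aggregates the retained RT set into the digit-level means on which all
#' effect regressions run. Each participant must contribute every one of
#' the eight task digits; cells with fewer than `min_cell` trials are
#' flagged (`low_n`) because an 8-point regression with near-empty cells
#' is not meaningful.
#'
#' @param trials Preprocessed trial table (the retained RT set).
#' @param min_cell Minimum trials per digit before a cell is flagged.
#' @param by_side Also split cells by `response_side` (for SNARC).
#'
#' @return Tibble with `participant_id`, `number`, `distance`,
#'   (`response_side`,) `mean_rt`, `n`, `low_n`.
#' @export
aggregate_digit_means <- function(trials, min_cell = 5, by_side = FALSE) {
  assert_cols(trials, c("participant_id", "number", "rt_ms"))
  keys <- c("participant_id", "number", if (by_side) "response_side")
  out <- trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      mean_rt = mean(.data$rt_ms),
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      distance = abs(.data$number - 5),
      low_n = .data$n < min_cell
    )

  present <- out |>
    dplyr::distinct(.data$participant_id, .data$number) |>
    dplyr::count(.data$participant_id)
  bad <- dplyr::filter(present, .data$n < length(mag_digits))
  if (nrow(bad) > 0) {
    missing <- out |>
      dplyr::filter(.data$participant_id %in% bad$participant_id) |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(
        gone = paste(setdiff(mag_digits, .data$number), collapse = ", "),
        .groups = "drop"
      )
    abort(paste0(
      "Missing digit cell(s): ",
      paste(sprintf("%s (digit %s)", missing$participant_id, missing$gone),
            collapse = "; ")
    ))
  }
  out
}

# OLS on one participant's 8 digit means; returns intercept, slopes, R^2.
# Degenerate (constant) means yield zero slopes and R^2 = 0.
fit_one <- function(mean_rt, number) {
  if (sd(mean_rt) == 0) {
    return(c(intercept = mean_rt[1], nde_slope = 0, nse_slope = 0,
             r_squared = 0))
  }
  # noiseless designs fit perfectly; the "essentially perfect fit"
  # warning is expected there, not a problem
  fit <- lm(mean_rt ~ I(abs(number - 5)) + number)
  c(
    intercept = unname(coef(fit)[1]),
    nde_slope = unname(coef(fit)[2]),
    nse_slope = unname(coef(fit)[3]),
    r_squared = suppressWarnings(summary(fit)$r.squared)
  )
}

#' Distance and size slopes from digit means
#'
#' Regresses each participant's eight digit-mean RTs on the numerical
#' distance from 5 (`|digit - 5|`) and the numerical magnitude (`digit`)
#' in a single multiple regression. A negative distance slope is the
#' typical NDE; a positive magnitude slope is the typical NSE. Because
#' the two predictors are orthogonal over the digit set, each slope
#' equals its simple-regression counterpart.
#'
#' @param means Digit means from [aggregate_digit_means()] (one or many
#'   participants).
#'
#' @return Tibble with one row per participant: `intercept`, `nde_slope`,
#'   `nse_slope`, `r_squared`.
#' @export
fit_distance_size <- function(means) {
  assert_cols(means, c("participant_id", "number", "mean_rt"),
              "digit-means table")
  means |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) != length(mag_digits)) {
        abort(sprintf("Expected %d digit means, got %d.",
                      length(mag_digits), nrow(df)))
      }
      tibble::as_tibble(as.list(fit_one(df$mean_rt, df$number)))
    }) |>
    dplyr::ungroup()
}

#' Numerical ratio of a digit against the standard 5
#'
#' `min(d, 5) / max(d, 5)`, the conventional smaller/larger ratio; larger
#' values mean a harder comparison.
#'
#' @param number Digit vector.
#' @param convention `"min_max"` (default) or `"max_min"`.
#' @return Numeric ratio(s).
#' @export
digit_ratio <- function(number, convention = c("min_max", "max_min")) {
  convention <- match.arg(convention)
  r <- pmin(number, 5) / pmax(number, 5)
  if (convention == "max_min") 1 / r else r
}

#' Ratio-effect slope from digit means
#'
#' Simple OLS slope of the digit-mean RTs on the numerical ratio
#' [digit_ratio()]; a positive slope means slower responses for harder
#' (larger) ratios, the typical ratio effect.
#'
#' @inheritParams fit_distance_size
#' @param convention Passed to [digit_ratio()].
#' @return Tibble with `participant_id`, `ratio_slope`.
#' @export
fit_ratio <- function(means, convention = "min_max") {
  assert_cols(means, c("participant_id", "number", "mean_rt"),
              "digit-means table")
  means |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      ratio_slope = simple_slope(
        digit_ratio(.data$number, convention), .data$mean_rt
      ),
      .groups = "drop"
    )
}

simple_slope <- function(x, y) {
  if (sd(y) == 0 || sd(x) == 0) return(0)
  cov(x, y) / var(x)
}

#' SNARC slope from left- and right-hand RTs
#'
#' For each digit, computes dRT = mean RT of right-hand responses minus
#' mean RT of left-hand responses (possible because the two blocks
#' reverse the response mapping, so every digit is answered with both
#' hands), then fits the OLS slope of dRT on digit magnitude. A negative
#' slope is the typical SNARC effect: relatively faster right-hand
#' responses to larger numbers.
#'
#' @param trials Preprocessed trial table including `response_side`.
#' @return Tibble with `participant_id`, `snarc_slope`.
#' @export
fit_snarc <- function(trials) {
  assert_cols(trials, c("participant_id", "number", "rt_ms",
                        "response_side"))
  side_means <- aggregate_digit_means(trials, min_cell = 1, by_side = TRUE)
  wide <- side_means |>
    dplyr::select("participant_id", "number", "response_side", "mean_rt") |>
    tidyr::pivot_wider(names_from = "response_side",
                       values_from = "mean_rt")
  if (!all(c("left", "right") %in% names(wide)) ||
      anyNA(wide$left) || anyNA(wide$right)) {
    miss <- wide[!complete.cases(wide), , drop = FALSE]
    abort(paste0(
      "SNARC needs both response sides for every digit; missing for: ",
      paste(unique(miss$participant_id), collapse = ", ")
    ))
  }
  wide |>
    dplyr::mutate(drt = .data$right - .data$left) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      snarc_slope = simple_slope(.data$number, .data$drt),
      .groups = "drop"
    )
}

#' Standardized distance and size slopes
#'
#' Refits the distance/size regression after z-scoring each participant's
#' digit means and both predictors, yielding unitless slopes (robustness
#' companion to the raw ms-per-unit slopes). With orthogonal predictors
#' the standardized slope equals the correlation between the digit means
#' and the predictor. Zero-variance means give zero slopes.
#'
#' @inheritParams fit_distance_size
#' @return Tibble with `participant_id`, `std_nde_slope`, `std_nse_slope`.
#' @export
standardize_slopes <- function(means) {
  assert_cols(means, c("participant_id", "number", "mean_rt"),
              "digit-means table")
  means |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(function(df, key) {
      if (sd(df$mean_rt) == 0) {
        return(tibble::tibble(std_nde_slope = 0, std_nse_slope = 0))
      }
      z <- as.numeric(scale(df$mean_rt))
      zd <- as.numeric(scale(abs(df$number - 5)))
      zm <- as.numeric(scale(df$number))
      fit <- lm(z ~ zd + zm)
      tibble::tibble(
        std_nde_slope = unname(coef(fit)[2]),
        std_nse_slope = unname(coef(fit)[3])
      )
    }) |>
    dplyr::ungroup()
}

#' Per-participant effect slopes
#'
#' The main estimation entry point: aggregates the retained RT set to
#' digit means and returns one row per participant with the distance and
#' size slopes (always), the ratio slope (always), and optionally the
#' SNARC slope and standardized slopes, alongside the participant's mean
#' and SD of retained RTs.
#'
#' @param trials Preprocessed trial table (retained RT set), e.g.
#'   `preprocess_trials(x)$trials`.
#' @param min_cell Passed to [aggregate_digit_means()].
#' @param include_snarc Add `snarc_slope` (needs `response_side`).
#' @param standardize Add standardized distance/size slopes.
#'
#' @return Tibble with one row per participant: identification columns,
#'   `n_retained`, `mean_rt`, `sd_rt`, `intercept`, `nde_slope`,
#'   `nse_slope`, `r_squared`, `ratio_slope` and the optional columns.
#' @examples
#' sim <- simulate_experiment(sim_config(n_per_group = c(A = 3), seed = 1))
#' fit_effects(preprocess_trials(sim$trials)$trials)
#' @export
fit_effects <- function(trials, min_cell = 5, include_snarc = FALSE,
                        standardize = FALSE) {
  means <- aggregate_digit_means(trials, min_cell = min_cell)
  base <- trials |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      group = if ("group" %in% names(trials)) dplyr::first(.data$group)
              else NA_character_,
      n_retained = dplyr::n(),
      mean_rt = mean(.data$rt_ms),
      sd_rt = sd(.data$rt_ms),
      .groups = "drop"
    )
  out <- base |>
    dplyr::left_join(fit_distance_size(means), by = "participant_id") |>
    dplyr::left_join(fit_ratio(means), by = "participant_id")
  if (include_snarc) {
    out <- dplyr::left_join(out, fit_snarc(trials), by = "participant_id")
  }
  if (standardize) {
    out <- dplyr::left_join(out, standardize_slopes(means),
                            by = "participant_id")
  }
  out
}
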