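# Reading, validating and writing trial tables.

#' Map external CSV headers onto the canonical trial columns
#'
#' External deposits name their columns freely; a column map states which
#' header holds each of the six required logical columns (`participant`,
#' `group`, `block`, `number`, `correct`, `rt_ms`) and the optional ones
#' (`response_side`, `trial_index`), plus how correctness is coded.
#'
#' @param participant,group,block,number,correct,rt_ms Header names of
#'   the required columns.
#' @param response_side,trial_index Header names of the optional columns,
#'   or NULL if absent.
#' @param correct_true Values (after conversion to character) that code a
#'   correct response; everything else codes an error.
#'
#' @return A list of class `"column_map"`.
#' @examples
#' cm <- column_map(participant = "subj", correct = "acc",
#'                  correct_true = "1")
#' @export
column_map <- function(participant = "participant_id", group = "group",
                       block = "block", number = "number",
                       correct = "correct", rt_ms = "rt_ms",
                       response_side = NULL, trial_index = NULL,
                       correct_true = c("TRUE", "T", "1", "true")) {
  structure(
    list(
      participant = participant, group = group, block = block,
      number = number, correct = correct, rt_ms = rt_ms,
      response_side = response_side, trial_index = trial_index,
      correct_true = as.character(correct_true)
    ),
    class = "column_map"
  )
}

#' Read and validate a trial-level CSV
#'
#' Reads a trial table, renames columns according to the map, recodes
#' correctness to logical, recomputes `distance = |number - 5|`, and
#' validates the design invariants that can be checked row-wise. The
#' standard digit 5 is never a stimulus; its presence is a hard error
#' naming the offending rows.
#'
#' @param path CSV file (UTF-8, header row; missing RTs as empty fields).
#' @param colmap A [column_map()].
#' @return A validated trial tibble.
#' @export
read_trials <- function(path, colmap = column_map()) {
  if (!inherits(colmap, "column_map")) {
    abort("`colmap` must be created by column_map().")
  }
  # read untyped so correctness codings ("T"/"F", 0/1, ...) reach the
  # recoding step verbatim instead of being guessed by the parser
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(
                           .default = readr::col_character()
                         ))
  required <- c("participant", "group", "block", "number", "correct",
                "rt_ms")
  for (field in required) {
    if (!colmap[[field]] %in% names(raw)) {
      abort(sprintf("Column '%s' (mapped to %s) not found in %s.",
                    colmap[[field]], field, path))
    }
  }
  trials <- tibble::tibble(
    participant_id = as.character(raw[[colmap$participant]]),
    group = as.character(raw[[colmap$group]]),
    block = as.integer(raw[[colmap$block]]),
    number = as.integer(raw[[colmap$number]]),
    correct = as.character(raw[[colmap$correct]]) %in% colmap$correct_true,
    rt_ms = as.numeric(raw[[colmap$rt_ms]])
  )
  if (!is.null(colmap$response_side)) {
    trials$response_side <- as.character(raw[[colmap$response_side]])
  }
  if (!is.null(colmap$trial_index)) {
    trials$trial_index <- as.integer(raw[[colmap$trial_index]])
  }
  trials$distance <- abs(trials$number - 5)
  validate_trials(trials)
  trials
}

#' Validate the row-wise invariants of a trial table
#'
#' Errors, with row numbers, on: digits outside `{1..9} \ {5}` (5 is the
#' comparison standard, never a stimulus), blocks outside `{1, 2}`,
#' nonpositive RTs, and a `distance` column inconsistent with
#' `|number - 5|`. With `design = TRUE` additionally checks the full
#' design: 8 digits x equal counts per block per participant, and no
#' digit more than `max_run` times in a row (needs `trial_index`).
#'
#' @param trials Trial tibble.
#' @param design Also check the per-block design invariants.
#' @param max_run Run-length bound used when `design = TRUE`.
#' @return `trials`, invisibly; errors describe every violation found.
#' @export
validate_trials <- function(trials, design = FALSE, max_run = 2) {
  assert_cols(trials, c("participant_id", "group", "block", "number",
                        "correct", "rt_ms"))
  problems <- character(0)
  bad_digit <- which(!trials$number %in% mag_digits)
  if (length(bad_digit) > 0) {
    problems <- c(problems, sprintf(
      "invalid digit (5 is the standard, digits must be 1-9 except 5) in row(s) %s",
      paste(utils::head(bad_digit, 10), collapse = ", ")
    ))
  }
  bad_block <- which(!trials$block %in% c(1L, 2L))
  if (length(bad_block) > 0) {
    problems <- c(problems, sprintf("block not in {1, 2} in row(s) %s",
      paste(utils::head(bad_block, 10), collapse = ", ")))
  }
  bad_rt <- which(!is.na(trials$rt_ms) & trials$rt_ms <= 0)
  if (length(bad_rt) > 0) {
    problems <- c(problems, sprintf("nonpositive RT in row(s) %s",
      paste(utils::head(bad_rt, 10), collapse = ", ")))
  }
  if ("distance" %in% names(trials)) {
    bad_d <- which(trials$distance != abs(trials$number - 5))
    if (length(bad_d) > 0) {
      problems <- c(problems, sprintf(
        "distance != |number - 5| in row(s) %s",
        paste(utils::head(bad_d, 10), collapse = ", ")
      ))
    }
  }
  if (design) {
    assert_cols(trials, "trial_index")
    per_block <- trials |>
      dplyr::count(.data$participant_id, .data$block, .data$number)
    uneven <- per_block |>
      dplyr::group_by(.data$participant_id, .data$block) |>
      dplyr::summarise(
        ok = dplyr::n() == length(mag_digits) &&
          dplyr::n_distinct(.data$n) == 1,
        .groups = "drop"
      ) |>
      dplyr::filter(!.data$ok)
    if (nrow(uneven) > 0) {
      problems <- c(problems, sprintf(
        "unbalanced digit counts for participant-block(s): %s",
        paste(sprintf("%s/%d", uneven$participant_id, uneven$block),
              collapse = ", ")
      ))
    }
    runs <- trials |>
      dplyr::arrange(.data$participant_id, .data$block,
                     .data$trial_index) |>
      dplyr::group_by(.data$participant_id, .data$block) |>
      dplyr::summarise(max_run_len = max(rle(.data$number)$lengths),
                       .groups = "drop") |>
      dplyr::filter(.data$max_run_len > max_run)
    if (nrow(runs) > 0) {
      problems <- c(problems, sprintf(
        "digit run longer than %d for participant-block(s): %s",
        max_run,
        paste(sprintf("%s/%d", runs$participant_id, runs$block),
              collapse = ", ")
      ))
    }
  }
  if (length(problems) > 0) {
    abort(paste0("Invalid trial table:\n- ",
                 paste(problems, collapse = "\n- ")))
  }
  invisible(trials)
}

#' Write a trial table (or any result tibble) as CSV
#'
#' UTF-8, comma-separated, header row, missing values as empty fields —
#' the interchange dialect used by every stage of the pipeline.
#'
#' @param x A tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_trials <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(path)
}
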