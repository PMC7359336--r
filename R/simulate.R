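#' Shuffle a multiset with a maximum run-length constraint
#'
#' Returns a random permutation of `items` in which no element occurs more
#' than `max_run` times consecutively, as required of trial orders in the
#' magnitude classification task. The shuffler draws the sequence element
#' by element, choosing uniformly among the remaining items that do not
#' violate the constraint, and restarts on a dead end.
#'
#' @param items Vector (multiset) to permute.
#' @param max_run Maximum allowed run length of identical elements.
#' @param seed Optional RNG seed; the result is deterministic given a seed.
#' @param max_restarts Restarts allowed before concluding the multiset is
#'   infeasible.
#'
#' @return A permutation of `items` with all runs of length <= `max_run`.
#' @examples
#' s <- constrained_shuffle(rep(mag_digits, 30), max_run = 2, seed = 1)
#' max(rle(s)$lengths)
#' @export
constrained_shuffle <- function(items, max_run = 2, seed = NULL,
                                max_restarts = 100) {
  if (max_run < 1) abort("`max_run` must be >= 1.")
  n <- length(items)
  if (n <= 1) return(items)
  uniq <- unique(items)
  counts0 <- tabulate(match(items, uniq), nbins = length(uniq))

  with_seed_opt(seed, {
    for (attempt in seq_len(max_restarts)) {
      counts <- counts0
      out <- integer(n)
      prev <- 0L
      run <- 0L
      ok <- TRUE
      for (i in seq_len(n)) {
        allowed <- which(counts > 0)
        if (run >= max_run) allowed <- allowed[allowed != prev]
        if (length(allowed) == 0) {
          ok <- FALSE
          break
        }
        # weight by remaining multiplicity: uniform over remaining items
        pick <- allowed[sample.int(length(allowed), 1,
                                   prob = counts[allowed])]
        out[i] <- pick
        counts[pick] <- counts[pick] - 1L
        if (pick == prev) run <- run + 1L else run <- 1L
        prev <- pick
      }
      if (ok) return(uniq[out])
    }
    abort(sprintf(
      "No ordering with runs <= %d found after %d restarts; the multiset is likely infeasible.",
      max_run, max_restarts
    ))
  })
}

#' Sample from an ex-Gaussian distribution
#'
#' The ex-Gaussian — the convolution of a Normal(mu, sigma) and an
#' Exponential(tau) — is the standard descriptive noise model for
#' reaction times. Its mean is `mu + tau` and its variance
#' `sigma^2 + tau^2`.
#'
#' @param n Number of draws.
#' @param mu,sigma Mean and SD of the Gaussian component (ms).
#' @param tau Mean of the exponential component (ms); 0 disables it.
#' @param seed Optional RNG seed.
#'
#' @return Numeric vector of length `n`.
#' @examples
#' x <- sample_ex_gaussian(1e4, mu = 400, sigma = 30, tau = 100, seed = 1)
#' mean(x) # ~ 500
#' @export
sample_ex_gaussian <- function(n, mu = 0, sigma = 1, tau = 1, seed = NULL) {
  if (sigma < 0 || tau < 0) abort("`sigma` and `tau` must be >= 0.")
  with_seed_opt(seed, {
    g <- if (sigma > 0) rnorm(n, mu, sigma) else rep(mu, n)
    e <- if (tau > 0) rexp(n, rate = 1 / tau) else 0
    g + e
  })
}

#' Simulate a magnitude-classification experiment
#'
#' Generates a complete trial table with the paradigm's design — two
#' blocks with reversed response-key assignment, each digit of
#' [mag_digits] presented `trials_per_digit` times per block, no digit
#' more than twice in a row — together with the ground-truth
#' per-participant effect structure, so parameter recovery by the
#' downstream estimators can be verified.
#'
#' The RT of an ordinary trial is
#' `intercept + b_dist * distance + b_size * number +
#'  side/2 * b_snarc * (number - 5) + ex-Gaussian noise`,
#' where `side` is +1 for right-hand and -1 for left-hand responses, so
#' that the right-minus-left RT difference regressed on magnitude has
#' slope `b_snarc`. RTs at or beyond the deadline are censored: recorded
#' as incorrect with missing RT. Errors occur with probability
#' `error_base * exp(-error_distance_decay * distance)` (the accuracy
#' distance effect). Anticipations replace a trial with an RT uniform in
#' (80, 200) ms, a random response side, and 50% chance of being scored
#' correct.
#'
#' Block order (which block maps "larger" to the right key) alternates
#' across consecutive participants, a deterministic counterbalancing.
#'
#' @param config A [sim_config()].
#' @param seed RNG seed; overrides `config$seed`. The same config and seed
#'   always reproduce the same tables.
#'
#' @return An object of class `"mag_sim"`: a list with
#'   * `trials` — tibble with columns `participant_id`, `group`, `block`,
#'     `trial_index`, `number`, `distance`, `mapping`, `response_side`,
#'     `correct`, `rt_ms` (NA for timeouts);
#'   * `truth` — tibble of the generative per-participant parameters;
#'   * `config` — the configuration used.
#' @examples
#' sim <- simulate_experiment(sim_config(n_per_group = c(A = 2), seed = 7))
#' dplyr::count(sim$trials, participant_id, block)
#' @export
simulate_experiment <- function(config = sim_config(), seed = NULL) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be created by sim_config().")
  }
  seed <- seed %||% config$seed
  if (is.null(seed)) {
    abort("Provide a `seed` (in the config or as an argument) for a reproducible experiment.")
  }

  groups <- rep(names(config$n_per_group), config$n_per_group)
  n_total <- length(groups)
  width <- max(2, nchar(n_total))
  ids <- sprintf(paste0("%s_%0", width, "d"), groups, seq_len(n_total))

  per_participant <- purrr::map2(
    ids, seq_len(n_total),
    function(id, idx) {
      simulate_participant(
        config, id = id, group = groups[idx],
        block1_larger_right = idx %% 2 == 1,
        seed = derive_seed(seed, id)
      )
    }
  )

  trials <- dplyr::bind_rows(purrr::map(per_participant, "trials"))
  truth <- dplyr::bind_rows(purrr::map(per_participant, "truth"))
  structure(
    list(trials = trials, truth = truth, config = config, seed = seed),
    class = "mag_sim"
  )
}

# One participant's two blocks; all randomness from `seed`.
simulate_participant <- function(config, id, group, block1_larger_right,
                                 seed) {
  with_seed_opt(seed, {
    intercept <- rnorm(1, config$intercept[1], config$intercept[2])
    b_dist <- rnorm(1, config$b_dist[1], config$b_dist[2])
    b_size <- rnorm(1, config$b_size[1], config$b_size[2])
    b_snarc <- rnorm(1, config$b_snarc[1], config$b_snarc[2])

    blocks <- purrr::map(1:2, function(b) {
      larger_right <- if (b == 1) block1_larger_right else !block1_larger_right
      number <- constrained_shuffle(
        rep(mag_digits, config$trials_per_digit), max_run = 2
      )
      n <- length(number)
      distance <- abs(number - 5)

      correct_side <- ifelse(xor(number > 5, !larger_right), "right", "left")
      p_err <- pmin(1, config$error_base *
                      exp(-config$error_distance_decay * distance))
      is_error <- runif(n) < p_err
      response_side <- ifelse(
        is_error,
        ifelse(correct_side == "right", "left", "right"),
        correct_side
      )
      side_sign <- ifelse(response_side == "right", 1, -1)

      rt <- intercept + b_dist * distance + b_size * number +
        0.5 * side_sign * b_snarc * (number - 5) +
        sample_ex_gaussian(n, config$noise["mu"], config$noise["sigma"],
                           config$noise["tau"])
      correct <- !is_error

      is_antic <- runif(n) < config$anticipation_rate
      if (any(is_antic)) {
        k <- sum(is_antic)
        rt[is_antic] <- runif(k, 80, 200)
        response_side[is_antic] <- sample(c("left", "right"), k,
                                          replace = TRUE)
        correct[is_antic] <- runif(k) < 0.5
      }

      timeout <- !is.na(rt) & rt >= config$rt_ceiling_ms
      correct[timeout] <- FALSE
      rt[timeout] <- NA_real_

      tibble::tibble(
        participant_id = id,
        group = group,
        block = b,
        trial_index = seq_len(n),
        number = number,
        distance = distance,
        mapping = ifelse(larger_right, "larger_right", "larger_left"),
        response_side = response_side,
        correct = correct,
        rt_ms = rt
      )
    })

    list(
      trials = dplyr::bind_rows(blocks),
      truth = tibble::tibble(
        participant_id = id, group = group,
        intercept = intercept, b_dist = b_dist,
        b_size = b_size, b_snarc = b_snarc
      )
    )
  })
}

#' @export
print.mag_sim <- function(x, ...) {
  cat("<mag_sim> synthetic magnitude-classification experiment\n")
  cat(sprintf("  %d participants, %d trials, seed %s\n",
              nrow(x$truth), nrow(x$trials), format(x$seed)))
  invisible(x)
}

#' @describeIn simulate_experiment The trial table of a simulation.
#' @param x A `mag_sim` object.
#' @param ... Unused.
#' @export
tidy.mag_sim <- function(x, ...) x$trials
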