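# Shared builders for synthetic fixtures. Everything is generated in code
# under fixed seeds; no stored data.

# A deterministic experiment: no trial noise, no errors, no anticipations,
# every participant has exactly the stated slopes.
noiseless_config <- function(n = 3, b_dist = -10, b_size = 2,
                             b_snarc = 0, intercept = 500) {
  sim_config(
    n_per_group = c(G = n),
    intercept = c(intercept, 0),
    b_dist = c(b_dist, 0),
    b_size = c(b_size, 0),
    b_snarc = c(b_snarc, 0),
    noise = c(0, 0, 0),
    error_base = 0,
    anticipation_rate = 0
  )
}

# Digit-means table for one participant, mean RT as a function of digit.
make_means <- function(f, pid = "p1") {
  d <- magchron::mag_digits
  tibble::tibble(
    participant_id = pid,
    number = d,
    distance = abs(d - 5),
    mean_rt = f(d),
    n = 60L,
    low_n = FALSE
  )
}

# Minimal hand-built trial table: one trial per row from parallel vectors.
make_trials <- function(pid, number, rt_ms, correct = TRUE, block = 1L,
                        response_side = "right", group = "G") {
  n <- max(length(number), length(rt_ms))
  tibble::tibble(
    participant_id = pid,
    group = group,
    block = rep_len(block, n),
    trial_index = seq_len(n),
    number = rep_len(number, n),
    distance = abs(rep_len(number, n) - 5),
    response_side = rep_len(response_side, n),
    correct = rep_len(correct, n),
    rt_ms = rep_len(rt_ms, n)
  )
}

# Independent normal-equations OLS oracle: intercept and slopes of y on
# columns of X (with intercept added), by direct matrix solve.
ols_oracle <- function(y, ...) {
  X <- cbind(1, ...)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}
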