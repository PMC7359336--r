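# Internal helpers: seeding and validation.

# Evaluate `code` under `seed` (Mersenne-Twister), restoring RNG state after.
# A NULL seed uses the current RNG stream unchanged.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) {
    force(code)
  } else {
    withr::with_seed(as.integer(seed), code)
  }
}

# Deterministic per-participant seed derived from a master seed and an id
# string, so serial and parallel (or reordered) runs classify identically.
# Polynomial string hash mod (2^31 - 1); exact in double arithmetic.
derive_seed <- function(master_seed, id) {
  m <- 2147483647
  h <- as.numeric(master_seed) %% m
  for (b in utf8ToInt(as.character(id))) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    abort(sprintf("`%s` must be a single probability in [0, 1].", name))
  }
  invisible(x)
}

assert_cols <- function(df, cols, what = "trial table") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "The %s lacks required column(s): %s.",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
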