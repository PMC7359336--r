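---
title: "Methods: individual-level distance and size effects in magnitude classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual-level distance and size effects in magnitude classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magchron)
library(dplyr)
```

## The task and the estimands

In symbolic magnitude classification a participant sees a single digit
from {1, 2, 3, 4, 6, 7, 8, 9} and presses a left or right key to report
whether it is smaller or larger than 5. The design analysed here has two
blocks of 240 trials with reversed key assignment (each digit 30 times
per block, never more than twice in a row, a 2 s response deadline).

Two estimands live at the participant level:

* the **distance slope** `bD` — ms of RT per unit of |digit − 5|;
  negative values are the typical numerical distance effect (NDE);
* the **magnitude slope** `bM` — ms per unit of digit magnitude;
  positive values are the typical size effect (NSE).

Both come from one OLS regression of the eight digit-mean RTs on
|d − 5| and d. Over this digit set the two predictors are *exactly*
orthogonal (the centred cross-product is zero), which has two pleasant
consequences: no collinearity, and the multiple-regression slopes equal
the simple-regression slopes — a property the test suite asserts to
1e-10 against a direct normal-equations solve. Ratio
(min(d,5)/max(d,5)) and SNARC (right-minus-left dRT on d) slopes are
simple regressions on the same means.

Regression is on the 8 digit means, not on raw trials: with a balanced
design the two give identical point estimates, and the mean-based
formulation is the one that the H0 bootstrap (below) must mirror. A
`min_cell` guard (default 5 retained trials per digit) flags cells too
thin to support an 8-point regression.

### SNARC details

Because each digit requires one specific hand within a block, a
right-minus-left contrast for a given digit necessarily spans the two
blocks: right-hand RTs for digit 8 come from the block mapping "larger"
to the right key, left-hand RTs from the other. dRT is therefore
computed per digit across blocks from correct retained trials, and the
SNARC slope is the OLS slope of dRT on digit. In the generator the
SNARC contribution to a single trial is `0.5 * side * b_snarc *
(d − 5)` with side = ±1, parameterised so that the *fitted* dRT slope
recovers `b_snarc` itself — the generative coefficient lives on the
same scale as the estimate, which is what parameter-recovery tests need.

## Preprocessing

The screening sequence, in order, with its tunable parameters:

1. **Participant exclusion** (`error_rate_threshold`, default 0.40):
   participants at or above the threshold are removed entirely. The
   default separates mapping-confused respondents (who sit near 50%
   errors because one block is answered with inverted keys) from even
   the worst ordinary performers. Timeouts count as errors — they carry
   no response.
2. **Accuracy summaries** with the arcsine transform
   `2·asin(√p)`, the classical variance-stabiliser for proportions
   entering ANOVA.
3. **Anticipation removal** (`min_rt_ms`, default 200, strict `<`):
   correct responses faster than the bound are guesses initiated before
   the stimulus could be processed.
4. **Sequential ±k SD trimming** (`trim_k = 3`,
   `trim_mode = "recursive"`): per participant, RTs strictly outside
   mean ± 3 SD are removed and the criterion recomputed until stable.
   Recursive mode is the default because a single extreme outlier
   inflates the SD enough to shelter moderate outliers; a
   `single_pass` mode is kept for comparison. Participants with fewer
   than 3 RTs are left untouched (the SD is degenerate), and a
   constant RT vector trims nothing (nothing is *strictly* outside
   ±0). Recursive trimming is idempotent, which the tests assert.

The retention statistic divides retained RT trials by *all*
experimental trials of non-excluded participants, so errors,
anticipations and trimmed trials all count as lost; the per-participant
accounting identity `retained + anticipations + trimmed + errors =
total` holds exactly on any input. Whether error trials belong in that
denominator is genuinely ambiguous; this choice is the one that lets
accuracy and retention be read off the same base and is stated in the
report so users can recompute alternatives.

## The H0 bootstrap

The question "does *this* participant show an NDE?" is answered by
building the participant's own null distribution. Under H0 the RT
pattern does not depend on the digit, so pooling all retained correct
RTs across digits and blocks and dealing them back out into 8 arbitrary
"digit" sets (60 RTs each, sampled with replacement) produces data that
are exactly like the participant's — except that the digit–RT link is
destroyed. Fitting the same distance/size regression to each resampled
set's means, 5,000 times, traces the distribution of slopes this
participant would generate with no effect at all.

Decision rule (for the NDE; signs flip for the NSE): an empirical slope
that is negative *and* strictly outside the central 90% of the null
slopes is a **reliable** effect; positive and strictly outside is a
**reliable reverse** effect; anything else is **not reliable**.
Numerical choices, each deliberate:

* *Pool:* all retained correct RTs pooled over digits and blocks —
  pooling is what destroys the association that constitutes H0.
* *Set size 60* mirrors the design (30 per digit × 2 blocks) and is
  configurable for other designs.
* *Percentiles:* type-7 (linear interpolation between order
  statistics), the default definition in most statistical software, so
  results can be compared digit-for-digit with other implementations.
* *Ties at a bound count as inside* — "outside" is strict.
* *Seeding:* each participant's stream is derived from the master seed
  and the participant id by a deterministic string hash, so serial,
  parallel and reordered runs classify identically.

Internally the 8 set means are mapped to slopes through the
precomputed hat-matrix rows of the fixed design — a linear map
identical to `fit_distance_size()` (asserted against an independently
coded resampling oracle drawing from the same RNG stream).

The calibration of the rule is testable: on simulated null participants
(no true effects, realistic noise) about 10% should be labelled
reliable in either direction at a 90% interval, and the labelled
fraction must grow with the true effect size. Both properties are in
the suite (500 null participants × 1,000 iterations for the type-I
check; the acceptance script recomputes it at every run).

## Split-half reliability

A slope can only correlate with anything else up to its own stability.
Reliability is estimated by random split-halves: within each
participant × digit × block cell the trials are randomly divided into
two halves (stratified, so each half preserves the 8-point design; odd
cells send their extra trial to a random half), the slope is fitted on
each half, the two half-slopes are correlated across participants, the
correlation is averaged over `n_splits` random splits (raw-r averaging
by default, Fisher-z behind a flag) and projected to full length with
Spearman–Brown, `2r/(1+r)`. Splits that strand a one-trial digit cell
entirely in one half cannot be scored and are dropped from the average.
The companion tools — correction for attenuation
(`r/√(rel_x·rel_y)`, clipped to [−1, 1] with a warning) and
first-order partial correlation (checked against residualising both
variables on the covariate) — support correlational follow-ups.

## Group-level inference

* **One-sample t-tests** are one-sided in the effect's typical
  direction (negative for NDE, positive for NSE), with
  `d = (mean − mu)/SD`, so `d = t/√n` exactly.
* **One-way ANOVA** reports `eta_p² = SS_b/(SS_b + SS_w)`.
* **JZS Bayes factors** are computed by direct 1-D quadrature, not via
  an external package. For the t-test, the marginal likelihood under H1
  is the noncentral-t likelihood of the observed t averaged over a
  Cauchy(0, √2/2) prior on the standardized effect; one-sided
  hypotheses truncate and renormalise the prior to the predicted
  half-line (order-restricted BF). The integrator runs at 1e-6 relative
  tolerance and non-convergence is an error, never a silent value; the
  suite checks the result against a brute-force 10⁶-point trapezoid to
  1e-4. For the ANOVA, group effects get iid Normal(0, g·sigma²) priors
  with the conventional scaled inverse-chi-squared mixing prior on g
  (scale 0.5); location and scale are integrated analytically and g
  numerically. This is an independent implementation of the standard
  default-prior ANOVA BF and is documented as such — agreement with
  reference implementations is expected to a few percent, not to the
  digit.
* **Fisher exact r×c tests** on prevalence tables delegate to the exact
  network algorithm in `stats::fisher.test` (with a conditional
  Monte-Carlo mode for large tables); the 2×2 case is verified against
  a hand-rolled hypergeometric enumeration in the tests.

A one-sided ("order-restricted") reading of the Bayes factors is used
in the summary table because the hypotheses are directional; this
choice reproduces published BFs of this literature noticeably better
than the two-sided variant.

## The synthetic generator

`sim_config()` + `simulate_experiment()` emulate the paradigm: exact
design constraints (two counterbalanced blocks, 30 presentations per
digit per block, runs ≤ 2 via a constrained shuffler that restarts on
dead ends and errors on infeasible multisets), per-participant
intercept and slopes drawn from normal distributions, ex-Gaussian trial
noise, an error probability decaying exponentially with distance (one
interpretable parameter reproducing the accuracy distance effect),
uniform (80, 200) ms anticipations marked correct with probability 0.5
(so the < 200 ms filter alone removes them), and censoring at the 2 s
deadline recorded as an incorrect trial with missing RT.

Default calibration (chosen once, from the published cohort summaries
of this paradigm): groups of 13/14/15/56; distance slope
N(−13.08, 7.90) ms/unit; size slope N(1.20, 3.16) ms/unit; intercept
N(466, 75) ms and ex-Gaussian (0, 60, 65) ms noise, which put the
overall mean RT near 504 ms, the between-participant SD near 79 ms and
the intraindividual SD near 90 ms; error model 0.06·exp(−0.3·distance)
(overall accuracy ≈ 97%); anticipation rate 5 × 10⁻⁴. The SNARC slope
defaults to N(0, 0) — its magnitude in this task is not pinned down by
the sources the defaults are calibrated to, and switching it off keeps
the default cohort minimal.

What the generator does **not** emulate: sequential effects (priming,
post-error slowing), practice and fatigue drifts, heterogeneity of
noise across participants beyond what the intercept/slope distributions
induce, speed–accuracy trade-offs (errors are independent of the
trial's RT), and any response-side asymmetry beyond SNARC. Passing
tests on synthetic data therefore demonstrate that the *estimators and
decision rules* behave as designed under the stated generative model —
not that real data meet that model.

```{r, eval = FALSE}
sim <- simulate_experiment(sim_config(), seed = 42)
pp  <- preprocess_trials(sim$trials)
cls <- classify_participants(pp$trials, n_iter = 5000, seed = 42)
prevalence_table(cls)
```

## Problem sizes and runtime choices

The shipped test-suite and acceptance-script runs use sizes chosen to
make Monte-Carlo conclusions stable while keeping a full run in the
minutes range on one CPU: 500 simulated participants × 1,000 bootstrap
iterations for the type-I calibration, a 300-participant cohort for
parameter recovery (2 Monte-Carlo-SE criterion), the full 98 × 5,000
bootstrap for the prevalence dissociation, 50 random splits for the
reliability estimates in the acceptance script (1,000 remains the
function default), and 5,000 replicates for the t-test alpha check.

## Known limitations

* The H0 bootstrap conditions on the empirical RT pool; with very small
  retained pools (< 50 RTs it refuses outright) the null distribution
  is itself noisy.
* Percentage tables round to integers by design (reporting
  convention), so percentages can sum to 99 or 101.
* The ANOVA Bayes factor's prior parametrisation follows the common
  default-prior formulation, but other implementations differ in
  detail; treat cross-package agreement as approximate.
* `fisher.test`'s exact network algorithm bounds the feasible table
  space; for much larger tables than the 4×3 used here, switch to the
  Monte-Carlo mode.
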