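# magchron

Individual-level analysis of numerical distance and size effects in
symbolic magnitude classification.

## The problem

In the magnitude classification task, participants decide as fast as
possible whether a single Arabic digit (1–4, 6–9) is smaller or larger
than 5. Two classic signatures of analogue magnitude processing appear
in the reaction times (RTs):

- **Numerical distance effect (NDE)** — responses are faster the farther
  the digit is from 5;
- **Numerical size effect (NSE)** — at a fixed distance, responses to
  larger digits are slower.

Group means tell you that the *average* participant shows these effects,
but not *how many* individuals do. `magchron` implements the full
analysis chain needed to answer both questions from trial-level data,
plus a synthetic experiment generator so the entire pipeline can be
exercised and validated without any external data. It is aimed at
numerical-cognition and individual-differences researchers working with
RT chronometry.

## The model

For each participant, RTs are aggregated into the eight digit means
RT(d), which are regressed on the distance and magnitude predictors

    RT(d) = b0 + bD |d − 5| + bM d + e,    d ∈ {1,2,3,4,6,7,8,9}

Over this digit set, |d − 5| and d are exactly orthogonal, so bD and bM
are simultaneously the multiple- and simple-regression slopes. bD < 0 is
the typical NDE; bM > 0 the typical NSE. Ratio and SNARC slopes are
estimated analogously.

Whether an *individual* reliably shows an effect is decided by an **H0
bootstrap**: the participant's retained RTs are pooled (destroying the
digit–RT association), resampled with replacement into 8 sets of 60,
relabelled with the digits, and refitted — 5,000 times — to give that
participant's own null distribution of slopes. An empirical slope of the
typical sign strictly outside the central 90% of this distribution is a
*reliable* effect; one of the opposite sign outside the interval is a
*reliable reverse* effect; anything inside is *not reliable*.

Around this core the package provides: preprocessing (error-rate
screening, < 200 ms anticipation removal, sequential ±3 SD trimming),
split-half reliability with Spearman–Brown correction, one-sided
one-sample t-tests with Cohen's d, one-way ANOVA with partial
eta-squared, default-prior (JZS) Bayes factors for both computed by
direct numerical integration, and exact r×c Fisher tests on prevalence
tables.

## Worked example

```r
library(magchron)

sim    <- simulate_experiment(sim_config(), seed = 42)   # 98 participants
pp     <- preprocess_trials(sim$trials)
slopes <- fit_effects(pp$trials)
cls    <- classify_participants(pp$trials, slopes, n_iter = 2000, seed = 42)
tab    <- table1_report(slopes, cls)

pp
#> <mag_preprocess>
#>   participants retained: 98 (excluded: 0)
#>   overall accuracy:      96.9%
#>   RT data retained:      95.0%

dplyr::filter(tab, group == "Overall")
#> # A tibble: 2 × 10
#>   effect estimate    sd statistic  p.value cohens_d    bf10 pct_reliable pct_reverse pct_not_reliable
#> 1 nde      -12.6   8.17    -15.2  8.51e-28   -1.54  4.18e24           84           2               14
#> 2 nse        1.39  3.38      4.09 4.52e- 5    0.413 4.07e 2           46          17               37
```

Reading the output: the simulated cohort shows a strong group-level NDE
(mean slope −12.6 ms per distance unit, d = −1.54, overwhelming Bayes
factor) and a much weaker NSE (1.39 ms per magnitude unit, d = 0.41).
At the individual level the bootstrap classifies 84% of participants as
showing a reliable NDE but only 46% a reliable NSE — the effects
dissociate in prevalence even though both are solid at the group level.
`plot_slopes(cls)` draws the per-participant slopes coloured by label;
`split_half_reliability(pp$trials, "nde")` quantifies the stability of
the slope measure.

External datasets enter through `read_trials(path, column_map(...))`,
which adapts arbitrary CSV headers and codings to the canonical trial
table, and `run_pipeline()` chains every stage and writes all result
files plus a reproducibility manifest. A thin command-line wrapper lives
in `inst/cli/magchron.R`.

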