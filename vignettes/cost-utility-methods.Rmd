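---
title: "Methods: decision-analytic model for de-escalated BTA dosing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-analytic model for de-escalated BTA dosing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btacea)
```

## The decision problem and the model

Bone-targeted agents are supportive-care drugs: they do not change
survival, only the rate of symptomatic skeletal events (SSEs) and quality
of life. Comparing 12-weekly with 4-weekly dosing is therefore naturally a
single-period cost–utility problem, and the model is a two-strategy
decision tree over a 48-week horizon — one chance node per strategy,
splitting patients into those who experience at least one SSE and those
who do not. No discounting is applied (the horizon is under a year) and no
Markov structure is needed (SSE risk is summarised as a single per-horizon
probability). Currency is 2019 Canadian dollars; the year is metadata
only, never converted.

Per strategy the tree computes

* expected cost `cost_bta + p_sse * cost_sse`, and
* expected QALY `p_sse * qaly_sse + (1 - p_sse) * qaly_no_sse`.

Both are linear, so closed forms are exact; the package nevertheless
carries an independent Monte Carlo branch-lottery simulator
(`simulate_tree_lottery()`) used by the tests to cross-check the algebra.

Incremental results are 12-weekly minus 4-weekly. The ICER is reported
through a dominance taxonomy (standard CEA practice: a negative ICER is
meaningless, so a cheaper-and-more-effective strategy is reported as
DOMINANT rather than with a ratio), and the incremental net benefit
`INB = wtp * delta_qaly - delta_cost` is evaluated at C$50,000/QALY.
Reporting rounds money to cents and QALYs to three decimals, but every
downstream computation uses unrounded values — the published table itself
shows signs of stage-wise rounding (its 12-weekly cost differs by about
C$1.30 from the value its own inputs imply), and the package treats the
input-consistent value (C$5669.95) as the reproducible base case. For the
same reason the printed INB of that analysis (C$3681.37, which back-implies
an unrounded QALY gain near 0.00775 rather than the displayed 0.008) is
validated by formula, not by equality.

### Choice of the 12-weekly SSE probability

The base-case table supplies both a direct 12-weekly SSE probability
(0.223) and a relative risk (1.099); `0.203 * 1.099 = 0.223097`, so the
two agree at three decimals. The default mode (`DIRECT`) uses the printed
probability and reproduces the printed arm values. Inside the PSA the
probability is always derived per draw as `min(1, p4 * RR)` (`VIA_RR`),
so sampled `p4` and `RR` stay coherent.

## Weighted costs

The per-arm BTA cost is `sum_d w_d * doses * (drug_d + admin_d)` over the
arm's drug mix, with doses at weeks 0, interval, 2·interval, … strictly
below the horizon: 12 doses for 4-weekly dosing and 4 for 12-weekly. The
per-arm SSE cost is the event-type-mix-weighted mean of the five per-event
costs, arm-specific because the two arms' event-type distributions differ.
The original unit-cost appendix is not reproduced in the available text,
so the packaged unit-cost table is an explicitly synthetic,
inverse-constructed fixture: unit costs and mix weights were solved so the
weighted aggregates equal the authoritative parameter-table values
(C$5642.07 / C$1826.73 for treatment, C$16,369.25 / C$17,234.19 for SSEs)
to the cent. Any real fee-schedule table in the same CSV layout can be
swapped in; the aggregates, not the fixture, are the defaults the model
trusts. The model costs one weighted SSE per event-experiencing patient —
the tree has a single SSE/no-SSE split, so event multiplicity is out of
scope — and the fixture assumes full adherence over 48 weeks (the trial's
handling of partial-year dropouts is unstated).

## Utilities and QALYs

QLQ-C30 responses at weeks 0/12/24/36/48 are mapped to the ten-dimension
QLU-C10D classification (13 contributing items; for a multi-item dimension
the level is the worst response among its present items), valued as
`1 - sum(decrements)` under a pluggable value set anchored at 1 for the
all-level-1 state, and integrated into per-patient QALYs by the trapezoid
rule with weeks converted to years at 52.1775 weeks/year. The conversion
convention is not stated in the source analysis; it is isolated in one
constant (`WEEKS_PER_YEAR`) and a different convention changes all QALYs
by under 0.3%.

Two shipped data files deserve emphasis. The Canadian QLU-C10D value-set
coefficients are published externally and are not redistributed here: the
packaged `valueset_ca_synthetic.csv` is a synthetic value set with
plausible magnitudes (worst state −0.05, pain and physical functioning the
heaviest dimensions), and the packaged item mapping is a best-effort
approximation of the published descriptive system. Both are versioned
fixtures the engine treats as data; applied work should substitute the
published files. Consequently the package's utility *engine* is exact,
while its utility *values* are only as good as the supplied value set —
the same caveat the original analysis makes about mapping algorithms.

Missing data policy (the source analysis is silent; all choices are
configurable arguments): interior missing visits are linearly
interpolated, a missing terminal visit carries the last observation
forward, and patients without a baseline visit are excluded. Utilities
below zero are permitted if the value set produces them.

## Sensitivity analyses

**One-way DSA.** Each parameter moves to its lower and upper 95% limit
with the rest at baseline; the outcome is the INB at C$50,000/QALY
(default, because the ICER is undefined under dominance; ICER mode is
available). The varied parameters are the published ones — the 4-weekly
no-SSE probability (the published limits attach to the no-SSE row and are
asymmetric), the relative risk (propagating to `p12 = p4 * RR`), and the
four weighted costs — plus the four QALY branch values with
`mean ± 1.96 SE` limits estimated from patient-level data, since the
source varied the no-SSE QALY but printed no limits for it. Bars are
sorted by width; sorting is invariant to input order.

**PSA.** 5000 Monte Carlo draws (seedable, bit-reproducible; parameters
sampled in a fixed order). Families follow standard CEA practice because
the source names none: beta for the SSE probability, gamma for costs,
lognormal for the relative risk — each CI-matched so the fitted 2.5th and
97.5th percentiles equal the published limits (gamma via root-finding on
the scale-free quantile ratio, beta via Nelder-Mead on the two quantile
errors, lognormal in closed form) — and normal for QALY branch values,
truncated above at the horizon maximum (48/52.1775 QALYs) by inverse-CDF
sampling. A fit whose implied mean drifts more than 1% from the baseline
is flagged `ci_matched` in its `note` field rather than silently
re-centred. All parameters are drawn independently (no correlation
structure is published); `p12` is derived within each draw. The CEAC
reports, for each willingness-to-pay value, the fraction of draws with
positive net benefit.

Because the original QALY variances are unpublished, the PSA's absolute
acceptability numbers are not comparable to the source's (63.2% at
C$50,000/QALY); the qualitative behaviour — acceptability above 0.5 at
C$50,000 and declining as willingness-to-pay rises, since the QALY gain is
small and uncertain while the cost saving is solid — is the reproducible
claim, and is what the tests assert.

## The synthetic trial generator

The generator emulates the study conditions the analysis assumes: two arms
of 133 (4-weekly) and 130 (12-weekly) patients, SSE probabilities
0.203/0.223, target arm mean QALYs 0.605/0.612, five SSE types assigned by
a radiotherapy-dominant mix, visits every 12 weeks, and 5% missingness on
non-baseline visits. Patient-level utility is `1 - X` with
`X ~ Gamma(shape, scale)` — right-skewed decrements give the left-skewed,
ceiling-bounded utility distributions typical of cancer QoL data — with a
between-patient SD of 0.22, multiplicative lognormal visit noise
(`sdlog = 0.15`, unit mean), and an additive decrement of 0.10 from a
uniformly drawn event week onward for SSE patients. These magnitudes are
field-plausible assumptions, stated once here; the trial's true
SSE-conditional utilities and per-type counts are not published.

Item responses are emitted by *randomised rounding*: the 30 possible
one-level worsenings of the value set form an ordered ladder of achievable
utility decrements, and each latent decrement is rounded to one of its two
bracketing rungs with probabilities that make the emitted utility equal
the latent one in expectation (the discrete descriptive system cannot hit
arbitrary reals; latent utilities are stored alongside for oracle tests).
The descriptive system also censors decrements at the worst achievable
state, so the gamma mean is calibrated against the *censored* expectation
(numerical integration plus root-finding) rather than the naive closed
form — without this the recovered arm means sit about 0.002 QALYs above
target. With it, the full pipeline (generate → map items → value → QALY)
recovers the target arm means and SSE proportions without bias, which is
the package's core parameter-recovery test (200 replicates, about 10 s).

What the generator does *not* emulate: informative dropout or survival
(missingness is uniform), treatment toxicity, correlation between SSE risk
and baseline utility, and real QLQ-C30 response patterns on the 17 items
the mapping does not use (they are filled cosmetically). Passing recovery
tests therefore show the pipeline is internally correct and unbiased under
these assumptions — not that the synthetic data are distributionally
indistinguishable from trial data.

## Numerical choices and degenerate inputs

* Money is double precision; reporting rounds to cents, comparisons in
  tests use 1e-9 relative tolerance (half-cent tolerance for the
  published aggregates).
* Weight vectors must sum to 1 within 1e-9; violations are errors, not
  renormalisations.
* `delta_qaly = 0` with a cost difference yields a `COST_ONLY` flag
  rather than an infinite ICER; identical arms are `EQUIVALENT`.
* Degenerate parameter ranges (`lower == upper`) become point masses in
  the PSA, under which the CEAC is a step function at `dC/dE` — a
  property the tests exercise.
* The branch-QALY calibration is exactly conservative: the observed-
  proportion-weighted recombination of the stratified means reproduces
  the arm mean to 1e-12 (law of total expectation).
* Problem sizes used by the shipped analyses and tests: 5000 PSA draws,
  200 recovery replicates, 10^6-draw lottery cross-check — all chosen as
  comfortable Monte Carlo sizes for the precision the assertions need.

## Known limitations

* The value set and item mapping are synthetic stand-ins; absolute
  utility levels carry no external validity until a published value set
  is substituted.
* The single-period tree cannot represent repeated SSEs, event timing
  effects on costs, or SSE-rate change beyond 48 weeks.
* PSA acceptability probabilities depend on QALY variances the source
  does not publish; only their qualitative shape is comparable.
* The DSA varies one parameter at a time; correlated scenarios (e.g.
  drug-mix shifts moving both arms' costs) are out of scope.
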