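---
title: "Measuring neurobehavioral change with the Coma/Near-Coma scale: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring neurobehavioral change with the Coma/Near-Coma scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cncrasch)
```

## The measurement problem

The Coma/Near-Coma (CNC) scale is a bedside assessment of neurobehavioral
function for patients with disorders of consciousness (vegetative
state/unresponsive wakefulness syndrome, minimally conscious state). Each
item is rated on a 3-point scale, coded 0/2/4 on the scoring form with lower
values meaning better function. Ordinal totals are not interval quantities:
a 2-point gain near the floor is not the same amount of change as a 2-point
gain mid-scale. Before change scores, measurement error, or responsiveness
benchmarks can be interpreted, the ordinal item responses must be placed on
an interval scale.

This package does that with the Andrich rating scale model (RSM), a
polytomous Rasch model. For a person of ability $\theta_n$ (logits) and an
item of difficulty $\delta_i$ (logits), with thresholds $\tau_1 \dots
\tau_m$ shared by all items,

$$P(X_{ni} = k) = \frac{\exp\sum_{j=1}^{k}(\theta_n - \delta_i - \tau_j)}
{\sum_{l=0}^{m}\exp\sum_{j=1}^{l}(\theta_n - \delta_i - \tau_j)},$$

with the empty sum for $k = 0$. Analysis uses the reversed, compacted item
coding 0/1/2 (`rescoreCNC()`), so a higher score and a higher measure both
mean better function. Two scale versions are supported throughout: the
10-item CNC (without the olfactory item) and the 8-item CNC, which further
drops the two painful-stimulus items.

## Estimation

`fitRSM()` implements joint maximum likelihood (JMLE): starting values from
logit-transformed score proportions (PROX-style), then alternating damped
Newton-Raphson updates of person abilities, item difficulties, and
thresholds until the largest update falls below `tol` (default $10^{-4}$
logits, capped at 200 sweeps). The score equations solved are the classical
Rasch sufficiency conditions: each person's expected total equals their
observed total, each item's expected score total equals its observed total,
and the expected count of responses at-or-above each category matches the
observed count. The model is identified by centering item difficulties at 0
and thresholds to sum 0; the person scale is left free, which matches the
0-centered frame of the published CNC conversion tables. The implementation
was checked against a brute-force BFGS maximisation of the same joint
likelihood; both give identical estimates to four decimals.

Persons with extreme raw scores (0 or the maximum over the items they
answered) carry no information about item parameters and are excluded from
estimation; they are measured afterwards by extrapolation. Missing responses
are simply skipped in all sufficient statistics, and the person's achievable
maximum shrinks accordingly.

Two estimation choices deserve comment:

* **JMLE bias.** JMLE estimates of the item/threshold structure are biased
  outward by roughly $L/(L-1)$ for an $L$-item test, because each person's
  ability is an incidental parameter. With only 8 items this is material: in
  simulation the thresholds overshoot by about 20%. The
  `biasCorrection` flag applies the standard $(L-1)/L$ shrinkage. It is
  **off by default**, matching the default behaviour of the widely used
  rating-scale software family, but parameter-recovery experiments in this
  package enable it, since their purpose is recovering generating values
  rather than mimicking other software. With the correction, simulation at
  $n = 500$, $L = 8$ recovers difficulties and thresholds with RMSE well
  below 0.15 logits.
* **Extreme-score adjustment.** Maximum-likelihood measures for raw 0 and
  the maximum are infinite. `personMeasureFromRaw()` pulls extreme scores
  inward by `extremeAdjust` score points (default 0.3) before inverting the
  test characteristic curve, yielding finite endpoint measures with large
  standard errors. The exact inward adjustment used by other software is not
  standardised, so it is exposed as a parameter and endpoint measures are
  treated as extrapolations, not as comparable targets.

Person measurement inverts the test characteristic curve (TCC): the raw
score is sufficient for ability, so `personMeasureFromRaw()` solves
$E[\text{score}](\theta) = r$ by Newton-Raphson and attaches
$SE = 1/\sqrt{\text{information}}$. `conversionTable()` applies this to
every achievable total, producing the familiar raw-score-to-measure table
(17 rows for the 8-item version, 21 for the 10-item one) together with the
equivalent total on the original 0/2/4 coding.

When a cohort is assessed twice, both timepoints are stacked into a single
calibration by default (`stackTimepoints()`), so one measurement frame
applies to baseline and follow-up; anchored designs can instead fit one
timepoint and measure the other against the fitted parameters with
`personMeasureFromRaw()`.

## Reliability and the responsiveness panel

Wright's person separation reliability (`wrightPSR()`) is
$R = (\mathrm{Var}_{obs} - \overline{SE^2})/\mathrm{Var}_{obs}$ over
included person measures, floored at 0. Non-extreme persons only are
included by default (their measures are model-based rather than
extrapolated); a flag includes everyone.

From paired baseline/follow-up measures, `computeIndices()` assembles:

| quantity | definition | units |
|---|---|---|
| pooled SD | $\sqrt{(SD_{bl}^2 + SD_{fu}^2)/2}$ (equal $n$: same cohort twice) | logits |
| SEM | $SD_{pooled}\sqrt{1-r}$ | logits |
| MDC95 | $1.96\sqrt{2}\,SEM$ | logits |
| MCID (0.20/0.33/0.50 SD) | $k \cdot SD_{pooled}$ | logits |
| effect size | $(\bar{x}_{fu}-\bar{x}_{bl})/SD_{pooled}$ | unitless |
| SRM | mean change / SD of change ($n-1$ denominator) | unitless |

The MDC95 multiplier deserves a note: clinical papers sometimes print the
formula as "$1.96 \times SEM \times 2$", but published CNC values (SEM 0.45
giving MDC95 1.25; SEM 0.37 giving 1.03) are only consistent with
$1.96\sqrt{2}$, the correct test-retest multiplier; this package uses
$\sqrt{2}$. The effect-size CI is a normal approximation for a paired
standardized mean difference, $es \pm 1.96\sqrt{1/n + es^2/2n}$ — an
approximation, documented as such; published CI variants differ and one
published 10-item CI pair is internally inconsistent (lower bound above the
upper), so CI cells are never used as reference values here. Report
rounding is half-away-from-zero to 2 decimals (`roundHalfUp()`), which is
what turns an MCID of 0.625 into the conventionally printed 0.63.

Individual change is classified against the MDC95 (`classifyChange()`):
*improved* strictly above $+MDC_{95}$, *declined* strictly below
$-MDC_{95}$, otherwise *within error*. A change exactly at the boundary is
conservatively within error ("beyond measurement error" read strictly); the
classification is antisymmetric in the sign of change. The MDC95 always
exceeds the 0.50-SD MCID while $r < 1 - (0.5/(1.96\sqrt 2))^2 \approx
0.967$, so individual "true change" is a stricter bar than the group-level
benchmarks for any realistically reliable version of this scale.

### A worked clinical example

```{r example}
measure <- lookupMeasure(28, version = 8)   # published 8-item conversion
measure
measureBand(measure, 0.45)                  # ability range, measure +/- SEM
trueChangeThreshold(measure, 1.25)          # true improvement beyond MDC95
```

A patient at raw total 28 (original coding) measures $-1.86$ logits; their
plausible ability band is $-2.31$ to $-1.41$, and only on reaching
$-0.61$ logits or better has the patient improved beyond measurement error.

## The cohort simulator

Patient-level CNC data are not publicly distributable, so validation runs on
simulated cohorts drawn from the same model the engine fits
(`simulateCohort()`). Defaults emulate a two-timepoint
disorders-of-consciousness cohort: baseline abilities
$\theta \sim N(-0.8,\ 1.25)$ logits, an additive latent change
$\Delta \sim N(0.35,\ 0.9)$ independent of baseline, 8 (or 10) items, and
thresholds $(-1, 1)$. The ability location/scale and mean improvement match
the published cohort summaries; the change SD of 0.9 logits is chosen so
that a realistic minority of patients (roughly a quarter to a third) change
beyond measurement error, as observed clinically. The item difficulty
spread of the real CNC items is unpublished, so the default spreads items
evenly over $[-1, 1]$ logits — wide enough to be realistic, narrow enough
that a severe cohort is not floored; it is fully configurable
(`deltas`/`deltaSpread`).

The simulator is generative plumbing for validation, and its realism has
limits: change is additive and independent of baseline (no
regression-to-the-mean structure, no diagnosis strata), missingness is
completely at random, and all items share thresholds exactly as the RSM
assumes. Passing recovery tests therefore demonstrates that the estimation
and index pipeline is self-consistent and correctly implemented — not that
real CNC data satisfy the rating scale model; that evidence must come from
fit analyses of real cohorts.

One subtlety affects group-level benchmarks in simulation: measured person
SDs include measurement error, so the pooled SD of measures exceeds the
generating ability SD. A true latent improvement of exactly $0.5\,SD$
(ability units) therefore sits *at or just below* the 0.50-SD MCID computed
from measured spread — a boundary case by construction. Recovery tests
consequently check that an injected change is recovered within tolerance
and cleanly exceeds the smaller MCID benchmarks, rather than asserting a
knife-edge comparison at 0.50 SD.

## Numerical choices and problem sizes

* Convergence: maximum absolute parameter update $< 10^{-4}$ logits, at
  most 200 sweeps; Newton steps damped to $\pm 1$ logit (parameters) and
  $\pm 3$ logits (TCC inversion, tolerance $10^{-11}$).
* Degenerate inputs fail fast with typed conditions: an all-extreme cohort
  (`cnc_no_estimable_items`), a never-observed category
  (`cnc_unobserved_category`), invalid codes naming the offending cell.
* Validation experiments use $n = 500$ persons for parameter and
  reliability recovery, $n = 2000$ for mean-change recovery, and $n = 5000$
  for the category-frequency goodness-of-fit check — sizes at which Monte
  Carlo noise is well inside the asserted tolerances while the full test
  suite still runs in well under a minute. The end-to-end pipeline check
  uses $n = 40$, the size of the motivating clinical cohort.

## Limitations

* The rating scale model shares one threshold set across items; items with
  idiosyncratic category structure would need the partial credit model,
  which is out of scope, as are item fit statistics and DIF analysis.
* JMLE is used for fidelity to standard clinical Rasch practice; CMLE/MMLE
  would avoid the incidental-parameter bias at the cost of that
  comparability.
* Distribution-based MCIDs are sample-dependent by definition (they scale
  with the cohort's pooled SD) and are group-level benchmarks; individual
  decisions should use the MDC95.
* Published conversion-table endpoints depend on the extreme-score
  adjustment convention of the software that produced them and are shipped
  as reference fixtures, not regenerated targets.
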