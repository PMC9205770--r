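---
title: "Methods: segmented ITS analysis of health-service disruption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmented ITS analysis of health-service disruption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhisits)
```

## The estimation problem

Routine health information systems record, for every facility and month,
how many times a service was delivered. After a system-wide shock we
want three things from such a panel: the immediate relative drop in
service volume, whether volume had returned to its expected path by the
end of the study period, and the cumulative number of visits that never
happened. None of these can be read off the raw series, because service
volumes trend, cycle seasonally, differ enormously between sub-national
units, and — crucially — because the shock also degrades the reporting
that produces the data.

`rhisits` addresses this with a fixed pipeline: facility-level cleaning,
aggregation to sub-national units, a segmented least-squares fit with
cluster-robust small-sample inference, percent-change effect transforms,
and counterfactual missed-care totals. A synthetic generator with known
ground truth exercises every stage.

## The impact model

For unit $i$ and study month $t \in 1..24$ (month 1 anchored at January
of the pre-shock year),

$$Y_{it} = \beta_0 + \beta_1 T + \beta_2 X_t + \beta_3 Z + \beta_4 W +
\beta_5 S + \beta_6 R + \epsilon_{it}$$

with a 15-month baseline, a 6-month acute shock window ($X_t = 1$,
$Z = T - 15 \in 1..6$) and a final resumption quarter ($W = 1$). $S$ is
a block of season dummies, $R$ of unit dummies. $\beta_2$ (level) and
$\beta_3$ (slope) describe the acute disruption; $\beta_4$ is the level
gap remaining at the end of the year relative to the continued baseline
trend. The fit is ordinary least squares on unit-month observations —
the model is linear in counts, not log-linear, so coefficients are
absolute monthly visits and divide naturally by a baseline mean to give
percentage effects.

**Coding of the resumption quarter.** In months $\geq 22$ we set
$X = Z = 0$ and only $W = 1$. The alternative (letting $X$ or $Z$
persist) would make the quarter-4 gap a sum of several coefficients;
under our coding $\beta_4$ alone is the full remaining deficit, which is
exactly the quantity the resumption percent-change effect divides by the
baseline mean. This coding is a genuine modelling choice — the final
quarter could also be parameterized as a new segment with its own slope
— and it is deliberately the most parsimonious one: three months support
at most a level.

**Reference levels.** The first season and first unit in alphabetical
order are absorbed into the intercept. Effect estimates and fitted
values are invariant to this; individual dummy coefficients are not,
which is why the choice is documented rather than configurable.

## Inference with few clusters

Serial correlation within a unit's monthly series would make classical
OLS standard errors badly anti-conservative, so the variance is the
cluster sandwich over units,
$(X'X)^{-1}\left(\sum_g X_g'e_g e_g'X_g\right)(X'X)^{-1}$, scaled by
$[G/(G-1)]\,[(n-1)/(n-k)]$ — the finite-sample convention of the major
econometrics packages, selected so that results are comparable with the
bulk of the applied ITS literature; the alternatives (only $G/(G-1)$, or
no correction) are available through `vcov_type` for sensitivity. With
singleton clusters the estimator collapses to the familiar HC1 form,
which the test suite checks explicitly.

Because national panels may have as few as 5–30 sub-national units,
critical values come from a $t$ distribution with $G-2$ degrees of
freedom rather than the normal — a deliberately blunt small-sample guard
(it keeps $G-2$ even though the unit fixed effects consume many more
parameters). Its operating characteristics are measured, not assumed:
over 500 synthetic replicates under the default conditions the 95% CI
for $\beta_2$ covers the generating value ~95–97% of the time and the
nominal 5% test rejects a true null ~4–5% of the time (the acceptance
script recomputes both).

## Data cleaning

Two threats, two steps, in a fixed order:

1. **Completeness filter** (default: at least 15 reported months of 24,
   boundary inclusive; a reported zero is a report). Applied first so
   that facilities about to be dropped do not contaminate the outlier
   statistics. The threshold balances completeness against
   representativeness: requiring all 24 months discards too much of a
   typical RHIS panel, while low thresholds admit facilities whose gaps
   mimic service declines. `threshold_sensitivity()` reruns the whole
   pipeline at 12/15/18/24 months to show how much the estimates move.
2. **High-outlier rule** (default 3.5 facility-level standard
   deviations above the facility mean, computed over the facility's
   reported months *including* the candidate value, single pass). Low
   outliers are kept: a collapse to near zero during the shock is
   signal, not error. Iterated re-flagging exists behind
   `iterate_outliers` but is off by default — one application is the
   documented procedure, and iteration only matters in pathological
   series.

Two consequences of the include-the-candidate choice are worth knowing.
A single spike among 23 comparable values can reach at most
$\sqrt{24}\cdot 23/24 \approx 4.69$ SDs of its own series, so the 3.5
threshold does catch lone entry errors of any size; but *two equal*
spikes in one series cap at about 3.3 SDs and are mutually masking under
any single-pass or iterated rule of this family. At realistic data-entry
error rates (well under 1% of cells) such collisions are rare; the test
suite measures detection power on singleton injections and documents the
masking bound.

Every run produces a retention audit (cleaned/raw sum per indicator,
facilities reporting per month) because cleaning-induced attrition is
the silent failure mode of RHIS analysis.

## Missing data conventions

A month a facility did not report is an *absent record*, never a zero —
zeros are legitimate data. Unit-month counts are sums over reporting
facilities only, and unit-months with no reporter are absent from the
regression (complete case): the linear model has no missing-data
machinery, and imputation is out of scope. One bias channel survives
cleaning: a retained facility can still skip individual pandemic months,
shrinking unit counts in exactly the window under study and exaggerating
the estimated drop. The generator reproduces this (its dropout rate can
rise during the pandemic), and the worked example in the README shows
the resulting overshoot on a corrupted realization; on uncorrupted
panels the estimates are unbiased, which is how the coverage properties
are measured.

## Effects and missed care

Percent effects are $100\,\beta/\bar{Y}_{\text{base}}$ where
$\bar{Y}_{\text{base}}$ is the observation-weighted mean unit-month
count over baseline months — the same scale the coefficients are
estimated on. CI limits are divided by the same fixed denominator (the
denominator's own sampling error is ignored — a delta-method shortcut
that keeps the effect exactly sign- and scale-coherent with the
coefficient); the p value is the coefficient's own. An alternative
denominator (mean national monthly total per unit) is available; the two
coincide on balanced panels.

Missed care is the sum over the pandemic window (default months 16–24)
of counterfactual minus observed, where the counterfactual is the fitted
model with $X = Z = W = 0$ — trend, season and unit terms retained.
Deficits are computed only for observed unit-months; predictions are not
floored at zero (flooring would bias deficits downward; negatives are
logged with a warning instead). Service groups (e.g. maternal and
newborn = antenatal + delivery + postnatal) sum member deficits before
normalization, and a group missing any member indicator is marked
excluded rather than silently summed over a partial set. Normalization
divides by annual births in thousands (population × crude birth rate /
1,000 / 1,000) or population in thousands. No uncertainty intervals are
attached to missed-care totals: they are point estimates by
construction.

## The synthetic generator

`generating_model()` runs the impact model forward at facility level
with negative-binomial (NB2) noise, $\mathrm{Var} = \mu + \phi\mu^2$,
chosen because RHIS counts are overdispersed relative to Poisson;
$\phi = 0$ switches noise off entirely (counts become the rounded linear
predictor), which is what every exact-recovery test uses, and a Poisson
family is available in between. The linear (not log) mean keeps the
generator's estimand identical to the fitted model's. Negative means are
a configuration error naming the offending cell, never silently clipped.

Default conditions describe a realistic mid-sized country panel: 10
units × 20 facilities × 24 months; baseline level 100 visits per
facility-month with trend +0.5/month; shock level −30 (a 30% drop) with
recovery slope +3/month; resumption gap −10; seasonal amplitude ±8;
unit offsets spanning ±20% of the baseline level; $\phi = 0.05$ (≈25%
coefficient of variation at the baseline mean). `corrupt_panel()` adds
reporting dropout (default 8%, ×1.5 during the pandemic) and replaces
~1% of values with 5× the facility mean, logging every altered cell.

What the generator does *not* emulate — and therefore what passing tests
do not demonstrate about real data: facility openings/closures and
catchment shifts, autocorrelated month-to-month noise within a facility,
reporting errors that are plausible rather than extreme (e.g. digit
transpositions near the mean), heterogeneous shock timing across units,
and any behavioural response of care-seeking. The validation shows the
*pipeline* recovers what it assumes; it cannot certify the impact
model's adequacy for any particular country's data.

## Numerical choices and scale of the validation

OLS is solved by QR (`lm.fit`); the explicit normal-equations solve and
a literal loop-over-clusters sandwich exist only as test oracles, which
the implementation must match to 1e-8 relative tolerance (and the
sandwich additionally cross-checks against an independent
implementation). Design rank is verified up front, with collinear
columns named — a panel with no observations in some regime fails here
rather than in the fit. Fitting requires $G \geq 2$, inference
$G \geq 3$; a metropolitan-subset analysis that leaves a single unit
aborts with an explanatory error.

Validation problem sizes were picked to make every stochastic check
statistically meaningful while keeping the whole suite quick on a
laptop: 10 units × 20 facilities (4,800 facility-months per replicate)
for the calibration studies, 500 replicates for coverage and size,
10,000+ cells for moment checks, 50 random panels for oracle
equivalence. Seeds are fixed throughout; the package never touches the
caller's RNG state (`simulate_panel()` saves and restores it).

## Known limitations

Inference relies on the cluster asymptotics in $G$; with very few units
(say $G < 8$) the $t(G-2)$ guard helps but wild-bootstrap alternatives
(out of scope) would be more principled. The missed-care counterfactual
inherits all the ITS identifying assumptions — no concurrent
interventions, correct functional form for trend and season. The
per-1,000 normalization treats population and birth-rate denominators as
known constants. And the cleaning rules are facility-level univariate
screens; cross-indicator consistency checks and imputation are
explicitly out of scope.
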