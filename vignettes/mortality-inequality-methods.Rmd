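---
title: "Methods: abridged life tables, lifespan variation, and inequality measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: abridged life tables, lifespan variation, and inequality measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lifevar)
```

## Overview

`lifevar` estimates period life expectancy and lifespan variation for
population strata defined by race/ethnicity, gender, county urbanicity, and
5-year calendar period, from death counts and midyear population counts on
an abridged age grid, and summarises absolute and relative inequalities
between strata. This vignette is the package's account of the methods: the
model assumptions, the parameters that matter, what the synthetic-data
generator does and does not emulate, the numerical choices, and the known
limitations.

## The age grid

All computation runs on the 19-interval abridged partition `[0,1)`, `[1,5)`,
five-year intervals to `[80,85)`, and an open `85+` interval (`age_grid()`).
This is the grid on which public vital-statistics tabulations are released;
the infant interval is split off because mortality in the first year of life
is an order of magnitude above early childhood, and the open interval exists
because age reporting and exposure estimation degrade at the oldest ages.

## Abridged life tables

For each stratum the central death rate is `m_x = D_x / N_x`, deaths over
person-years (midyear populations summed over the pooled years; summing
versus averaging changes deaths and exposure by the same factor and leaves
the rates untouched). Rates convert to death probabilities with the standard
Greville relation

    q_x = n m_x / (1 + (n - a_x) m_x),

clipped at 1, and the usual recursion gives `l_x`, `d_x`, person-years
`L_x = n l_{x+n} + a_x d_x`, cumulative `T_x`, and `e_x = T_x / l_x` with
radix 100,000. Nothing is rounded inside the recursion; rounding is purely a
presentation concern.

Separation factors (`default_ax()`): `a_0 = 0.1` year (infant deaths are
heavily concentrated shortly after birth; 0.1 is the conventional choice for
low-infant-mortality populations and is configurable, with an
Andreev-Kingkade-style rate-dependent rule available as
`infant_rule = "mx"` for schedules where `m_0` is far from modern US
levels), `a = 1.5` for `[1,5)`, the midpoint `n/2` elsewhere, and
`a = 1/m` for the open interval. The open interval is closed by a
constant-hazard assumption: if everyone alive at 85 dies at constant rate
`m`, remaining life is exponential and `e_85 = 1/m`. This closure is exact
in the following sense: in any stationary population the open-interval
central rate *is* `l_85 / (l_85 e_85)`, so `1/m` recovers `e_85` without
further assumptions about the hazard's shape above 85.

## Lifespan variation

The standard deviation of age at death among survivors to age `y` is
computed from the life-table death distribution in the Shkolnikov-Andreev
style: interval deaths `d_x` sit at their mean age at death `x + a_x`, and

    sd_y^2 = sum_{x >= y} d_x ((x + a_x) - mu_y)^2 / l_y,

centred at the `d_x`-weighted mean `mu_y` (identical to `y + e_y` under the
table's accounting identity, but the weighted form keeps the variance
nonnegative even for an inconsistent user-supplied table).

**Open-interval variance.** A design choice was genuinely open here. The
spreadsheet convention treats the open interval as a bare point mass at
`85 + a_open`, which makes `sd` ignore all dispersion above 85; in the
constant-hazard limit (`m_x = mu` everywhere) it yields `cv_0 ~ 0.90` where
the exponential distribution's true coefficient of variation is exactly 1.
The package default instead carries the same constant-hazard closure used
for `e_85` through to the second moment: remaining lifetimes above 85 are
exponential with mean `a_open`, hence variance `a_open^2`, and the open
interval contributes `d_open * a_open^2 / l_y` beyond its location term.
This makes the exponential limit exact and keeps the two moments of the
table mutually consistent. The strict point-mass variant remains available
as `sd_at_age(..., open_tail = "point")`. Both variants summarise everything
above 85 through one closure assumption, so both degrade as the share of
deaths above 85 grows (see Limitations).

The coefficient of variation is `cv_y = sd_y / e_y`. At older starting ages
the default normalises by *remaining* life expectancy — dispersion in the
timing of death relative to the time still expected to live — because that
is the quantity that makes variation at, say, age 65 comparable across
groups with very different survival. Normalising by the total mean age at
death `y + e_y` is available via `normalize = "total"`.

## Uncertainty

Death counts in vital registration are well modelled as Poisson; exposures
are census-derived and comparatively stable. `poisson_bootstrap()` therefore
redraws `D*_x ~ Poisson(D_x)` with exposures fixed, rebuilds the life table,
and re-evaluates the statistic; the standard error is the replicate standard
deviation and the 95% interval uses the 2.5/97.5 percentiles (replicate
distributions of `cv` can be skewed in small strata, so percentile bounds
are preferred over a normal approximation). The default is 1000 replicates;
at least 100 are required. A replicate whose open-interval count is zero
cannot close a table and is redrawn (counted and reported), with a capped
number of rounds. Coverage of the 95% interval for `e_0` is validated by
simulation in the test suite (100 simulated datasets of one million
person-years, 1000 replicates each; observed coverage is required to fall in
[90%, 98%]).

This bootstrap quantifies only stochastic count noise. It is a transparent
Monte-Carlo stand-in for fluctuation-theory standard errors used in the
demography literature; systematic errors (denominator mismatch, age
misreporting) are out of scope.

## Inequality measures

All inequality operations are deliberately elementary and auditable:
`absolute_gap(a, b) = a - b`, `relative_ratio(a, b) = a / b` (reference
group first, by convention metropolitan), `range_gap()` the max-min spread
across races within a cell (ties broken by the fixed race order and
flagged), `trend_change(g1, g2) = g1 - g2` (earlier minus later, positive =
narrowed), and `measure_correlation()` the Pearson coefficient across
strata. `inequality_report()` assembles these for every measure column in a
results table. Rounding to the conventional 1 decimal (years) or 2 decimals
(ratios) is left to the caller/report layer; tests compare unrounded values.

## The synthetic-data generator

Restricted-access mortality microdata cannot ship with a package, so
validation runs against a generator whose truth is known exactly
(`scenario_config()`, `make_study_dataset()`).

*Mortality model.* A Siler hazard
`h(t) = a1 exp(-b1 t) + c + a2 exp(b2 t)` — infant decline, background,
Gompertz senescence — reproduces the infant hump and old-age growth the
abridged grid was designed around. The default base schedule
(`a1 = 0.01`, `b1 = 1.5`, `c = 6e-4`, `a2 = 2e-5`, `b2 = 0.105`, all 1/yr)
gives infant mortality near 0.6% and baseline `e0` near 74, plausible for
the study era.

*Group structure.* Strata differ by proportional-hazards multipliers —
race (NHAPI 0.8, H 0.9, NHW 1.0, NHB 1.3), gender (men 1.18, women 0.86),
and a graded urbanicity penalty (0.94 for large-fringe metro up to 1.16 for
noncore) — with a secular improvement factor of 0.995 per year applied as
`0.995^(year - 1990)`. These produce a 4-5 year gender gap, a 5-6 year
NHAPI-NHB race range, a widening metro advantage, and about 3.5 years of
improvement over 30 years: the right orders of magnitude for late-20th
century US mortality differentials. The multipliers keep every stratum's
combined hazard factor above ~0.56 of base, which keeps all strata inside
the operating regime of an 85+-terminated grid (below, on why that
matters).

*Exposures and counts.* County populations are log-normal around the
configured scale; each group's age structure uses the stationary-population
weights of its own period-start schedule and is held fixed over time; death
counts are Poisson draws around the exact interval rates. Counties are
placed in states with realistic weights (including the states named in the
default Hispanic exclusion list, so the exclusion path is exercised; at the
default national scale the excluded share of Hispanic person-years falls
below 1%).

*Ground truth.* The truth table's `e0`, `sd0`, `cv0` per group and period
come from fine-step numerical integration of the continuous generating
hazard — no grid, no sampling. Because exposures are constant within a group
across years, the pooled-period rate equals the mean of yearly rates, and
the pooled truth is evaluated at the mean of the yearly multipliers (the
residual nonlinearity across a 5-year multiplier spread is O(1e-5)
relative).

*What the generator does not emulate* — and hence what passing tests do not
establish about real data: non-proportional group differences (mortality
cross-overs, group-specific age patterns such as a large-fringe advantage
for one race only), migration, spatial correlation between neighbouring
counties, numerator/denominator mismatch in race reporting, and
bridged-race estimation itself (race is a label on input rows). Tests prove
the *pipeline arithmetic* correct against known truth, not that the
generator is a demographic model of the United States.

## Numerical choices

- Hazard integration uses the closed-form Siler cumulative hazard evaluated
  on trapezoid grids with step 0.005 yr for interval rates (0.01 yr for
  truth integrals); the open-ended integrals cut off where unconditional
  survival drops below 1e-10.
- Lifetime simulation inverts the cumulative hazard against
  unit-exponential draws by interpolation on a 0.01-yr grid.
- `q_x` is clipped to 1; once `l_x` hits zero, later `e_x` are reported as 0
  rather than NaN.
- Strata with any zero-exposure interval, or a zero open-interval death
  count, cannot support a life table and are excluded with a warning rather
  than smoothed or imputed — no smoothing method is part of this design.
- All randomness flows from explicit seeds; the pipeline derives
  per-stratum bootstrap seeds by hashing the stratum key against the root
  seed, so adding strata never reshuffles the draws of existing ones.

## Validation design and problem sizes

The test suite validates every stage against independent oracles: the
exponential closed form (constant hazard: `e_0 = e_65 = 1/mu`, `cv_0 = 1`);
fine-grid numerical integration (50 random realistic Siler schedules, `e_0`
within 1%); brute-force simulation (one million exact lifetimes per
schedule, `sd_0` within 2%); exact accounting identities
(`sum d_x = l_0` to 1e-6, mean age at death equal to `e_0` to 1e-9
relative); generator ground truth at large exposures (288 strata, `e_0`
within 0.1 yr and `cv_0` within 0.005); and the bootstrap coverage
experiment described above. The random-schedule distribution anchors adult
mortality through the hazard at age 80 (0.07-0.18/yr), spanning `e0` of
roughly 66-78 — general-population schedules for which an 85+-terminated
grid is an adequate summary of the death distribution.

## Limitations

- **The 85+ truncation bounds what lifespan variation can be measured.**
  With mortality low enough that `e0` exceeds roughly 82, more than half of
  deaths fall in the open interval, where the grid carries no shape
  information; `sd_0` from such a table is dominated by the closure
  assumption under either `open_tail` convention and can deviate from the
  continuous truth by well over 2%. Estimates for very-low-mortality strata
  should be read with that caveat, or computed from a table extended past
  age 100. The generator's default scenario deliberately stays inside the
  reliable regime.
- Abridged discretization biases `e0` slightly low (about −0.05 yr for the
  default schedules, driven by midpoint `a_x` in the old-age intervals);
  this is well inside the 0.1-yr recovery tolerance but is a bias, not
  noise.
- The proportional-hazards group structure cannot represent interactions
  (e.g. urbanicity gradients that differ by race), so inequality *patterns*
  beyond multiplicative ones are outside what the synthetic validation
  exercises.
- The Poisson bootstrap treats exposures as fixed and counts as independent
  across cells; overdispersion or shared-year shocks would widen true
  uncertainty beyond the reported intervals.
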