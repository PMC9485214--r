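# lifevar

Abridged life tables, lifespan variation, and mortality inequalities from
stratified vital-registration counts.

## What problem this solves

Comparing population subgroups on life expectancy alone hides how *unequally*
death is spread within each group. Demographers therefore pair life
expectancy at birth (e0) with a lifespan-variation measure — here the
standard deviation of age at death (sd0, following Shkolnikov and Andreev's
life-table method) and the coefficient of variation (cv0 = sd0 / e0), which
captures both the pace and the shape of mortality. A subgroup with low e0
*and* high cv0 carries a "double burden": shorter and less predictable
lives.

`lifevar` implements that analysis as a reusable, tested pipeline for
death/population counts stratified by year, county, age group (0, 1–4,
5–9, …, 85+), gender, and race/ethnicity:

1. **ingest** — county merges, NCHS-style state-year race exclusions,
   county-to-urbanicity crosswalks (6-level, collapsible to
   metropolitan/nonmetropolitan), pooling into 5-year periods, central death
   rates m_x = D_x / N_x;
2. **lifetable** — abridged period life tables (Greville conversion
   q_x = n·m_x / (1 + (n − a_x)·m_x), radix 100,000, constant-hazard closure
   of the open interval so e_85 = 1/m_85+), with e_x at any grid age;
3. **variation** — sd_y and cv_y of age at death among survivors to age y;
4. **uncertainty** — parametric Poisson bootstrap (resampling death counts)
   for standard errors and 95% percentile intervals of e_y and cv_y;
5. **inequality** — absolute gaps (metro − nonmetro), relative ratios
   (metro / nonmetro), between-race range gaps, period-to-period trend
   changes, and cross-measure correlations;
6. **synthetic data** — a Siler-model (infant decline + background +
   Gompertz senescence) vital-registration generator with exact ground truth
   by numerical integration, so the entire pipeline is testable end to end
   without restricted mortality files.

Real vital-registration microdata are typically restricted; the generator
emulates their schema (counts CSV + crosswalk CSV) with known truth, which
is what all validation in this package runs against.

## Worked example

```r
library(lifevar)

cfg <- pipeline_config(
  scenario = scenario_config(counties_per_level = 4, county_pop_scale = 2e6),
  ages = c(0, 65))
res <- run_pipeline(cfg)

subset(res$results, period == "2015-2019" & race_ethnicity %in% c("NHB", "NHAPI", "ALL"))
```

```
 race_ethnicity gender      urbanicity    e0   sd0    cv0   e65   cv65
            ALL    man    metropolitan 73.61 16.30 0.2215 14.91 0.5230
            ALL    man nonmetropolitan 72.10 16.52 0.2292 14.02 0.5332
            ALL  woman    metropolitan 77.08 15.80 0.2050 17.14 0.5037
            ALL  woman nonmetropolitan 75.62 16.03 0.2120 16.19 0.5108
          NHAPI  woman    metropolitan 79.55 15.33 0.1927 18.74 0.4910
            NHB    man nonmetropolitan 69.10 16.92 0.2449 12.27 0.5524
            ...
```

Each row is one stratum: metropolitan residents outlive nonmetropolitan ones
(here by ~1.5 years), women outlive men, and the best-off group (NHAPI
women, metro) and worst-off group (NHB men, nonmetro) differ by ~10 years of
e0 while the worst-off group also has the *highest* cv0 — the double-burden
pattern. The inequality report makes those comparisons explicit:

```r
subset(res$inequality, period == "2015-2019" & measure == "e0" & gender == "man")
```

```
  race    urbanicity_a    urbanicity_b absolute ratio direction
   ALL    metropolitan nonmetropolitan     1.50  1.02  higher_a
   NHB    metropolitan nonmetropolitan     1.54  1.02  higher_a
 range    metropolitan    metropolitan     5.42  1.08 NHAPI>NHB
 ...
```

`absolute` is metro − nonmetro in years; `ratio` is metro / nonmetro;
`range` rows give the gap between the highest and lowest race within one
urbanicity level. Single comparisons are also available directly:
`absolute_gap(89.8, 72.1)` returns `17.7`, `trend_change(15.4, 13.3)`
returns `2.1` with direction `"narrowed"`.

A thin command-line wrapper ships in `inst/cli/lifevar.R`
(`simulate`, `run`, `lifetable`, `report` subcommands over YAML configs).

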