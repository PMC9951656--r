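# hedgelife

Demographic analysis of wildlife age-at-death records, built for
citizen-science collections of European hedgehogs (*Erinaceus
europaeus*) aged by counting periosteal growth lines — the winter
bone-growth arrest lines that record one survived hibernation each, so
a line count is an integer age in completed years.

The package is aimed at wildlife demographers and conservation
ecologists who have a table of carcass records (sex, integer
age-at-death, death date, cause of death, optionally coordinates and
individual heterozygosity) and want the standard downstream analyses
reproducibly, with every step testable against synthetic data.

## What it computes

**Cohort life tables.** From deaths $d_x$ at each completed age $x$:

    l_x = Σ_{y≥x} d_y      q_x = d_x / l_x       L_x = l_x − 0.5 d_x
    T_x = Σ_{y≥x} L_y      e_x = T_x / l_x       m_x = d_x / L_x

with deaths assumed uniform within each one-year interval
(a = 0.5, including the last). Survivorship ($l_x/l_0$) and hazard
($m_x$) trajectories follow, plus a statistical Type I/II/III
survivorship classification: a quasi-Poisson regression of interval
deaths on age with offset $\log L_x$ (a discrete Gompertz hazard-trend
test), significant positive slope → Type I (risk rises with age),
significant negative → Type III, otherwise Type II.

**Stratified summaries.** Mean age-at-death with normal-theory 95%
intervals (sample sd, z quantile), minimum-age-filtered means, monthly
death distributions with tie-aware peak months, cause/habitat
cross-tabulations with margins and percentages.

**Quasi-Poisson GLM.** A log-link IRLS fitter written in the package
(Pearson dispersion, t tests on n−p d.f.) driving the inbreeding
analyses: age-at-death on individual observed heterozygosity,
optionally interacted with the traffic/non-traffic cause dichotomy.

**Habitat classification.** Urban/rural labelling of death sites from
an integer-coded 100 m land-cover grid: the 81 cells whose centers lie
within 500 m of the site's cell center, reclassified
(urban/rural/other) and decided by strict majority, ties surfaced.

**Synthetic cohorts.** A seeded generator emulating the study
structure (sex/cause mixtures, monthly peaks, truncated-normal
heterozygosity, constant male vs Gompertz female hazards) for
pipeline tests and parameter-recovery validation.

## Worked example

The packaged data are the study sample's age distribution: 388
hedgehogs collected across Denmark (177 males, 109 females, 102
unsexed), ages 0–16.

```r
library(hedgelife)

lt <- life_table(hedgehog_agecounts("male"))
lt
#> Empirical cohort life table (male) - cohort size 177
#>   x  lx ndx   nqx   npx   nLx    Tx    ex   nmx nax
#>   0 177  43 0.243 0.757 155.5 460.5 2.602 0.277 0.5
#>   1 134  54 0.403 0.597 107.0 305.0 2.276 0.505 0.5
#>   ...
#>  16   1   1 1.000 0.000   0.5   0.5 0.500 2.000 0.5
#>  17   0   0     -     -     -   0.0     -     - 0.5

summary(lt)
#> Cohort life table, stratum: male
#>   cohort size      : 177
#>   oldest death     : 16 years
#>   life expectancy  : 2.602 years at age 0
#>   survivorship type: TypeII (hazard-trend slope 0.009, p = 0.824)
```

A newborn male can expect 2.60 further years; the hazard-trend slope
is indistinguishable from zero, i.e. male risk of death is roughly
constant with age (classic Type II). The female table gives e0 =
2.124 years and a significantly rising hazard (Type I):

```r
summary(life_table(hedgehog_agecounts("female")))
#>   life expectancy  : 2.124 years at age 0
#>   survivorship type: TypeI (hazard-trend slope 0.200, p = 0.043)

mean_age_ci(hedgehog_records())
#> all: mean age-at-death 1.83 years, 95% CI [1.62, 2.04] (n = 388)

sex_longevity_ratio(2.602, 2.124)
#> $full_precision
#> [1] 22.50471
#> $rounded_inputs
#> [1] 23.80952
```

The mean age across all 388 animals is 1.8 years; males outlive
females by ~24% when quoted from rounded life expectancies (22.5% at
full precision — both are reported because the rounding convention
changes the headline number).

End-to-end, on any records file:

```r
rec <- simulate_cohort(default_study_config(n = 500), seed = 1)
run_report(rec, "report_out")   # life tables, means, cross-tabs, GLM, log
```

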