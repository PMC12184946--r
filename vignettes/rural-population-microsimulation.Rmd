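---
title: "Microsimulating rural village populations: model, rates and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microsimulating rural village populations: model, rates and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruralsim)
```

## The problem

Small rural villages in China are depopulating through three channels —
low birth rates, out-migration of the young, and ageing in place. Aggregate
cohort models describe the county scale well but smear out exactly the
micro-structure that matters at village scale: who is of working age, who
is likely to leave, and who is left behind. `ruralsim` models a village as
a roster of individual agents. Each agent carries an age (completed integer
years), a sex, a marital status and a vital/residency state, and each
simulated year every resident independently experiences probabilistic
events. Aggregating the surviving roster reproduces village-level counts,
age pyramids and sex structure, and lets counterfactual rate scenarios be
run agent-by-agent.

## The annual step

Within one simulated year, events are applied in a fixed order:

1. **Death.** Each resident dies with its age-band mortality probability.
   Two bands are used: young/middle-aged (ages 0–59, default 0.55‰ per
   year) and elderly (60+, default 8.5‰). Agents have a hard lifespan cap:
   anyone ageing past 100 is removed unconditionally and counted as a
   death.
2. **Out-migration.** Three channels are evaluated in the order education
   (ages 3–22) → marriage (20–40) → labour (19–59); the first success wins,
   so an agent emigrates at most once per year. Emigration is absorbing:
   emigrated agents remain on the roster for auditability but undergo no
   further events, and their recorded age freezes at the year they left.
3. **Birth.** Each eligible woman — by default married and aged 22–40 —
   independently produces one newborn with the annual fertility probability
   (default 6.77‰). Newborns enter at age 0, single, resident; repeated
   births in later years are allowed.
4. **Marriage.** Single residents aged 20–40 flip to `married` with a small
   annual probability (default 7.65‰). Marriage is a status flip only — no
   two-agent matching is performed, because marital status matters here
   only as a fertility-eligibility flag (and marriage-driven emigration is
   its own channel with its own rate).
5. **Ageing.** Resident ages increment by one year.

Because deaths are applied before migration and births, exposure-to-risk
follows standard cohort bookkeeping; the order is fixed inside
`step_year()` so an alternative convention needs only a wrapper. The
identity

```
residents(t+1) = residents(t) + births(t) − deaths(t) − emigrants(t)
```

holds exactly every year by construction (age-cap removals count as
deaths), and the test suite asserts it across random rosters, schedules
and seeds.

Ages increment for residents only. Emigrated agents could in principle
keep ageing, but freezing them at their exit age keeps every recorded age
inside \[0, 100\] without inventing deaths among people the model no longer
follows, and makes the emigrant age distribution — which the empirical
rate fit needs — directly readable from the roster.

## Rate schedules

A `rate_schedule` stores one annual probability per integer age 0–100 for
each event family. The published behavioural rules give *ranges*; the
engine needs point values. Two built-in policies:

* `default_rate_schedule("paper")` — the stated simulation point values
  where given (fertility 6.77‰; mortality 0.55‰ / 8.5‰) and range midpoints
  otherwise (school migration 7.21%, college migration 24.3%, marriage
  migration 7.65‰, labour migration 12.5%).
* `default_rate_schedule("midpoint")` — midpoints throughout.

Two boundaries inside the published windows are not stated anywhere and
are package choices, both configurable: the elderly-mortality band starts
at age 60 (the labour window ends at 59), and the education window 3–22 is
split at age 18 between the school and college sub-rates. Scenario
overrides (`schedule_with_overrides()`) replace a family's probability
uniformly over its window; values outside the published ranges raise a
warning rather than an error because counterfactuals (3% births, 14%
labour migration) exceed them deliberately.

Two readings of fertility eligibility exist in the source material: the
behavioural table restricts births to married women of marriageable age,
while the narrative ties the probability to the village-level birth rate
for all women in the window. The default follows the explicit rule
(married only); `sim_config(fertility_requires_marriage = FALSE)` selects
the broader reading. The sex of a newborn is female with probability 0.5
by default (`p_female_birth`); the source is silent on the birth sex
ratio.

## Randomness and reproducibility

The default engine (`rng = "sequential"`) draws, each year, one uniform
per agent per event family from a single seeded stream, in a fixed order —
fast, vectorised, and bit-reproducible from `(roster, rates, seed)`.
Replicate *r* of an ensemble uses `seed + r`, so a single run coincides
with replicate 1 of the matching ensemble.

For coupled scenario comparisons there is a second mode,
`rng = "per-agent"`: every agent owns a deterministic stream derived from
the base seed and its roster position, and a newborn's stream is a hash of
its mother's. Under this common-random-numbers coupling, raising one rate
(say labour migration) can only remove agents relative to the lower-rate
run — it never changes anyone else's draws — so monotone responses hold
*pathwise*, not just in expectation. The property test for "more migration
never increases the working-age count" uses this mode; aggregate
stochastic checks use the default.

## The Leslie-type comparator

The comparator projects per-age-group counts. Its printed recurrence
scales each group by a survival-net-of-migration bracket and adds
fertility-weighted newborns to the first group:

$$x_0(t+1) = \sum_i b_i\, w_i\, x_i(t), \qquad
  x_i(t+1) = x_i(t)\,[1 - d_i - m_i],$$

with $b$ the per-group fertility rate, $w$ the proportion female, $d$ the
death rate and $m$ the emigration rate (emigrants in group $i$ over people
in group $i$). The source states the survival term ambiguously — read
literally it would roughly double a population every year — so the default
interprets the bracket as $1 - d - m$; the literal form is kept behind
`leslie_step(..., literal_eq1 = TRUE)` for audit and is flagged as such,
not asserted as intended.

The printed recurrence never moves people between age groups, which is
only defensible for one-step checks. The `"cohort"` variant (the default
for multi-year projection) additionally advances survivors to the next
group at rate $1/\text{width}$ per year (the terminal group retains its
survivors), which is exactly multiplication by the assembled Leslie matrix
— `leslie_matrix()` builds it, and the suite checks projector/matrix
equivalence to $10^{-10}$ on random instances, plus convergence of the
long-run growth factor to the dominant eigenvalue.

`fit_leslie_rates()` estimates $d_i, m_i, w_i$ from two consecutive
rosters by the ratio definitions (the roster retains dead and emigrated
agents, so transitions are read off matched ids). Fertility is the one
quantity that is not identifiable per group: rosters carry no mother
links, so total newborns are converted to a single rate spread uniformly
over the groups overlapping the fertility window. Empty groups get rate 0
with a warning.

## Validation statistics

Validation pairs simulated against observed per-bin counts (five reporting
bins per village — ≤19, 20–30, 31–40, 41–59, ≥60 — plus the village totals,
giving 12 pairs for two villages) and runs:

* `paired_t_test()` — the classical two-sided paired *t*-test on the
  differences, with its internal identities (`df = n − 1`,
  `se = sd/√n`, `t = mean/se`) holding exactly for every input. Zero
  variance is reported as an exact tie rather than NaN.
* `bootstrap_paired()` — `n_boot` resamples of the difference vector with
  replacement; reports bias, the bootstrap SE, a percentile CI and a
  two-sided p from the null-centred resampling distribution with the
  (1 + extreme)/(n_boot + 1) correction. The reference software's exact
  bootstrap p/CI conventions are not published, so these two standard
  choices are labelled in the output and matched in distribution, not
  bit-for-bit; the bootstrap seed is always explicit.
* `compare_sex_structure()` — per-sex share deltas.

The published 2024 verification counts ship with the package as a plain
CSV (`verification_2024()`), and `verification_comparison()` rebuilds the
12 pairs. One internal inconsistency of the published table is worth
noting: the Shihan Leslie column sums to 1354 while its printed total is
1355; totals here are always recomputed from the bins (the simulation and
observed columns sum consistently, so the t-test pairs are unaffected).

```{r ttest}
paired_t_test(verification_comparison())
bootstrap_paired(verification_comparison(), n_boot = 1000, seed = 1)
```

## The synthetic generator

`generate_roster()` makes every stage testable without the deposited
village rosters. Given a profile (total residents; youth/working/elderly
shares; male share; pyramid shape) it allocates the exact total across the
three bands by a multinomial draw, spreads ages within bands using fixed
per-5-year weights, draws sex at the male share, and assigns marital
status `married` with probability 0.8 from age 25 up (the source is silent
on initial marital status; both knobs are arguments).

The two pyramid shapes are qualitative emulations of the study villages:
`"broad-base"` puts extra mass at ages 0–4 and 45–54, `"narrow-base"` at
55+. The source provides pyramids only as figures, so the weight vectors
are an artifact choice, fixed in `R/synthetic.R` and deliberately not
tuned to any test outcome. The built-in profiles carry the published 2024
totals and shares (Yunfeng 1060: 38.49/52.26/9.25%; Shihan 1319:
12.21/63.23/24.56%) with a default male share of 0.51, a slight male
surplus typical of rural rosters (the published sex structure is
"near-balanced" without an exact figure).

What the generator does **not** emulate: household and kinship structure,
spatial location, heaped or erroneous ages, the exact 2017 baselines, and
any correlation between marital status and migration history. Tests that
pass on generated rosters therefore establish the *mechanics* of the
simulator and statistics, not the historical accuracy of any particular
village forecast — that requires the deposited baseline rosters, for which
`reproduce_2024_verification()` implements the full 2017→2024 pipeline.

## Numerical choices and problem sizes

* Bin edges are inclusive integer ranges exactly as printed; bins must
  partition \[0, 100\], anything else is a configuration error.
* Probabilities are validated into \[0, 1\]; published-range violations
  warn.
* Degenerate inputs: an empty roster aggregates to a zero table but cannot
  start a simulation; zero residents make proportions undefined (error);
  a zero-variance difference vector yields the exact-tie t report.
* Tie-breaks: migration channels are evaluated education → marriage →
  labour (the windows overlap at ages 20–22); at most one success per
  agent-year.
* The suite sizes its stochastic checks so the whole test run stays in a
  few tens of seconds: binomial rate-recovery uses 10^5 agent-years
  (3 binomial standard errors), conservation uses 100 random triples of
  roster/schedule/seed over 3-year horizons, scenario contrasts use 20
  replicates of a 1319-person roster over 11 years, and the bootstrap
  limit check uses 10^5 resamples against the plug-in closed form
  `sd(d)·√((n−1)/n)/√n` (within 2%).

## Known limitations

* One-way flows only: no return migration, no immigration, no births to
  emigrants. Villages with in-flows need an extended state machine.
* Marriage is a status flip, not a matching process; marital status and
  migration are conditionally independent given age.
* Rates are age- and sex-blind within a family except where the rule
  itself is sex-specific (fertility); the published rules give no
  sex-specific mortality or migration.
* The per-group fertility of the empirical Leslie fit is an aggregate
  (see above); feeding it to long projections attributes births to groups
  only approximately.
* The literal printed projection bracket is preserved for audit but is
  not a usable dynamic model.
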