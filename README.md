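# ruralsim

Agent-based microsimulation of rural village populations.

Small villages depopulate through three channels — few births, heavy
out-migration of the young, and ageing in place. `ruralsim` models a
village as a roster of individual agents (age, sex, marital status,
residency state) and advances it in annual steps: each resident
independently dies, emigrates (education / marriage / labour channels) or
gives birth with age-band probabilities, then ages one year. Aggregating
the roster yields village totals, age pyramids and sex structure; running
the same baseline under different rate schedules yields counterfactual
scenarios. The package is aimed at demographers and rural-planning
researchers who need village-scale (≈10²–10³ residents) projections where
cohort models are too coarse.

Alongside the simulator it provides:

* an age-structured **Leslie-type comparator**: newborns
  `x₀(t+1) = Σᵢ bᵢ wᵢ xᵢ(t)` and per-group survival net of migration
  `xᵢ(t+1) = xᵢ(t)[1 − dᵢ − mᵢ]`, in both an as-printed fixed-group form
  and a standard cohort-advancing matrix form, plus empirical per-group
  rate estimation from consecutive rosters;
* a **validation workflow**: bin simulated vs observed rosters, classical
  paired t-test, bootstrap robustness check, sex-structure comparison;
* a **synthetic roster generator** reproducing observed village profiles
  (exact totals, youth/working/elderly shares, pyramid shape), so the
  whole pipeline is testable without restricted survey data;
* CSV/JSON **I/O with run manifests** that make every simulation
  re-runnable bit-identically, and a thin command-line front end
  (`system.file("cli", "ruralsim.R", package = "ruralsim")`).

## Worked example

Simulate a village with the built-in Shihan profile (1319 residents,
narrow-base pyramid) for 11 years under the default rate schedule, with
20 replicates:

```r
library(ruralsim)

pop <- generate_roster(builtin_profiles()$shihan, seed = 7, year = 2024)
pop
#> <village_population> Shihan, year 2024: 1319 person(s) on roster
#>   resident 1319 | emigrated 0 | dead 0
#>   resident ages: median 50, range 0-100; 49.7% female

run <- simulate_population(pop, default_rate_schedule(),
                           end_year = 2035, seed = 11, replicates = 20)
run
#> <sim_ensemble> Shihan, 2024-2035, 20 replicates (base seed 11)
#>   mean final residents: 649.2

ts <- trajectory_structure(run)
round(ts[ts$year %in% c(2024, 2030, 2035), ], 3)
#>  year youth working elderly residents
#>  2024 0.124   0.641   0.235    1319.0
#>  2030 0.077   0.387   0.536     838.6
#>  2035 0.028   0.220   0.752     649.2
```

Under the default rates (fertility 6.77‰; mortality 0.55‰ below 60, 8.5‰
from 60; migration at the midpoints of the published ranges) the village
halves in 11 years and the elderly share climbs from 24% to 75%: the
"hollowing-out" pattern, driven almost entirely by labour and education
out-migration of working-age residents. `scenario_sweep()` re-runs the
same baseline under overrides (e.g. `birth_rate = 0.03`,
`labor_migration_rate = 0.07` vs `0.14`) to compare policy
counterfactuals.

Validating simulated against observed 2024 bin counts for the two study
villages (12 pairs: five age bins plus the total, per village) with the
bundled verification table:

```r
paired_t_test(verification_comparison())
#> Paired t-test (simulated - observed)
#>   n = 12, mean = 1.000, sd = 36.332, se = 10.488
#>   95% CI (-22.084, 24.084); t = 0.095, df = 11, p = 0.926
```

The mean simulated−observed difference is one person with a
t-statistic near zero: the simulation is statistically indistinguishable
from the observed rosters at the 95% level. `bootstrap_paired()` backs
this with a resampling check.

See `vignettes/rural-population-microsimulation.Rmd` for the model's
assumptions, every tunable parameter with units and defaults, the RNG
design (including per-agent streams for coupled scenario comparisons) and
known limitations.

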