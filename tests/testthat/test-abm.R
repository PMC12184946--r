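test_that("zero rates give a pure aging step", {
  set.seed(101)
  pop <- pop_from_ages(sample(0:98, 150, replace = TRUE))  # nobody near 100
  set.seed(1)
  st <- step_year(pop, rate_schedule())
  expect_identical(st$population$year, pop$year + 1L)
  expect_identical(n_residents(st$population), n_residents(pop))
  expect_identical(st$population$persons$age,
                   pop$persons$age + as.integer(pop$persons$state ==
                                                  "resident"))
  expect_true(all(st$tally[, c("births", "deaths", "emigrants")] == 0))
})

test_that("agents age out at the 100-year cap even with zero mortality", {
  pop <- pop_from_ages(c(100L, 99L, 50L))
  set.seed(1)
  st <- step_year(pop, rate_schedule())
  p <- st$population$persons
  expect_identical(p$state, c("dead", "resident", "resident"))
  expect_identical(st$tally$deaths, 1L)          # cap removal counts as death
  expect_identical(st$tally$residents, 2L)
  expect_true(all(p$age <= 100L))
})

test_that("one-shot event operators respect windows and rates", {
  # mortality zero, nobody over 100 -> zero deaths
  set.seed(2)
  expect_identical(apply_mortality(make_pop(50), rate_schedule())$deaths, 0L)

  # an agent aged 2 is below every migration window
  toddler <- make_pop(1000, age = 2L, marital = "single")
  set.seed(3)
  mig <- apply_migration(toddler, default_rate_schedule())
  expect_identical(sum(mig$emigrants), 0L)

  # a 45-year-old woman is never fertile (outside 22-40)
  older <- make_pop(1000, age = 45L)
  set.seed(4)
  expect_identical(apply_births(older, default_rate_schedule())$births, 0L)

  # fertility zero -> zero births
  set.seed(5)
  expect_identical(apply_births(make_pop(1000), rate_schedule())$births, 0L)
})

test_that("event frequencies match their binomial expectation", {
  n <- 20000L
  # elderly mortality 8.5 per mille
  eld <- make_pop(n, age = 70L)
  sched <- rate_schedule(mortality = data.frame(age_lo = 60, age_hi = 100,
                                                prob = 0.0085))
  set.seed(10)
  d <- apply_mortality(eld, sched)$deaths
  expect_lt(abs(d - n * 0.0085), 3 * sqrt(n * 0.0085 * (1 - 0.0085)))

  # labour migration 25% at age 25, other channels zero
  lab <- make_pop(n, age = 25L, marital = "single")
  set.seed(11)
  m <- apply_migration(lab, rate_schedule(labor = 0.25))$emigrants
  expect_identical(m[["education"]] + m[["marriage"]], 0L)
  expect_lt(abs(m[["labor"]] - n * 0.25), 3 * sqrt(n * 0.25 * 0.75))

  # fertility 6.77 per mille for married women aged 30
  mom <- make_pop(n, age = 30L)
  set.seed(12)
  b <- apply_births(mom, default_rate_schedule())$births
  expect_lt(abs(b - n * 0.00677), 3 * sqrt(n * 0.00677 * (1 - 0.00677)))

  # unmarried women are excluded under the default eligibility rule
  single <- make_pop(n, age = 30L, marital = "single")
  set.seed(13)
  expect_identical(apply_births(single, default_rate_schedule())$births, 0L)
  set.seed(13)
  cfg <- sim_config(fertility_requires_marriage = FALSE)
  b2 <- apply_births(single, default_rate_schedule(), cfg)$births
  expect_gt(b2, 0L)
})

test_that("emigrated agents undergo no further events and never return", {
  p <- make_persons(100, age = 30L, marital = "single")
  p$state[1:50] <- "emigrated"
  pop <- village_population(p, year = 2020L)
  sched <- suppressWarnings(rate_schedule(labor = 1, mortality = 1))
  set.seed(6)
  st <- step_year(pop, sched)
  out <- st$population$persons
  expect_identical(out$state[1:50], rep("emigrated", 50))   # no double events
  expect_identical(out$age[1:50], rep(30L, 50))             # age frozen
  expect_true(all(out$state[51:100] == "dead"))             # certain death
  expect_identical(st$tally$deaths, 50L)
})

test_that("the conservation identity holds exactly for random scenarios", {
  for (seed in 1:15) {
    pop <- random_roster(seed)
    sched <- random_schedule(seed + 500)
    traj <- simulate_population(pop, sched, horizon = 4L, seed = seed)
    res <- vapply(traj$snapshots, n_residents, integer(1))
    expect_identical(diff(res),
                     with(traj$tallies, births - deaths - emigrants))
    expect_identical(res[-1], traj$tallies$residents)
    # channel tallies add up
    expect_identical(traj$tallies$emigrants,
                     with(traj$tallies, emigrants_education +
                            emigrants_marriage + emigrants_labor))
  }
})

test_that("identical inputs and seed reproduce the trajectory exactly", {
  pop <- random_roster(42)
  sched <- default_rate_schedule()
  for (mode in c("sequential", "per-agent")) {
    cfg <- sim_config(rng = mode)
    a <- simulate_population(pop, sched, horizon = 5L, seed = 7, config = cfg)
    b <- simulate_population(pop, sched, horizon = 5L, seed = 7, config = cfg)
    expect_identical(a$tallies, b$tallies)
    expect_identical(a$snapshots[[6]]$persons, b$snapshots[[6]]$persons)
    c2 <- simulate_population(pop, sched, horizon = 5L, seed = 8,
                              config = cfg)
    expect_false(identical(a$tallies, c2$tallies))
  }
})

test_that("a zero-year horizon returns the baseline only", {
  pop <- random_roster(3)
  traj <- simulate_population(pop, default_rate_schedule(), horizon = 0L)
  expect_length(traj$snapshots, 1L)
  expect_identical(traj$snapshots[[1]]$persons, pop$persons)
  expect_identical(nrow(traj$tallies), 0L)
  empty <- village_population(make_persons(0), year = 2020L)
  expect_error(simulate_population(empty, default_rate_schedule(),
                                   horizon = 1L), "empty")
})

test_that("replicate ensembles average tallies and replicate r matches seed + r", {
  pop <- generate_roster(builtin_profiles()$yunfeng, seed = 1, year = 2017L)
  sched <- default_rate_schedule()
  ens <- simulate_population(pop, sched, horizon = 3L, seed = 100,
                             replicates = 4L)
  expect_length(ens$replicates, 4L)
  single <- simulate_population(pop, sched, horizon = 3L, seed = 100)
  # replicate 1 of the ensemble coincides with the single run (both seed + 1)
  expect_identical(ens$replicates[[1]]$tallies, single$tallies)
  man <- Reduce(`+`, lapply(ens$replicates,
                            function(tr) tr$tallies$residents)) / 4
  expect_equal(ens$mean_tallies$residents, man)
})

test_that("one simulated year recovers the per-group net rate of the projection", {
  # large single-age cohort with constant death and labour-migration rates
  n <- 50000L
  pop <- make_pop(n, age = 30L, marital = "single")
  sched <- rate_schedule(labor = 0.14,
                         mortality = data.frame(age_lo = 0, age_hi = 59,
                                                prob = 0.0085))
  traj <- simulate_population(pop, sched, horizon = 1L, seed = 9)
  got <- n_residents(traj$snapshots[[2]])
  bins <- age_bins(c(0L, 60L), c(59L, 100L))
  lr <- leslie_rates(bins, d = c(0.0085, 0), m = c(0.14, 0))
  expected <- leslie_step(c(n, 0), lr, variant = "printed")[1]
  # binomial Monte-Carlo error around the deterministic projection
  se <- sqrt(n * 0.15 * 0.85)
  expect_lt(abs(got - expected), 4 * se)
})

test_that("raising labour migration never increases the working-age count under per-agent streams", {
  pop <- generate_roster(builtin_profiles()$shihan, seed = 21, year = 2024L)
  sched <- default_rate_schedule()
  cfg <- sim_config(rng = "per-agent")
  low <- simulate_population(pop, schedule_with_overrides(
    sched, labor_migration_rate = 0.07), horizon = 10L, seed = 33,
    config = cfg)
  high <- simulate_population(pop, schedule_with_overrides(
    sched, labor_migration_rate = 0.14), horizon = 10L, seed = 33,
    config = cfg)
  working <- function(traj) vapply(traj$snapshots, function(s) {
    r <- residents(s)
    sum(r$age >= 15L & r$age <= 64L)
  }, integer(1))
  expect_true(all(working(high) <= working(low)))
})
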