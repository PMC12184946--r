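test_that("default schedules use the stated point values and band midpoints", {
  sched <- default_rate_schedule("paper")
  expect_equal(sched$fertility[31], 0.00677)        # age 30
  expect_equal(sched$fertility[22], 0)              # age 21, outside 22-40
  expect_equal(sched$fertility[42], 0)              # age 41
  expect_equal(sched$mortality[31], 0.00055)        # young/middle-aged
  expect_equal(sched$mortality[71], 0.0085)         # elderly (>= 60)
  expect_equal(sched$mortality[60], 0.00055)        # age 59 still young band
  expect_equal(sched$education[3], 0)               # age 2: below all windows
  expect_equal(sched$labor[20], 0.125)              # age 19, midpoint of 0-25%
  expect_equal(sched$labor[19], 0)                  # age 18

  mid <- default_rate_schedule("midpoint")
  expect_equal(unique(mid$labor[20:60]), 0.125)
  expect_equal(mid$fertility[31], mean(c(0.00573, 0.00935)))
  expect_equal(mid$mortality[71], mean(c(0.00483, 0.0087)))
})

test_that("schedule construction validates windows and flags out-of-range values", {
  z <- rate_schedule()                              # all zero is valid
  expect_true(all(vapply(z, function(v) all(v == 0), logical(1))))

  # band outside the family window
  expect_error(rate_schedule(fertility = data.frame(age_lo = 10, age_hi = 30,
                                                    prob = 0.01)),
               "window")
  # overlapping bands
  expect_error(rate_schedule(mortality = data.frame(
    age_lo = c(0, 50), age_hi = c(59, 100), prob = c(0.001, 0.002))),
    "overlap")
  # full vector with mass outside the window
  v <- numeric(101); v[5] <- 0.1                    # age 4 < fertility window
  expect_error(rate_schedule(fertility = v), "must be 0")
  expect_error(rate_schedule(labor = 1.2), "\\[0, 1\\]")

  # scenario values beyond the published range warn but are accepted
  expect_warning(s3 <- schedule_with_overrides(default_rate_schedule(),
                                               birth_rate = 0.03),
                 "outside the published")
  expect_equal(s3$fertility[31], 0.03)
  expect_silent(s7 <- schedule_with_overrides(default_rate_schedule(),
                                              labor_migration_rate = 0.14))
  expect_equal(unique(s7$labor[20:60]), 0.14)
})

test_that("builtin profiles carry the published totals and shares", {
  pr <- builtin_profiles()
  expect_identical(pr$yunfeng$total_residents, 1060L)
  expect_equal(c(pr$yunfeng$youth_share, pr$yunfeng$working_share,
                 pr$yunfeng$elderly_share), c(0.3849, 0.5226, 0.0925))
  expect_identical(pr$shihan$total_residents, 1319L)
  expect_equal(c(pr$shihan$youth_share, pr$shihan$working_share,
                 pr$shihan$elderly_share), c(0.1221, 0.6323, 0.2456))
  for (p in pr) {
    expect_equal(p$youth_share + p$working_share + p$elderly_share, 1,
                 tolerance = 1e-9)
    expect_true(p$male_share > 0.4 && p$male_share < 0.6)
  }
  expect_error(village_profile("bad", 10, 0.5, 0.4, 0.2), "sum to 1")
})

test_that("generated rosters have exact totals and are reproducible per seed", {
  prof <- builtin_profiles()$yunfeng
  a <- generate_roster(prof, seed = 5, year = 2024L)
  b <- generate_roster(prof, seed = 5, year = 2024L)
  c2 <- generate_roster(prof, seed = 6, year = 2024L)
  expect_identical(a$persons, b$persons)
  expect_false(identical(a$persons, c2$persons))
  expect_identical(n_residents(a), 1060L)

  pr <- structure_proportions(a)
  # multinomial error at N = 1060
  tol <- 3 * sqrt(0.53 * 0.47 / 1060)
  expect_true(all(abs(pr - c(0.3849, 0.5226, 0.0925)) < tol))

  empty <- generate_roster(village_profile("none", 0L, 0.2, 0.6, 0.2),
                           seed = 1)
  expect_identical(nrow(empty$persons), 0L)
})

test_that("band allocation at large N is within the multinomial bound", {
  prof <- village_profile("big", 100000L, 0.2, 0.6, 0.2)
  pop <- generate_roster(prof, seed = 2, year = 2020L)
  pr <- structure_proportions(pop)
  for (i in 1:3) {
    p0 <- c(0.2, 0.6, 0.2)[i]
    expect_lt(abs(pr[[i]] - p0), 3 * sqrt(p0 * (1 - p0) / 100000))
  }
  # ages stay within the band the agent was allocated to
  expect_true(all(pop$persons$age >= 0 & pop$persons$age <= 100))
})

test_that("pyramid shapes skew the within-band age spread as described", {
  broad <- generate_roster(village_profile("b", 20000L, 1/3, 1/3, 1/3,
                                           pyramid = "broad-base"),
                           seed = 4, year = 2020L)
  narrow <- generate_roster(village_profile("n", 20000L, 1/3, 1/3, 1/3,
                                            pyramid = "narrow-base"),
                            seed = 4, year = 2020L)
  ab <- broad$persons$age
  an <- narrow$persons$age
  # broad base: more mass at 0-4 within the youth band
  expect_gt(mean(ab[ab <= 14] <= 4), mean(an[an <= 14] <= 4))
  # narrow base: more working-age mass at 55+
  expect_gt(mean(an[an >= 15 & an <= 64] >= 55),
            mean(ab[ab >= 15 & ab <= 64] >= 55))
})
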