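test_that("projected births follow the fertility-weighted female counts", {
  bins <- age_bins(c(0L, 50L), c(49L, 100L))
  lr <- leslie_rates(bins, b = c(0.02, 0.01), w = c(0.5, 0.5))
  expect_equal(project_births(c(100, 200), lr), 2)       # hand sum
  expect_equal(project_births(c(100, 200),
                              leslie_rates(bins, b = 0, w = 0.5)), 0)
  expect_equal(project_births(c(100, 200),
                              leslie_rates(bins, b = c(0.02, 0.01), w = 0)),
               0)
  expect_error(project_births(c(1, 2, 3), lr), "one count per age group")
})

test_that("the printed recurrence scales each group by 1 - d - m", {
  bins <- age_bins(0L, 100L)
  lr <- leslie_rates(bins, d = 0.0085, m = 0.14)
  expect_equal(leslie_step(1000, lr, variant = "printed"), 851.5)
  # literal audit form [1 + p - m] with p = 1 - d
  expect_equal(leslie_step(1000, lr, variant = "printed",
                           literal_eq1 = TRUE),
               1000 * (1 + (1 - 0.0085) - 0.14))
  # with all rates zero both variants are the identity
  z <- leslie_rates(bins)
  expect_equal(leslie_step(123, z, variant = "printed"), 123)
  expect_equal(leslie_step(123, z, variant = "cohort"), 123)
})

test_that("zero-rate cohort advance is a pure shift on single-year groups", {
  lo <- 0:100
  bins <- age_bins(lo, lo)
  lr <- leslie_rates(bins, b = 0, w = 0.5, d = 0, m = 0)
  x <- as.numeric(1:101)
  xn <- leslie_step(x, lr, variant = "cohort")
  expect_equal(xn[1], 0)
  expect_equal(xn[2:100], x[1:99])
  expect_equal(xn[101], x[100] + x[101])   # terminal group accumulates
  expect_equal(sum(xn), sum(x))            # totals preserved while shifting
})

test_that("the cohort projector equals multiplication by its projection matrix", {
  for (seed in 1:10) {
    set.seed(seed)
    bins <- random_bins(seed + 300)
    k <- nrow(bins)
    lr <- leslie_rates(bins,
                       b = runif(k, 0, 0.1), w = runif(k),
                       d = runif(k, 0, 0.05), m = runif(k, 0, 0.2))
    x <- runif(k, 0, 1000)
    expect_equal(leslie_step(x, lr, variant = "cohort"),
                 as.vector(leslie_matrix(lr) %*% x), tolerance = 1e-12)
  }
})

test_that("long-horizon growth converges to the dominant eigenvalue", {
  bins <- five_year_bins()
  k <- nrow(bins)
  set.seed(8)
  lr <- leslie_rates(bins,
                     b = c(0, 0, 0, 0.05, 0.08, 0.06, 0.02, rep(0, k - 7)),
                     w = 0.5,
                     d = seq(0.002, 0.08, length.out = k),
                     m = c(rep(0.01, 4), rep(0.05, 8), rep(0.005, k - 12)))
  proj <- project_leslie(rep(100, k), lr, n_steps = 300, variant = "cohort")
  growth <- sum(proj[301, ]) / sum(proj[300, ])
  lambda <- max(Mod(eigen(leslie_matrix(lr))$values))
  expect_equal(growth, lambda, tolerance = 1e-6)
})

test_that("empirical rates are recovered from consecutive rosters", {
  # hand case: a group of 10 with 2 emigrants has m = 0.2
  p <- make_persons(10, age = 30L)
  pop_t <- village_population(p, year = 2020L)
  p1 <- p
  p1$state[1:2] <- "emigrated"
  pop_t1 <- village_population(p1, year = 2021L)
  bins <- report_bins()
  expect_warning(lr <- fit_leslie_rates(pop_t, pop_t1, bins), "empty")
  expect_equal(lr$m, c(0, 0.2, 0, 0, 0))        # age 30 sits in the 20-30 bin
  expect_equal(lr$d, rep(0, 5))
  expect_equal(lr$w[2], 1)                      # all-female fixture

  # no emigrants anywhere -> m identically zero (empty bins warn)
  expect_warning(lr0 <- fit_leslie_rates(pop_t, pop_t, bins), "empty")
  expect_equal(lr0$m, rep(0, 5))

  # generator ground truth at large N
  n <- 100000L
  set.seed(15)
  pb <- make_persons(n, age = sample(0:100, n, replace = TRUE),
                     sex = sample(c("F", "M"), n, replace = TRUE),
                     prefix = "q")
  big_t <- village_population(pb, year = 2020L)
  pb1 <- pb
  u <- runif(n)
  pb1$state[u < 0.01] <- "dead"
  pb1$state[u >= 0.01 & u < 0.06] <- "emigrated"    # m = 0.05
  big_t1 <- village_population(pb1, year = 2021L)
  fit <- fit_leslie_rates(big_t, big_t1, bins)
  n_i <- leslie_state(big_t, bins)
  for (i in seq_len(nrow(bins))) {
    expect_lt(abs(fit$d[i] - 0.01), 3 * sqrt(0.01 * 0.99 / n_i[i]))
    expect_lt(abs(fit$m[i] - 0.05), 3 * sqrt(0.05 * 0.95 / n_i[i]))
  }

  # mismatched ids are an error
  expect_error(fit_leslie_rates(pop_t, big_t1, bins), "share ids")
})

test_that("a simulated year feeds the rate fit back consistently", {
  pop <- generate_roster(builtin_profiles()$shihan, seed = 30, year = 2024L)
  sched <- default_rate_schedule()
  traj <- simulate_population(pop, sched, horizon = 1L, seed = 14)
  fit <- fit_leslie_rates(traj$snapshots[[1]], traj$snapshots[[2]])
  tal <- traj$tallies
  n0 <- n_residents(pop)
  # group emigration rates aggregate to the overall emigration frequency
  n_i <- leslie_state(pop)
  expect_equal(sum(fit$m * n_i) / n0, tal$emigrants / n0)
  expect_equal(sum(fit$d * n_i) / n0, tal$deaths / n0)
})
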