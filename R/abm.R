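## Annual-time-step agent-based engine. Within a simulated year the event
## order is: mortality -> migration (education, marriage, labour; first
## success wins) -> births -> marriage status update -> age increment.
## Deaths-before-births matches standard cohort bookkeeping; the order is
## carried by step_year() so a different convention only needs a wrapper.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulation engine configuration
#'
#' @param p_female_birth probability that a newborn is female (default 0.5).
#' @param fertility_requires_marriage if `TRUE` (default) the fertility
#'   probability applies to married women in the fertility window only; if
#'   `FALSE`, to all women in the window (the schedule's window is carried by
#'   the fertility rate vector itself).
#' @param rng `"sequential"` (default): one seeded stream per replicate,
#'   fully vectorised. `"per-agent"`: every agent draws from its own
#'   deterministic stream (derived from the base seed and the agent's roster
#'   position; newborns inherit a hash of the mother's stream), so two runs
#'   that differ only in a rate are coupled agent-by-agent -- the mode to use
#'   for monotone scenario comparisons under common random numbers.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(p_female_birth = 0.5,
                       fertility_requires_marriage = TRUE,
                       rng = c("sequential", "per-agent")) {
  stopifnot(p_female_birth >= 0, p_female_birth <= 1)
  structure(list(p_female_birth = p_female_birth,
                 fertility_requires_marriage =
                   isTRUE(fertility_requires_marriage),
                 rng = match.arg(rng),
                 base_seed = NULL),
            class = "sim_config")
}

.draw_names <- c("death", "education", "marriage_mig", "labor",
                 "birth", "child_sex", "marriage")

## One uniform per agent per event family, drawn in a fixed order so that a
## replicate is a single reproducible stream.
.year_draws_seq <- function(n) {
  U <- matrix(stats::runif(7L * n), nrow = n, ncol = 7L)
  colnames(U) <- .draw_names
  U
}

## Per-agent streams: agent i's draws for a given year come from its own
## seed, independent of every other agent, so adding or removing agents
## never shifts anyone else's randomness.
.year_draws_agent <- function(agent_seed, year) {
  n <- length(agent_seed)
  yr <- if (is.na(year)) 0 else as.numeric(year)
  U <- matrix(0, nrow = n, ncol = 7L, dimnames = list(NULL, .draw_names))
  seeds <- (agent_seed * 69069 + yr * 2654435761) %% 2147483647
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    U[i, ] <- stats::runif(7L)
  }
  U
}

.child_stream_seed <- function(mother_seed) {
  (mother_seed * 1664525 + 9973) %% 2147483647
}

#' Advance a village population by one simulated year
#'
#' Applies, in order: probabilistic death per the age-band mortality rates
#' (agents past age 100 cease to exist unconditionally); out-migration with
#' the education, marriage and labour channels evaluated in that fixed order
#' and at most one emigration per agent-year; births for eligible women
#' (newborns enter at age 0, single, resident); marriage status flips
#' (single -> married) in the marriage window; then the age increment for
#' residents. Emigrated agents stay on the roster but undergo no further
#' events, and their age freezes at the year they left.
#'
#' The conservation identity
#' `residents(t+1) = residents(t) + births - deaths - emigrants`
#' holds exactly every year by construction (age-cap removals count as
#' deaths). Randomness comes from R's global RNG: seed with `set.seed()` or
#' use [simulate_population()], which manages seeds per replicate.
#'
#' @param pop a `village_population` at year `t`.
#' @param rates a [rate_schedule()].
#' @param config a [sim_config()].
#' @return a list with `population` (the state at `t + 1`) and `tally`
#'   (one-row data frame: `year`, `births`, `deaths`,
#'   `emigrants_education`, `emigrants_marriage`, `emigrants_labor`,
#'   `emigrants`, `residents`).
#' @export
step_year <- function(pop, rates, config = sim_config()) {
  stopifnot(inherits(pop, "village_population"),
            inherits(rates, "rate_schedule"))
  p <- pop$persons
  n <- nrow(p)
  aseed <- attr(p, "agent_seed")
  if (config$rng == "per-agent") {
    if (is.null(aseed))
      aseed <- (as.numeric(config$base_seed %||% 0L) + seq_len(n)) %%
        2147483647
    U <- .year_draws_agent(aseed, pop$year)
  } else {
    U <- .year_draws_seq(n)
  }

  ai <- p$age + 1L
  resident <- p$state == "resident"

  dies <- resident & (U[, "death"] < rates$mortality[ai] | p$age > 100L)
  alive <- resident & !dies

  mig_edu <- alive & U[, "education"] < rates$education[ai]
  mig_mar <- alive & !mig_edu &
    U[, "marriage_mig"] < rates$marriage_migration[ai]
  mig_lab <- alive & !mig_edu & !mig_mar & U[, "labor"] < rates$labor[ai]
  migrated <- mig_edu | mig_mar | mig_lab
  stays <- alive & !migrated

  eligible <- stays & p$sex == "F" &
    (p$marital_status == "married" | !config$fertility_requires_marriage)
  gives_birth <- eligible & U[, "birth"] < rates$fertility[ai]

  marries <- stays & p$marital_status == "single" &
    U[, "marriage"] < rates$marriage[ai]

  p$marital_status[marries] <- "married"
  p$state[dies] <- "dead"
  p$state[migrated] <- "emigrated"

  res_now <- p$state == "resident"
  p$age[res_now] <- p$age[res_now] + 1L
  capped <- res_now & p$age > 100L
  if (any(capped)) {        # aged past the 100-year cap: cease to exist
    p$age[capped] <- 100L
    p$state[capped] <- "dead"
  }

  mothers <- which(gives_birth)
  nb <- length(mothers)
  if (nb > 0L) {
    child_sex <- ifelse(U[mothers, "child_sex"] < config$p_female_birth,
                        "F", "M")
    ids <- sprintf("%s_nb%06d", pop$village, n + seq_len(nb))
    ids <- make.unique(c(p$id, ids), sep = "_")[n + seq_len(nb)]
    p <- rbind(p, data.frame(id = ids, age = 0L, sex = child_sex,
                             marital_status = "single", state = "resident",
                             stringsAsFactors = FALSE))
    if (!is.null(aseed)) aseed <- c(aseed, .child_stream_seed(aseed[mothers]))
  }
  if (config$rng == "per-agent") attr(p, "agent_seed") <- aseed

  tally <- data.frame(
    year = pop$year,
    births = nb,
    deaths = sum(dies) + sum(capped),
    emigrants_education = sum(mig_edu),
    emigrants_marriage = sum(mig_mar),
    emigrants_labor = sum(mig_lab),
    emigrants = sum(migrated),
    residents = sum(p$state == "resident"))

  list(population = village_population(p, pop$village, pop$year + 1L),
       tally = tally)
}

#' Apply one event family to a roster
#'
#' Standalone one-shot versions of the engine's phases, useful for rate
#' checks and unit experiments; each draws its own uniforms from the global
#' RNG. [apply_mortality()] kills each resident with its age-band mortality
#' probability and removes any agent past age 100 unconditionally.
#' [apply_migration()] evaluates the education, marriage and labour channels
#' in that order with at most one emigration per agent. [apply_births()]
#' lets each eligible woman independently produce one newborn.
#'
#' @param pop a `village_population`.
#' @param rates a [rate_schedule()].
#' @param config a [sim_config()] (births only).
#' @return a list with the updated `population` and the event tally
#'   (`deaths`, a named `emigrants` vector, or `births`).
#' @export
apply_mortality <- function(pop, rates) {
  stopifnot(inherits(pop, "village_population"),
            inherits(rates, "rate_schedule"))
  p <- pop$persons
  u <- stats::runif(nrow(p))
  dies <- p$state == "resident" &
    (u < rates$mortality[p$age + 1L] | p$age > 100L)
  p$state[dies] <- "dead"
  pop$persons <- p
  list(population = pop, deaths = sum(dies))
}

#' @rdname apply_mortality
#' @export
apply_migration <- function(pop, rates) {
  stopifnot(inherits(pop, "village_population"),
            inherits(rates, "rate_schedule"))
  p <- pop$persons
  n <- nrow(p)
  ai <- p$age + 1L
  alive <- p$state == "resident"
  mig_edu <- alive & stats::runif(n) < rates$education[ai]
  mig_mar <- alive & !mig_edu & stats::runif(n) < rates$marriage_migration[ai]
  mig_lab <- alive & !mig_edu & !mig_mar & stats::runif(n) < rates$labor[ai]
  p$state[mig_edu | mig_mar | mig_lab] <- "emigrated"
  pop$persons <- p
  list(population = pop,
       emigrants = c(education = sum(mig_edu), marriage = sum(mig_mar),
                     labor = sum(mig_lab)))
}

#' @rdname apply_mortality
#' @export
apply_births <- function(pop, rates, config = sim_config()) {
  stopifnot(inherits(pop, "village_population"),
            inherits(rates, "rate_schedule"))
  p <- pop$persons
  n <- nrow(p)
  eligible <- p$state == "resident" & p$sex == "F" &
    (p$marital_status == "married" | !config$fertility_requires_marriage)
  gives_birth <- eligible & stats::runif(n) < rates$fertility[p$age + 1L]
  nb <- sum(gives_birth)
  if (nb > 0L) {
    child_sex <- ifelse(stats::runif(nb) < config$p_female_birth, "F", "M")
    ids <- make.unique(c(p$id, sprintf("%s_nb%06d", pop$village,
                                       n + seq_len(nb))),
                       sep = "_")[n + seq_len(nb)]
    p <- rbind(p, data.frame(id = ids, age = 0L, sex = child_sex,
                             marital_status = "single", state = "resident",
                             stringsAsFactors = FALSE))
    pop$persons <- p
  }
  list(population = pop, births = nb)
}

## single reproducible run; `seed` is used verbatim
simulate_once <- function(pop, rates, n_steps, seed, config = sim_config()) {
  cfg <- config
  cfg$base_seed <- seed
  if (cfg$rng == "sequential") set.seed(seed)
  snaps <- vector("list", n_steps + 1L)
  snaps[[1L]] <- pop
  tallies <- vector("list", n_steps)
  cur <- pop
  for (k in seq_len(n_steps)) {
    st <- step_year(cur, rates, cfg)
    cur <- st$population
    snaps[[k + 1L]] <- cur
    tallies[[k]] <- st$tally
  }
  tal <- if (n_steps > 0L) do.call(rbind, tallies) else
    data.frame(year = integer(), births = integer(), deaths = integer(),
               emigrants_education = integer(), emigrants_marriage = integer(),
               emigrants_labor = integer(), emigrants = integer(),
               residents = integer())
  structure(list(village = pop$village,
                 years = pop$year + 0:n_steps,
                 snapshots = snaps,
                 tallies = tal,
                 rates = rates,
                 config = config,
                 seed = seed),
            class = "sim_trajectory")
}

#' Simulate a village population over several years
#'
#' Runs the annual agent-based step from the baseline roster to the horizon,
#' keeping one population snapshot per year (endpoints included) and the
#' per-year event tallies. Replicate `r` of an ensemble uses seed
#' `seed + r`, so a single run (`replicates = 1`) coincides with replicate 1
#' of the matching ensemble and everything is reproducible from
#' `(roster, rates, seed)` alone.
#'
#' @param pop baseline `village_population`; must be non-empty and carry a
#'   calendar year.
#' @param rates a [rate_schedule()].
#' @param horizon number of simulated years (0 returns the baseline-only
#'   trajectory); alternatively give `end_year`.
#' @param end_year final calendar year (used when `horizon` is `NULL`).
#' @param seed base integer seed.
#' @param replicates number of independent replicates.
#' @param config a [sim_config()].
#' @return for `replicates = 1` a `sim_trajectory` (fields `years`,
#'   `snapshots`, `tallies`, `rates`, `config`, `seed`); otherwise a
#'   `sim_ensemble` with the per-replicate trajectories and the mean tally
#'   across replicates.
#' @examples
#' pop <- generate_roster(builtin_profiles()$yunfeng, seed = 1, year = 2017)
#' traj <- simulate_population(pop, default_rate_schedule(), end_year = 2024,
#'                             seed = 42)
#' traj$tallies
#' @export
simulate_population <- function(pop, rates, horizon = NULL, end_year = NULL,
                                seed = 1L, replicates = 1L,
                                config = sim_config()) {
  stopifnot(inherits(pop, "village_population"),
            inherits(rates, "rate_schedule"))
  if (nrow(pop$persons) == 0L)
    stop("starting roster is empty", call. = FALSE)
  if (is.na(pop$year))
    stop("baseline roster must carry a calendar year", call. = FALSE)
  if (is.null(horizon)) {
    if (is.null(end_year))
      stop("supply `horizon` or `end_year`", call. = FALSE)
    if (end_year < pop$year)
      stop("`end_year` must not precede the baseline year", call. = FALSE)
    horizon <- as.integer(end_year) - pop$year
  }
  horizon <- as.integer(horizon)
  replicates <- as.integer(replicates)
  seed <- as.integer(seed)
  stopifnot(horizon >= 0L, replicates >= 1L, !is.na(seed))

  if (replicates == 1L)
    return(simulate_once(pop, rates, horizon, seed + 1L, config))
  runs <- lapply(seq_len(replicates), function(r)
    simulate_once(pop, rates, horizon, seed + r, config))
  num <- setdiff(names(runs[[1L]]$tallies), "year")
  mean_tallies <- runs[[1L]]$tallies
  if (nrow(mean_tallies) > 0L)
    mean_tallies[num] <- Reduce(`+`, lapply(runs, function(tr)
      tr$tallies[num])) / replicates
  structure(list(village = pop$village,
                 years = runs[[1L]]$years,
                 replicates = runs,
                 mean_tallies = mean_tallies,
                 seed = seed),
            class = "sim_ensemble")
}

## per-snapshot age-structure summary; NA shares once a roster empties out
.snapshot_structure <- function(snap) {
  if (n_residents(snap) == 0L)
    return(c(youth = NA_real_, working = NA_real_, elderly = NA_real_,
             residents = 0))
  c(structure_proportions(snap), residents = n_residents(snap))
}

#' Age-structure time series of a simulation
#'
#' @param x a `sim_trajectory` or `sim_ensemble`.
#' @return data frame with one row per simulated year: `year`, `youth`,
#'   `working`, `elderly` shares and the resident count (ensemble: means
#'   across replicates).
#' @export
trajectory_structure <- function(x) {
  if (inherits(x, "sim_ensemble")) {
    mats <- lapply(x$replicates, function(tr)
      t(vapply(tr$snapshots, .snapshot_structure, numeric(4L))))
    avg <- Reduce(`+`, mats) / length(mats)
    return(data.frame(year = x$years, avg))
  }
  stopifnot(inherits(x, "sim_trajectory"))
  data.frame(year = x$years,
             t(vapply(x$snapshots, .snapshot_structure, numeric(4L))))
}

#' Run counterfactual scenarios side by side
#'
#' Applies each scenario's rate overrides (see [schedule_with_overrides()])
#' to a common baseline schedule, simulates each with the same baseline
#' roster, seed policy and replicate count, and returns the mean
#' age-structure trajectories stacked for comparison -- the engine behind
#' high-birth / low-vs-high-migration comparisons.
#'
#' @param pop baseline `village_population`.
#' @param rates baseline [rate_schedule()].
#' @param scenarios named list; each element is a list of override arguments
#'   for [schedule_with_overrides()] (an empty list keeps the baseline).
#' @param horizon,end_year,seed,replicates,config as in
#'   [simulate_population()].
#' @return data frame with columns `scenario`, `year`, `youth`, `working`,
#'   `elderly`, `residents`.
#' @export
scenario_sweep <- function(pop, rates, scenarios, horizon = NULL,
                           end_year = NULL, seed = 1L, replicates = 1L,
                           config = sim_config()) {
  stopifnot(is.list(scenarios), length(scenarios) > 0L,
            !is.null(names(scenarios)), all(nzchar(names(scenarios))))
  out <- lapply(names(scenarios), function(nm) {
    sched <- do.call(schedule_with_overrides,
                     c(list(schedule = rates), scenarios[[nm]]))
    run <- simulate_population(pop, sched, horizon = horizon,
                               end_year = end_year, seed = seed,
                               replicates = replicates, config = config)
    cbind(scenario = nm, trajectory_structure(run))
  })
  do.call(rbind, out)
}

#' @export
print.sim_trajectory <- function(x, ...) {
  n0 <- n_residents(x$snapshots[[1L]])
  n1 <- n_residents(x$snapshots[[length(x$snapshots)]])
  cat(sprintf("<sim_trajectory> %s, %d-%d (seed %d)\n", x$village,
              min(x$years), max(x$years), x$seed))
  cat(sprintf("  residents %d -> %d | births %d, deaths %d, emigrants %d\n",
              n0, n1, sum(x$tallies$births), sum(x$tallies$deaths),
              sum(x$tallies$emigrants)))
  invisible(x)
}

#' @export
print.sim_ensemble <- function(x, ...) {
  cat(sprintf("<sim_ensemble> %s, %d-%d, %d replicates (base seed %d)\n",
              x$village, min(x$years), max(x$years), length(x$replicates),
              x$seed))
  last <- nrow(x$mean_tallies)
  if (last > 0L)
    cat(sprintf("  mean final residents: %.1f\n",
                x$mean_tallies$residents[last]))
  invisible(x)
}
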