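## Published 2024 verification counts for the two study villages and the
## convenience constructors that feed them into the validation workflow.

#' Published 2024 verification counts
#'
#' Per-village, per-age-bin resident counts for 2024: the agent-based
#' simulation, the Leslie-model comparator and the observed resident
#' roster, in the five reporting bins of [report_bins()]. Shipped with the
#' package as a plain CSV.
#'
#' @param include_totals append a `total` row per village (the totals are
#'   recomputed from the bins; the ABM and observed columns reproduce the
#'   published totals of 1061/1060 for Yunfeng and 1324/1319 for Shihan).
#' @return data frame with columns `village`, `age_group`, `abm`,
#'   `leslie`, `observed`.
#' @export
verification_2024 <- function(include_totals = FALSE) {
  path <- system.file("extdata", "verification_2024.csv",
                      package = "ruralsim", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (include_totals) {
    tot <- do.call(rbind, lapply(split(tab, tab$village), function(v)
      data.frame(village = v$village[1L], age_group = "total",
                 abm = sum(v$abm), leslie = sum(v$leslie),
                 observed = sum(v$observed))))
    rownames(tot) <- NULL
    tab <- rbind(tab, tot)
    tab <- tab[order(match(tab$village, unique(tab$village))), ]
    rownames(tab) <- NULL
  }
  tab
}

#' Paired comparison of the published verification counts
#'
#' Builds the [paired_comparison()] behind the published verification
#' statistics: one pair per village and age bin, plus (by default) the
#' total-population row of each village, giving 12 pairs and 11 degrees
#' of freedom.
#'
#' @param model which simulated column to pair against the observed counts
#'   (`"abm"` or `"leslie"`).
#' @param include_totals include the per-village total rows as pairs
#'   (default `TRUE`).
#' @return a [paired_comparison()].
#' @examples
#' paired_t_test(verification_comparison())
#' @export
verification_comparison <- function(model = c("abm", "leslie"),
                                    include_totals = TRUE) {
  model <- match.arg(model)
  tab <- verification_2024(include_totals = include_totals)
  paired_comparison(tab[[model]], tab$observed,
                    labels = paste(tab$village, tab$age_group, sep = ":"))
}

#' Re-run the 2017 -> 2024 verification from deposited baselines
#'
#' Given a directory containing the deposited 2017 resident rosters
#' (`yunfeng_2017.csv`, `shihan_2017.csv`, in the canonical roster format
#' of [read_roster()]), runs the 7-year agent-based simulation for each
#' village under the supplied schedule and summarises the replicate spread
#' of the 2024 resident totals next to the published values.
#'
#' The deposited rosters are supplementary data and are not bundled with
#' the package; point `baseline_dir` at an unpacked copy.
#'
#' @param baseline_dir directory holding the two baseline roster CSVs.
#' @param rates a [rate_schedule()] (default [default_rate_schedule()]).
#' @param replicates replicates per village (default 20).
#' @param seed base seed.
#' @param marital_age marital-status imputation age passed to
#'   [read_roster()] when the deposited files lack a marital column.
#' @return data frame with one row per village: mean, sd, min and max of
#'   the replicate 2024 totals, next to the published ABM (1061, 1324) and
#'   observed (1060, 1319) totals.
#' @export
reproduce_2024_verification <- function(baseline_dir,
                                        rates = default_rate_schedule(),
                                        replicates = 20L, seed = 1L,
                                        marital_age = 25L) {
  published <- data.frame(village = c("Yunfeng", "Shihan"),
                          file = c("yunfeng_2017.csv", "shihan_2017.csv"),
                          abm_published = c(1061L, 1324L),
                          observed_2024 = c(1060L, 1319L))
  out <- lapply(seq_len(nrow(published)), function(i) {
    path <- file.path(baseline_dir, published$file[i])
    if (!file.exists(path))
      stop("baseline roster not found: ", path, call. = FALSE)
    pop <- read_roster(path, village = published$village[i], year = 2017L,
                       default_state = "resident", marital_age = marital_age)
    ens <- simulate_population(pop, rates, end_year = 2024L,
                               seed = seed + 1000L * i,
                               replicates = replicates)
    finals <- vapply(ens$replicates, function(tr)
      n_residents(tr$snapshots[[length(tr$snapshots)]]), numeric(1L))
    data.frame(village = published$village[i],
               mean_total = mean(finals), sd_total = stats::sd(finals),
               min_total = min(finals), max_total = max(finals),
               abm_published = published$abm_published[i],
               observed_2024 = published$observed_2024[i])
  })
  do.call(rbind, out)
}
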