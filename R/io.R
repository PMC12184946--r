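## Roster CSV readers/writers, simulation output directories and the run
## manifest that makes a simulation re-runnable bit-identically.

#' Read a village roster from CSV
#'
#' The canonical roster format is a CSV with header
#' `id,age,sex,marital_status,state`, `sex` in `F`/`M`, `state` in
#' `resident`/`emigrated`/`dead`, one file per village per year. Deposited
#' or third-party rosters with different column names can be adapted with
#' `col_map`, and files lacking the state or marital columns can be
#' completed deterministically (`default_state`, `marital_age`). Validation
#' failures report the offending row numbers.
#'
#' @param path CSV file path.
#' @param village village label (default: file name without extension).
#' @param year calendar year of the roster.
#' @param col_map optional named character vector mapping canonical names
#'   to the file's column names, e.g.
#'   `c(age = "Age", sex = "Gender")`.
#' @param default_state state to assign when the file has no `state`
#'   column (`NULL`, the default, makes the column mandatory).
#' @param marital_age when the file has no `marital_status` column, mark
#'   ages at or above this threshold `married` and the rest `single`
#'   (`NULL` makes the column mandatory).
#' @return a `village_population`.
#' @export
read_roster <- function(path, village = NULL, year = NA_integer_,
                        col_map = NULL, default_state = NULL,
                        marital_age = NULL) {
  if (!file.exists(path))
    stop("roster file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(raw))
        stop("column `", src, "` (mapped to `", canon,
             "`) not found in ", path, call. = FALSE)
      names(raw)[names(raw) == src] <- canon
    }
  }
  if (!"state" %in% names(raw) && !is.null(default_state))
    raw$state <- default_state
  if (!"marital_status" %in% names(raw) && !is.null(marital_age)) {
    age_num <- suppressWarnings(as.numeric(raw$age))
    raw$marital_status <- ifelse(!is.na(age_num) & age_num >= marital_age,
                                 "married", "single")
  }
  miss <- setdiff(.person_cols, names(raw))
  if (length(miss) > 0L)
    stop("roster ", path, " is missing column(s): ",
         paste(miss, collapse = ", "),
         " (expected header id,age,sex,marital_status,state)",
         call. = FALSE)
  raw$age <- suppressWarnings(as.numeric(raw$age))
  if (is.null(village))
    village <- sub("\\.[^.]*$", "", basename(path))
  village_population(raw, village = village, year = year)
}

#' Write a village roster to CSV
#'
#' @param pop a `village_population`.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_roster <- function(pop, path) {
  stopifnot(inherits(pop, "village_population"))
  utils::write.csv(pop$persons, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## reconstruct a rate_schedule from its serialised per-age vectors
.schedule_from_vectors <- function(vecs) {
  stopifnot(all(.rate_families %in% names(vecs)))
  sched <- lapply(.rate_families, function(f) {
    v <- as.numeric(vecs[[f]])
    if (length(v) != 101L || anyNA(v) || any(v < 0) || any(v > 1))
      stop("invalid serialised schedule for family ", f, call. = FALSE)
    v
  })
  names(sched) <- .rate_families
  structure(sched, class = "rate_schedule")
}

#' Write a simulation run to an output directory
#'
#' Writes one roster CSV per simulated year, the per-year event-tally CSV
#' (`year,births,deaths,emigrants_education,emigrants_marriage,`
#' `emigrants_labor,emigrants,residents`), a human-readable run log, and a
#' JSON manifest (seed, configuration, full rate schedule, input digest)
#' sufficient to re-run the simulation bit-identically with
#' [rerun_from_manifest()].
#'
#' @param traj a `sim_trajectory` from [simulate_population()].
#' @param dir output directory (created if needed).
#' @param command free-text command line or label recorded in the manifest.
#' @return invisibly, the manifest path.
#' @export
write_outputs <- function(traj, dir, command = "simulate") {
  stopifnot(inherits(traj, "sim_trajectory"))
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", dir, call. = FALSE)
  roster_files <- sprintf("roster_%d.csv", traj$years)
  for (i in seq_along(traj$snapshots))
    write_roster(traj$snapshots[[i]], file.path(dir, roster_files[i]))
  utils::write.csv(traj$tallies, file.path(dir, "tallies.csv"),
                   row.names = FALSE, quote = FALSE)
  baseline <- roster_files[1L]
  manifest <- list(
    package = "ruralsim",
    version = as.character(utils::packageVersion("ruralsim")),
    command = command,
    village = traj$village,
    years = c(min(traj$years), max(traj$years)),
    seed = traj$seed,
    config = list(p_female_birth = traj$config$p_female_birth,
                  fertility_requires_marriage =
                    traj$config$fertility_requires_marriage,
                  rng = traj$config$rng),
    schedule = traj$rates[.rate_families],
    baseline = list(file = baseline,
                    md5 = unname(tools::md5sum(file.path(dir, baseline)))),
    outputs = c(roster_files, "tallies.csv"),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  manifest_path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_lines <- c(
    sprintf("ruralsim %s run: %s", manifest$version, command),
    sprintf("village %s, years %d-%d, seed %d", traj$village,
            min(traj$years), max(traj$years), traj$seed),
    sprintf("final residents: %d",
            n_residents(traj$snapshots[[length(traj$snapshots)]])))
  writeLines(log_lines, file.path(dir, "run.log"))
  invisible(manifest_path)
}

#' Re-run a simulation from its manifest
#'
#' Reads `manifest.json` and the baseline roster from an output directory
#' written by [write_outputs()] and repeats the simulation with the stored
#' schedule, configuration and seed. The recomputed event tallies are
#' byte-identical to the stored ones.
#'
#' @param dir an output directory containing `manifest.json`.
#' @return the recomputed `sim_trajectory`.
#' @export
rerun_from_manifest <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path))
    stop("no manifest.json in ", dir, call. = FALSE)
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  baseline_path <- file.path(dir, man$baseline$file)
  digest <- unname(tools::md5sum(baseline_path))
  if (!identical(digest, man$baseline$md5))
    warning("baseline roster digest differs from the manifest",
            call. = FALSE)
  pop <- read_roster(baseline_path, village = man$village,
                     year = man$years[1L])
  rates <- .schedule_from_vectors(man$schedule)
  config <- sim_config(p_female_birth = man$config$p_female_birth,
                       fertility_requires_marriage =
                         man$config$fertility_requires_marriage,
                       rng = man$config$rng)
  simulate_once(pop, rates, n_steps = man$years[2L] - man$years[1L],
                seed = as.integer(man$seed), config = config)
}
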