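## Domain types: person rosters, village populations, age bins and
## the aggregation operations shared by the simulator, the Leslie
## projector and the validation workflow.

.person_cols    <- c("id", "age", "sex", "marital_status", "state")
.sex_levels     <- c("F", "M")
.marital_levels <- c("single", "married")
.state_levels   <- c("resident", "emigrated", "dead")

#' Validate a person roster data frame
#'
#' Checks the canonical roster columns (`id`, `age`, `sex`, `marital_status`,
#' `state`), coerces types, and reports the offending row numbers on failure.
#' Ages must be integer years in \[0, 100\] (agents cease to exist past 100),
#' ids must be unique, and the categorical fields must use the canonical codes
#' (`F`/`M`, `single`/`married`, `resident`/`emigrated`/`dead`).
#'
#' @param persons a data frame with the canonical roster columns.
#' @return the validated data frame (canonical columns, canonical types).
#' @keywords internal
validate_persons <- function(persons) {
  if (!is.data.frame(persons))
    stop("`persons` must be a data frame", call. = FALSE)
  miss <- setdiff(.person_cols, names(persons))
  if (length(miss) > 0L)
    stop("roster is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  aseed <- attr(persons, "agent_seed")
  persons <- as.data.frame(persons[.person_cols])
  rownames(persons) <- NULL
  persons$id <- as.character(persons$id)

  age_int <- suppressWarnings(as.integer(persons$age))
  bad <- which(is.na(age_int) | age_int < 0L | age_int > 100L |
                 age_int != persons$age)
  if (length(bad) > 0L)
    stop("invalid age (must be an integer in [0, 100]) at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  persons$age <- age_int

  for (fld in c(sex = "sex", marital_status = "marital_status",
                state = "state")) {
    levs <- switch(fld, sex = .sex_levels, marital_status = .marital_levels,
                   state = .state_levels)
    persons[[fld]] <- as.character(persons[[fld]])
    bad <- which(!persons[[fld]] %in% levs)
    if (length(bad) > 0L)
      stop("invalid ", fld, " (expected one of ",
           paste(levs, collapse = ", "), ") at row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }

  dup <- which(duplicated(persons$id))
  if (length(dup) > 0L)
    stop("duplicated id at row(s): ",
         paste(utils::head(dup, 5L), collapse = ", "), call. = FALSE)
  if (!is.null(aseed)) attr(persons, "agent_seed") <- aseed
  persons
}

#' Create a village population
#'
#' A village population is the simulation state: a roster of individual
#' persons (one row per agent) labelled with a village name and a calendar
#' year. Emigrated and dead agents are retained in the roster with their
#' `state` updated, so event counts stay auditable.
#'
#' @param persons a data frame with columns `id`, `age` (integer years,
#'   0--100), `sex` (`"F"`/`"M"`), `marital_status` (`"single"`/`"married"`)
#'   and `state` (`"resident"`/`"emigrated"`/`"dead"`).
#' @param village village name label.
#' @param year calendar year of the roster (integer; may be `NA` for
#'   year-free rosters, but a year is required to run a simulation).
#' @return an object of class `village_population`.
#' @examples
#' pop <- village_population(data.frame(
#'   id = c("a", "b"), age = c(30L, 70L), sex = c("F", "M"),
#'   marital_status = c("married", "married"),
#'   state = c("resident", "resident")), village = "demo", year = 2017)
#' n_residents(pop)
#' @export
village_population <- function(persons, village = "village",
                               year = NA_integer_) {
  structure(list(village = as.character(village)[1L],
                 year = as.integer(year)[1L],
                 persons = validate_persons(persons)),
            class = "village_population")
}

#' Resident subset of a roster
#'
#' @param pop a `village_population`.
#' @return `residents()`: the data frame of persons with `state == "resident"`;
#'   `n_residents()`: their count.
#' @export
residents <- function(pop) {
  stopifnot(inherits(pop, "village_population"))
  p <- pop$persons
  p[p$state == "resident", , drop = FALSE]
}

#' @rdname residents
#' @export
n_residents <- function(pop) nrow(residents(pop))

#' @export
print.village_population <- function(x, ...) {
  st <- table(factor(x$persons$state, levels = .state_levels))
  cat(sprintf("<village_population> %s, year %s: %d person(s) on roster\n",
              x$village, ifelse(is.na(x$year), "?", x$year),
              nrow(x$persons)))
  cat(sprintf("  resident %d | emigrated %d | dead %d\n",
              st[["resident"]], st[["emigrated"]], st[["dead"]]))
  res <- x$persons[x$persons$state == "resident", ]
  if (nrow(res) > 0L)
    cat(sprintf("  resident ages: median %d, range %d-%d; %.1f%% female\n",
                as.integer(stats::median(res$age)), min(res$age),
                max(res$age), 100 * mean(res$sex == "F")))
  invisible(x)
}

#' Define an age-bin partition of 0--100
#'
#' Bins are inclusive integer ranges that must partition the full age span
#' \[0, 100\] with no gaps or overlaps (overlapping or non-covering bins are a
#' configuration error).
#'
#' @param lo,hi integer vectors of lower/upper bin edges (both inclusive).
#' @param labels optional character labels, one per bin.
#' @return an object of class `age_bins` (a data frame with columns `lo`,
#'   `hi`, `label`).
#' @seealso [report_bins()], [structure_bins()], [five_year_bins()]
#' @export
age_bins <- function(lo, hi, labels = NULL) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != length(hi) || length(lo) == 0L)
    stop("`lo` and `hi` must be non-empty and of equal length", call. = FALSE)
  if (any(is.na(lo)) || any(is.na(hi)) || any(lo > hi))
    stop("each bin needs lo <= hi", call. = FALSE)
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  if (lo[1L] != 0L || hi[length(hi)] != 100L ||
      (length(lo) > 1L && any(lo[-1L] != hi[-length(hi)] + 1L)))
    stop("bins must partition [0, 100] with no gaps or overlaps",
         call. = FALSE)
  if (is.null(labels)) labels <- sprintf("%d-%d", lo, hi)
  if (length(labels) != length(lo))
    stop("`labels` must have one entry per bin", call. = FALSE)
  structure(data.frame(lo = lo, hi = hi, label = as.character(labels[o])),
            class = c("age_bins", "data.frame"))
}

#' Standard reporting bins
#'
#' `report_bins()` gives the five validation bins used to compare simulated
#' and observed rosters (<=19, 20--30, 31--40, 41--59, >=60);
#' `structure_bins()` the youth/working/elderly split (<=14, 15--64, >=65);
#' `five_year_bins()` conventional 5-year pyramid bins (last bin 95--100).
#'
#' @return an [age_bins()] object.
#' @export
report_bins <- function() {
  age_bins(c(0L, 20L, 31L, 41L, 60L), c(19L, 30L, 40L, 59L, 100L),
           labels = c("<=19", "20-30", "31-40", "41-59", ">=60"))
}

#' @rdname report_bins
#' @export
structure_bins <- function() {
  age_bins(c(0L, 15L, 65L), c(14L, 64L, 100L),
           labels = c("youth", "working", "elderly"))
}

#' @rdname report_bins
#' @export
five_year_bins <- function() {
  lo <- seq(0L, 95L, by = 5L)
  age_bins(lo, c(seq(4L, 94L, by = 5L), 100L))
}

## bin index for each age (bins are contiguous, so findInterval suffices)
bin_of <- function(ages, bins) findInterval(ages, bins$lo)

#' Aggregate residents into an age-group table
#'
#' Counts residents (only agents with `state == "resident"`) per age bin and
#' sex. The bin total always equals the resident count: binning is
#' partition-consistent by construction.
#'
#' @param pop a `village_population`.
#' @param bins an [age_bins()] partition (default [report_bins()]).
#' @return an object of class `age_group_table`: a list with `bins`, a
#'   `counts` matrix (bins x sex), and `total`.
#' @export
aggregate_to_bins <- function(pop, bins = report_bins()) {
  stopifnot(inherits(pop, "village_population"))
  if (!inherits(bins, "age_bins"))
    stop("`bins` must be an age_bins partition", call. = FALSE)
  res <- residents(pop)
  idx <- factor(bin_of(res$age, bins), levels = seq_len(nrow(bins)))
  sex <- factor(res$sex, levels = .sex_levels)
  counts <- unclass(table(idx, sex))
  dimnames(counts) <- list(bins$label, .sex_levels)
  structure(list(bins = bins, counts = counts, total = nrow(res)),
            class = "age_group_table")
}

#' Per-bin totals of an age-group table
#'
#' @param tab an `age_group_table`.
#' @return named integer vector of sex-marginal counts per bin.
#' @export
bin_totals <- function(tab) {
  stopifnot(inherits(tab, "age_group_table"))
  rowSums(tab$counts)
}

#' @export
as.data.frame.age_group_table <- function(x, ...) {
  data.frame(age_group = x$bins$label,
             F = unname(x$counts[, "F"]),
             M = unname(x$counts[, "M"]),
             total = unname(rowSums(x$counts)))
}

#' @export
print.age_group_table <- function(x, ...) {
  print(as.data.frame(x), row.names = FALSE)
  cat(sprintf("Total residents: %d\n", x$total))
  invisible(x)
}

#' Youth / working-age / elderly proportions
#'
#' Shares of residents aged <=14, 15--64 and >=65, the three-band structure
#' used to profile village populations.
#'
#' @param pop a `village_population` with at least one resident.
#' @return named numeric vector `c(youth, working, elderly)`, summing to 1.
#' @export
structure_proportions <- function(pop) {
  res <- residents(pop)
  if (nrow(res) == 0L)
    stop("no residents: age-structure proportions are undefined",
         call. = FALSE)
  a <- res$age
  c(youth = mean(a <= 14L),
    working = mean(a >= 15L & a <= 64L),
    elderly = mean(a >= 65L))
}

#' Male and female shares of residents
#'
#' @param pop a `village_population` with at least one resident.
#' @return named numeric vector `c(male, female)`, summing to 1.
#' @export
sex_ratio <- function(pop) {
  res <- residents(pop)
  if (nrow(res) == 0L)
    stop("no residents: sex shares are undefined", call. = FALSE)
  c(male = mean(res$sex == "M"), female = mean(res$sex == "F"))
}
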