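## Age-band rate schedules for the five event families (education,
## marriage and labour out-migration; fertility; mortality) plus the
## marriage status-flip probability backing the fertility eligibility rule.
## Internally every family is a length-101 vector of annual probabilities
## indexed by age 0..100; probabilities outside a rule's age window are 0.

.rate_families <- c("education", "marriage_migration", "labor",
                    "fertility", "mortality", "marriage")

.rate_windows <- list(
  education          = c(3L, 22L),
  marriage_migration = c(20L, 40L),
  labor              = c(19L, 59L),
  fertility          = c(22L, 40L),
  mortality          = c(0L, 100L),
  marriage           = c(20L, 40L)
)

## published annual ranges per family (union of sub-bands where a family
## has several: education = school 4.66-9.76% plus college 0-48.6%;
## mortality = young 0.55-0.95 per mille plus elderly 4.83-8.7 per mille)
.published_ranges <- list(
  education          = c(0, 0.486),
  marriage_migration = c(0.0054, 0.0099),
  labor              = c(0, 0.25),
  fertility          = c(0.00573, 0.00935),
  mortality          = c(0.00055, 0.0087),
  marriage           = c(0.0054, 0.0099)
)

.warn_outside_range <- function(value, family) {
  rng <- .published_ranges[[family]]
  out <- value[value > 0 & (value < rng[1L] | value > rng[2L])]
  if (length(out) > 0L)
    warning(sprintf(
      "%s probability %.4g is outside the published annual range [%g, %g]",
      family, out[1L], rng[1L], rng[2L]), call. = FALSE)
  invisible(value)
}

## Turn a scalar, a bands data frame (age_lo, age_hi, prob) or a full
## length-101 vector into the canonical per-age probability vector.
age_rate_vector <- function(x, family) {
  win <- .rate_windows[[family]]
  v <- numeric(101L)
  if (is.data.frame(x)) {
    need <- c("age_lo", "age_hi", "prob")
    if (!all(need %in% names(x)))
      stop("rate bands need columns age_lo, age_hi, prob", call. = FALSE)
    seen <- logical(101L)
    for (r in seq_len(nrow(x))) {
      lo <- as.integer(x$age_lo[r]); hi <- as.integer(x$age_hi[r])
      p <- as.numeric(x$prob[r])
      if (is.na(lo) || is.na(hi) || lo > hi || lo < win[1L] || hi > win[2L])
        stop(sprintf("%s band %d-%d falls outside the %d-%d age window",
                     family, lo, hi, win[1L], win[2L]), call. = FALSE)
      idx <- (lo:hi) + 1L
      if (any(seen[idx]))
        stop(family, " bands overlap", call. = FALSE)
      seen[idx] <- TRUE
      v[idx] <- p
    }
  } else if (is.numeric(x) && length(x) == 101L) {
    v <- as.numeric(x)
    outside <- setdiff(0:100, win[1L]:win[2L]) + 1L
    if (any(v[outside] != 0))
      stop(family, " probabilities outside the ", win[1L], "-", win[2L],
           " age window must be 0", call. = FALSE)
  } else if (is.numeric(x) && length(x) == 1L) {
    v[(win[1L]:win[2L]) + 1L] <- as.numeric(x)
  } else {
    stop(family, " rate must be a scalar, a bands data frame or a ",
         "length-101 vector", call. = FALSE)
  }
  if (any(is.na(v)) || any(v < 0) || any(v > 1))
    stop(family, " probabilities must lie in [0, 1]", call. = FALSE)
  .warn_outside_range(v[v > 0], family)
  v
}

#' Build an age-band rate schedule
#'
#' A rate schedule holds the annual event probabilities per integer age for
#' the five event families of the behavioural rules (education migration,
#' ages 3--22; marriage migration, 20--40; labour migration, 19--59;
#' fertility, 22--40; mortality, 0--100) plus the annual marriage
#' (single -> married) status-flip probability (20--40). Every probability
#' must lie in \[0, 1\] and is implicitly 0 outside its family's age window.
#'
#' Each argument may be a single probability (applied uniformly over the
#' family's window), a data frame of bands with columns `age_lo`, `age_hi`,
#' `prob`, or a full length-101 per-age vector. Values outside the published
#' annual ranges raise a warning, not an error, because counterfactual
#' scenarios exceed them deliberately.
#'
#' @param education,marriage_migration,labor,fertility,mortality,marriage
#'   per-family rates (scalar, bands data frame, or length-101 vector).
#' @return an object of class `rate_schedule` (list of six length-101
#'   per-age probability vectors).
#' @seealso [default_rate_schedule()], [schedule_with_overrides()]
#' @export
rate_schedule <- function(education = 0, marriage_migration = 0, labor = 0,
                          fertility = 0, mortality = 0, marriage = 0) {
  args <- list(education = education, marriage_migration = marriage_migration,
               labor = labor, fertility = fertility, mortality = mortality,
               marriage = marriage)
  sched <- lapply(.rate_families, function(f) age_rate_vector(args[[f]], f))
  names(sched) <- .rate_families
  structure(sched, class = "rate_schedule")
}

#' Default rate schedule from the published behavioural rules
#'
#' Point values for the published rate ranges. Policy `"paper"` uses the
#' stated simulation point values where given -- fertility 6.77 per mille,
#' young/middle-aged mortality 0.55 per mille, elderly mortality 8.5 per
#' mille -- and band midpoints otherwise (school migration 7.21%, college
#' migration 24.3%, marriage migration 7.65 per mille, labour migration
#' 12.5%). Policy `"midpoint"` uses the midpoint of every published range.
#'
#' @param policy `"paper"` (default) or `"midpoint"`.
#' @param elderly_age first age of the elderly mortality band (default 60;
#'   the young/middle-aged band covers ages 0 to `elderly_age - 1`).
#' @param college_age first age of the college education-migration sub-band
#'   within the 3--22 window (default 18).
#' @return a [rate_schedule()].
#' @examples
#' sched <- default_rate_schedule()
#' sched$fertility[31]  # annual birth probability at age 30
#' @export
default_rate_schedule <- function(policy = c("paper", "midpoint"),
                                  elderly_age = 60L, college_age = 18L) {
  policy <- match.arg(policy)
  elderly_age <- as.integer(elderly_age)
  college_age <- as.integer(college_age)
  stopifnot(elderly_age >= 1L, elderly_age <= 100L,
            college_age >= 4L, college_age <= 22L)
  school  <- mean(c(0.0466, 0.0976))   # primary/secondary migration
  college <- mean(c(0, 0.486))         # college enrollment migration
  marmig  <- mean(c(0.0054, 0.0099))
  labor   <- mean(c(0, 0.25))
  fert <- if (policy == "paper") 0.00677 else mean(c(0.00573, 0.00935))
  mort_young <- if (policy == "paper") 0.00055 else mean(c(0.00055, 0.00095))
  mort_old   <- if (policy == "paper") 0.0085 else mean(c(0.00483, 0.0087))
  rate_schedule(
    education = data.frame(age_lo = c(3L, college_age),
                           age_hi = c(college_age - 1L, 22L),
                           prob = c(school, college)),
    marriage_migration = marmig,
    labor = labor,
    fertility = fert,
    mortality = data.frame(age_lo = c(0L, elderly_age),
                           age_hi = c(elderly_age - 1L, 100L),
                           prob = c(mort_young, mort_old)),
    marriage = marmig)
}

#' Override schedule rates for a counterfactual scenario
#'
#' Replaces a family's probability uniformly over its age window, leaving
#' the other families untouched. Used for the constant-rate and
#' high-birth / low-vs-high-migration scenario runs. Values outside the
#' published ranges warn (scenarios exceed them on purpose, e.g. a 3% birth
#' rate or a 14% labour migration rate).
#'
#' @param schedule a [rate_schedule()].
#' @param birth_rate,labor_migration_rate,education_rate,
#'   marriage_migration_rate,marriage_rate optional replacement
#'   probabilities, applied uniformly over the family's window.
#' @param death_rate_young,death_rate_elderly optional mortality
#'   replacements for ages below / from `elderly_age`.
#' @param elderly_age boundary between the two mortality bands (default 60).
#' @return the modified `rate_schedule`.
#' @export
schedule_with_overrides <- function(schedule,
                                    birth_rate = NULL,
                                    labor_migration_rate = NULL,
                                    education_rate = NULL,
                                    marriage_migration_rate = NULL,
                                    marriage_rate = NULL,
                                    death_rate_young = NULL,
                                    death_rate_elderly = NULL,
                                    elderly_age = 60L) {
  stopifnot(inherits(schedule, "rate_schedule"))
  elderly_age <- as.integer(elderly_age)
  if (!is.null(birth_rate))
    schedule$fertility <- age_rate_vector(birth_rate, "fertility")
  if (!is.null(labor_migration_rate))
    schedule$labor <- age_rate_vector(labor_migration_rate, "labor")
  if (!is.null(education_rate))
    schedule$education <- age_rate_vector(education_rate, "education")
  if (!is.null(marriage_migration_rate))
    schedule$marriage_migration <-
      age_rate_vector(marriage_migration_rate, "marriage_migration")
  if (!is.null(marriage_rate))
    schedule$marriage <- age_rate_vector(marriage_rate, "marriage")
  if (!is.null(death_rate_young)) {
    p <- as.numeric(death_rate_young)
    stopifnot(p >= 0, p <= 1)
    .warn_outside_range(p, "mortality")
    schedule$mortality[seq_len(elderly_age)] <- p
  }
  if (!is.null(death_rate_elderly)) {
    p <- as.numeric(death_rate_elderly)
    stopifnot(p >= 0, p <= 1)
    .warn_outside_range(p, "mortality")
    schedule$mortality[(elderly_age + 1L):101L] <- p
  }
  schedule
}

#' @export
print.rate_schedule <- function(x, ...) {
  cat("<rate_schedule> annual probabilities by age band\n")
  for (f in .rate_families) {
    v <- x[[f]]
    nz <- which(v > 0) - 1L
    if (length(nz) == 0L) {
      cat(sprintf("  %-18s all zero\n", f))
    } else {
      ## collapse runs of equal probability into bands
      brk <- c(TRUE, diff(nz) != 1L | diff(v[nz + 1L]) != 0)
      grp <- cumsum(brk)
      bands <- vapply(split(nz, grp), function(a)
        sprintf("%d-%d: %.4g", min(a), max(a), v[min(a) + 1L]), "")
      cat(sprintf("  %-18s %s\n", f, paste(bands, collapse = "; ")))
    }
  }
  invisible(x)
}
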