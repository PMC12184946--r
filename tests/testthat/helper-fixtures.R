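# fixtures are built in code; no files needed

make_persons <- function(n, age = 30L, sex = "F", marital = "married",
                         state = "resident", prefix = "p") {
  if (n == 0L)
    return(data.frame(id = character(), age = integer(), sex = character(),
                      marital_status = character(), state = character()))
  data.frame(id = sprintf("%s%05d", prefix, seq_len(n)),
             age = rep_len(as.integer(age), n),
             sex = rep_len(sex, n),
             marital_status = rep_len(marital, n),
             state = rep_len(state, n),
             stringsAsFactors = FALSE)
}

make_pop <- function(n, ..., village = "test", year = 2017L) {
  village_population(make_persons(n, ...), village = village, year = year)
}

## roster with prescribed ages
pop_from_ages <- function(ages, sex = NULL, village = "test", year = 2017L) {
  n <- length(ages)
  p <- make_persons(n)
  p$age <- as.integer(ages)
  if (!is.null(sex)) p$sex <- rep_len(sex, n)
  village_population(p, village = village, year = year)
}

## random roster + rate schedule pair for property tests
random_roster <- function(seed, n = 150L) {
  set.seed(seed)
  p <- make_persons(n)
  p$age <- sample(0:100, n, replace = TRUE)
  p$sex <- sample(c("F", "M"), n, replace = TRUE)
  p$marital_status <- ifelse(p$age >= 22 & stats::runif(n) < 0.6,
                             "married", "single")
  village_population(p, village = sprintf("rand%d", seed), year = 2020L)
}

random_schedule <- function(seed) {
  set.seed(seed)
  suppressWarnings(rate_schedule(
    education = stats::runif(1, 0, 0.3),
    marriage_migration = stats::runif(1, 0, 0.05),
    labor = stats::runif(1, 0, 0.25),
    fertility = stats::runif(1, 0, 0.1),
    mortality = stats::runif(1, 0, 0.05),
    marriage = stats::runif(1, 0, 0.05)))
}

## random contiguous partition of [0, 100] into k bins
random_bins <- function(seed, k = NULL) {
  set.seed(seed)
  if (is.null(k)) k <- sample(2:8, 1L)
  cuts <- sort(sample(1:100, k - 1L))
  age_bins(c(0L, cuts), c(cuts - 1L, 100L))
}

## the published 2024 verification differences (12 pairs incl. totals)
published_differences <- function() {
  verification_comparison(model = "abm", include_totals = TRUE)$differences
}
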