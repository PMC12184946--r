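## Age-group projection comparator. The printed recurrence updates each
## group in place,
##   x_0(t+1) = sum_i b_i w_i x_i(t),   x_i(t+1) = x_i(t) [1 - d_i - m_i],
## with b the group fertility rate, w the proportion female, d the death
## rate and m the emigration rate (emigrants in group i / people in group
## i). The source states the survival term ambiguously; the default reads
## the bracket as survival net of death and migration, [1 - d - m], which
## gives sensible dynamics, while `literal_eq1 = TRUE` keeps the literal
## [1 + p - m] with p = 1 - d for audit. A cohort-advancing variant
## additionally moves survivors towards older groups each year (the
## standard Leslie-matrix construction) and is the recommended form for
## multi-year projection.

#' Per-age-group rates for the Leslie-type projector
#'
#' @param bins an [age_bins()] partition defining the groups.
#' @param b annual fertility rate per group (births per woman; >= 0).
#' @param w proportion of women per group (in \[0, 1\]).
#' @param d annual death rate per group (in \[0, 1\]).
#' @param m annual emigration rate per group (in \[0, 1\]).
#' @return an object of class `leslie_rates`. Scalars are recycled across
#'   groups.
#' @export
leslie_rates <- function(bins, b = 0, w = 0.5, d = 0, m = 0) {
  if (!inherits(bins, "age_bins"))
    stop("`bins` must be an age_bins partition", call. = FALSE)
  k <- nrow(bins)
  fix <- function(v, name, lo = 0, hi = 1) {
    if (length(v) == 1L) v <- rep(as.numeric(v), k)
    if (length(v) != k)
      stop("`", name, "` must have one value per age group", call. = FALSE)
    if (any(is.na(v)) || any(v < lo) || any(v > hi))
      stop("`", name, "` out of range", call. = FALSE)
    as.numeric(v)
  }
  structure(list(bins = bins,
                 b = fix(b, "b", hi = Inf),
                 w = fix(w, "w"),
                 d = fix(d, "d"),
                 m = fix(m, "m")),
            class = "leslie_rates")
}

#' Newborns produced by one projection year
#'
#' Sum over groups of fertility times the female share times the group
#' count.
#'
#' @param x numeric vector of group counts.
#' @param rates a [leslie_rates()].
#' @return the projected newborn count (numeric scalar).
#' @export
project_births <- function(x, rates) {
  stopifnot(inherits(rates, "leslie_rates"))
  if (length(x) != nrow(rates$bins))
    stop("`x` must have one count per age group", call. = FALSE)
  sum(rates$b * rates$w * x)
}

#' Assemble the projection matrix of the cohort-advance variant
#'
#' Survivors of group `i` (fraction `1 - d_i - m_i`) advance to the next
#' group at rate `1 / width_i` per year (the last group retains its
#' survivors), and the first row adds the fertility contributions
#' `b_i w_i`. One projection year is multiplication by this matrix.
#'
#' @param rates a [leslie_rates()].
#' @return a square numeric matrix (groups x groups).
#' @export
leslie_matrix <- function(rates) {
  stopifnot(inherits(rates, "leslie_rates"))
  k <- nrow(rates$bins)
  width <- rates$bins$hi - rates$bins$lo + 1L
  adv <- 1 / width
  adv[k] <- 0
  s <- 1 - rates$d - rates$m
  L <- matrix(0, k, k, dimnames = list(rates$bins$label, rates$bins$label))
  diag(L) <- s * (1 - adv)
  if (k > 1L)
    for (i in seq_len(k - 1L)) L[i + 1L, i] <- s[i] * adv[i]
  L[1L, ] <- L[1L, ] + rates$b * rates$w
  L
}

#' One year of the age-group projection
#'
#' @param x numeric vector of group counts at year `t`.
#' @param rates a [leslie_rates()].
#' @param variant `"cohort"` (default): survivors advance towards older
#'   groups as in a standard Leslie matrix; `"printed"`: group membership
#'   stays fixed and each group is scaled by its survival-net-of-migration
#'   factor. Both add the projected newborns to the first group.
#' @param literal_eq1 audit switch for the printed variant: use the literal
#'   bracket `[1 + p - m]` with `p = 1 - d` (roughly doubles a population
#'   yearly; retained for scrutiny only).
#' @return numeric vector of group counts at year `t + 1`.
#' @export
leslie_step <- function(x, rates, variant = c("cohort", "printed"),
                        literal_eq1 = FALSE) {
  stopifnot(inherits(rates, "leslie_rates"))
  variant <- match.arg(variant)
  k <- nrow(rates$bins)
  if (length(x) != k)
    stop("`x` must have one count per age group", call. = FALSE)
  x <- as.numeric(x)
  births <- project_births(x, rates)
  if (variant == "printed") {
    fac <- if (literal_eq1) 1 + (1 - rates$d) - rates$m else
      1 - rates$d - rates$m
    xn <- x * fac
    xn[1L] <- xn[1L] + births
    return(xn)
  }
  width <- rates$bins$hi - rates$bins$lo + 1L
  adv <- 1 / width
  adv[k] <- 0
  surv <- x * (1 - rates$d - rates$m)
  xn <- surv * (1 - adv)
  if (k > 1L) xn[2:k] <- xn[2:k] + surv[seq_len(k - 1L)] * adv[seq_len(k - 1L)]
  xn[1L] <- xn[1L] + births
  xn
}

#' Multi-year age-group projection
#'
#' Iterates [leslie_step()] from a starting group vector.
#'
#' @param x starting group counts (or a `village_population`, binned with
#'   `rates$bins` via [leslie_state()]).
#' @param rates a [leslie_rates()].
#' @param n_steps number of projection years.
#' @param variant,literal_eq1 passed to [leslie_step()].
#' @return numeric matrix with `n_steps + 1` rows (year 0 first) and one
#'   column per age group.
#' @export
project_leslie <- function(x, rates, n_steps,
                           variant = c("cohort", "printed"),
                           literal_eq1 = FALSE) {
  variant <- match.arg(variant)
  if (inherits(x, "village_population")) x <- leslie_state(x, rates$bins)
  n_steps <- as.integer(n_steps)
  stopifnot(n_steps >= 0L)
  out <- matrix(NA_real_, n_steps + 1L, nrow(rates$bins),
                dimnames = list(0:n_steps, rates$bins$label))
  out[1L, ] <- as.numeric(x)
  for (k in seq_len(n_steps))
    out[k + 1L, ] <- leslie_step(out[k, ], rates, variant, literal_eq1)
  out
}

#' Resident group counts of a roster
#'
#' @param pop a `village_population`.
#' @param bins an [age_bins()] partition.
#' @return named numeric vector of resident counts per group.
#' @export
leslie_state <- function(pop, bins = report_bins()) {
  bin_totals(aggregate_to_bins(pop, bins))
}

#' Estimate per-group rates from two consecutive rosters
#'
#' Computes the empirical ratio estimates per age group at year `t`:
#' death rate `d_i` = deaths among group-`i` residents / group-`i`
#' residents; emigration rate `m_i` = emigrants in group `i` / group-`i`
#' residents; female share `w_i`. Rosters retain emigrated and dead agents,
#' so both transitions are read off the matched ids. Newborn counts (ids
#' present only in the later roster, age 0) are converted to a fertility
#' rate spread uniformly over the groups overlapping the fertility window,
#' because rosters carry no mother links and the per-group allocation of
#' births is not identifiable. Groups with no residents get rate 0 with a
#' warning.
#'
#' @param pop_t,pop_t1 `village_population` rosters for years `t` and
#'   `t + 1`; every person of `pop_t` must appear in `pop_t1`.
#' @param bins an [age_bins()] partition.
#' @param fertility_window integer `c(lo, hi)` ages of the fertile span
#'   used to allocate births (default 22--40).
#' @return a [leslie_rates()].
#' @export
fit_leslie_rates <- function(pop_t, pop_t1, bins = report_bins(),
                             fertility_window = c(22L, 40L)) {
  stopifnot(inherits(pop_t, "village_population"),
            inherits(pop_t1, "village_population"))
  res <- residents(pop_t)
  if (nrow(res) == 0L)
    stop("no residents in the year-t roster", call. = FALSE)
  k <- nrow(bins)
  g <- bin_of(res$age, bins)
  n_i <- tabulate(g, nbins = k)
  st1 <- pop_t1$persons$state[match(res$id, pop_t1$persons$id)]
  if (anyNA(st1))
    stop("rosters do not share ids: ",
         sum(is.na(st1)), " year-t resident(s) missing from the ",
         "year-t+1 roster", call. = FALSE)
  rate <- function(events) ifelse(n_i > 0L, tabulate(g[events], nbins = k) /
                                    pmax(n_i, 1L), 0)
  d_i <- rate(st1 == "dead")
  m_i <- rate(st1 == "emigrated")
  w_i <- rate(res$sex == "F")
  if (any(n_i == 0L))
    warning("empty age group(s), rates recorded as 0: ",
            paste(bins$label[n_i == 0L], collapse = ", "), call. = FALSE)

  newborn <- pop_t1$persons$age == 0L &
    !(pop_t1$persons$id %in% pop_t$persons$id)
  births <- sum(newborn)
  fw <- res$sex == "F" & res$age >= fertility_window[1L] &
    res$age <= fertility_window[2L]
  b_i <- numeric(k)
  if (births > 0L && sum(fw) > 0L) {
    overlap <- bins$hi >= fertility_window[1L] & bins$lo <= fertility_window[2L]
    b_i[overlap] <- births / sum(fw)
  }
  leslie_rates(bins, b = b_i, w = w_i, d = d_i, m = m_i)
}
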