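## Synthetic roster generation. Profiles carry the published village-level
## structure (total residents, youth/working/elderly shares, a near-balanced
## sex ratio, and a pyramid shape); the generator allocates residents across
## the three bands by a multinomial draw at the profile shares and spreads
## ages within bands by fixed per-5-year weights that emulate the two
## observed pyramid shapes. The weights are an artifact choice (the source
## pyramids exist only as figures) and are documented in the package
## vignette.

## per-5-year-bin weights within each structural band
.pyramid_weights <- list(
  "broad-base" = list(                       # wide base, bulge at 45-54
    youth   = c(1.2, 1.0, 0.9),              # 0-4, 5-9, 10-14
    working = c(1.0, 0.8, 0.7, 0.7, 0.8, 0.9, 1.4, 1.3, 1.0, 0.9),
    elderly = c(1.0, 0.8, 0.6, 0.4, 0.2, 0.08, 0.02)
  ),
  "narrow-base" = list(                      # thin base, mass above 55
    youth   = c(0.8, 1.0, 1.2),
    working = c(0.9, 0.9, 0.8, 0.7, 0.7, 0.8, 1.0, 1.2, 1.4, 1.6),
    elderly = c(1.3, 1.2, 1.0, 0.7, 0.4, 0.15, 0.05)
  )
)

#' Describe a village's population structure
#'
#' @param name village name.
#' @param total_residents resident head count (>= 0).
#' @param youth_share,working_share,elderly_share proportions of residents
#'   aged <=14, 15--64 and >=65; must lie in \[0, 1\] and sum to 1 (within
#'   1e-9).
#' @param male_share male share of residents (default 0.51, a slight male
#'   surplus typical of rural rosters).
#' @param pyramid `"broad-base"` (many children, working-age bulge at
#'   45--54) or `"narrow-base"` (few children, mass above 55).
#' @return an object of class `village_profile`.
#' @export
village_profile <- function(name, total_residents, youth_share,
                            working_share, elderly_share,
                            male_share = 0.51,
                            pyramid = c("broad-base", "narrow-base")) {
  pyramid <- match.arg(pyramid)
  total_residents <- as.integer(total_residents)
  shares <- c(youth_share, working_share, elderly_share)
  if (total_residents < 0L)
    stop("`total_residents` must be non-negative", call. = FALSE)
  if (any(shares < 0) || any(shares > 1) || male_share < 0 || male_share > 1)
    stop("shares must lie in [0, 1]", call. = FALSE)
  if (abs(sum(shares) - 1) > 1e-9)
    stop("youth + working + elderly shares must sum to 1", call. = FALSE)
  structure(list(name = as.character(name),
                 total_residents = total_residents,
                 youth_share = youth_share,
                 working_share = working_share,
                 elderly_share = elderly_share,
                 male_share = male_share,
                 pyramid = pyramid),
            class = "village_profile")
}

#' Profiles of the two study villages
#'
#' The published 2024 structure of the two villages: Yunfeng (1060
#' residents; 38.49% youth, 52.26% working-age, 9.25% elderly; broad-base
#' pyramid) and Shihan (1319 residents; 12.21% / 63.23% / 24.56%;
#' narrow-base pyramid).
#'
#' @return named list of two [village_profile()] objects (`yunfeng`,
#'   `shihan`).
#' @export
builtin_profiles <- function() {
  list(
    yunfeng = village_profile("Yunfeng", 1060L, 0.3849, 0.5226, 0.0925,
                              pyramid = "broad-base"),
    shihan = village_profile("Shihan", 1319L, 0.1221, 0.6323, 0.2456,
                             pyramid = "narrow-base"))
}

## sample `count` integer ages from 5-year bins at the given weights
.draw_band_ages <- function(count, bin_lo, bin_hi, weights) {
  if (count == 0L) return(integer(0L))
  bin <- sample.int(length(weights), count, replace = TRUE, prob = weights)
  lo <- bin_lo[bin]
  hi <- bin_hi[bin]
  as.integer(lo + floor(stats::runif(count) * (hi - lo + 1L)))
}

#' Generate a synthetic village roster
#'
#' Draws a roster with exactly `profile$total_residents` residents:
#' a multinomial allocation across the youth/working/elderly bands at the
#' profile shares, shape-specific 5-year age weights within bands, sex
#' drawn at the profile's male share, and marital status assigned
#' `married` with probability `marriage_prob` from `marriage_age` upward.
#' Reproducible for a given seed.
#'
#' @param profile a [village_profile()].
#' @param seed integer seed.
#' @param year calendar year label of the roster.
#' @param marriage_age age from which marital status may be `married`
#'   (default 25).
#' @param marriage_prob probability of being married at or above
#'   `marriage_age` (default 0.8).
#' @return a `village_population` of residents.
#' @examples
#' pop <- generate_roster(builtin_profiles()$shihan, seed = 7, year = 2024)
#' structure_proportions(pop)
#' @export
generate_roster <- function(profile, seed = 1L, year = NA_integer_,
                            marriage_age = 25L, marriage_prob = 0.8) {
  stopifnot(inherits(profile, "village_profile"),
            marriage_prob >= 0, marriage_prob <= 1)
  set.seed(as.integer(seed))
  n <- profile$total_residents
  shares <- c(profile$youth_share, profile$working_share,
              profile$elderly_share)
  nb <- if (n > 0L) as.vector(stats::rmultinom(1L, n, shares)) else
    c(0L, 0L, 0L)
  wts <- .pyramid_weights[[profile$pyramid]]
  ages <- c(
    .draw_band_ages(nb[1L], c(0L, 5L, 10L), c(4L, 9L, 14L), wts$youth),
    .draw_band_ages(nb[2L], seq(15L, 60L, 5L), seq(19L, 64L, 5L),
                    wts$working),
    .draw_band_ages(nb[3L], seq(65L, 95L, 5L),
                    c(seq(69L, 94L, 5L), 100L), wts$elderly))
  sex <- ifelse(stats::runif(n) < profile$male_share, "M", "F")
  marital <- ifelse(ages >= marriage_age &
                      stats::runif(n) < marriage_prob,
                    "married", "single")
  slug <- tolower(gsub("[^A-Za-z0-9]+", "_", profile$name))
  persons <- data.frame(id = sprintf("%s_%05d", slug, seq_len(n)),
                        age = ages,
                        sex = if (n > 0L) sex else character(0L),
                        marital_status = if (n > 0L) marital else
                          character(0L),
                        state = rep("resident", n),
                        stringsAsFactors = FALSE)
  village_population(persons, village = profile$name, year = year)
}
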