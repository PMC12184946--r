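## Verification workflow: pair simulated and observed age-bin counts,
## run the classical paired t-test on the differences, back it with a
## bootstrap robustness check, and compare sex structure.

#' Pair simulated and observed counts
#'
#' @param simulated,observed numeric vectors of equal length (typically
#'   age-bin counts for one or more villages, optionally including the
#'   total-population rows).
#' @param labels optional labels per pair.
#' @return an object of class `paired_comparison` with the element-wise
#'   `differences = simulated - observed`.
#' @export
paired_comparison <- function(simulated, observed, labels = NULL) {
  simulated <- as.numeric(simulated)
  observed <- as.numeric(observed)
  if (length(simulated) != length(observed))
    stop("`simulated` and `observed` must have equal length", call. = FALSE)
  if (anyNA(simulated) || anyNA(observed))
    stop("paired counts must not contain NA", call. = FALSE)
  if (is.null(labels)) labels <- sprintf("pair%d", seq_along(simulated))
  structure(list(labels = as.character(labels),
                 simulated = simulated,
                 observed = observed,
                 differences = simulated - observed),
            class = "paired_comparison")
}

.pair_diffs <- function(x) {
  if (inherits(x, "paired_comparison")) return(x$differences)
  if (is.numeric(x)) return(as.numeric(x))
  stop("expected a paired_comparison or a numeric difference vector",
       call. = FALSE)
}

#' Paired t-test on simulated-minus-observed differences
#'
#' Classical two-sided paired t-test: with `n` pairs and differences `d`,
#' `t = mean(d) / (sd(d)/sqrt(n))` on `n - 1` degrees of freedom, with the
#' 95% confidence interval `mean(d) +/- t_{0.975, n-1} sd(d)/sqrt(n)`.
#' Zero-variance differences are reported as an exact tie (t of infinite
#' magnitude when the common difference is non-zero; t = 0, p = 1 when the
#' vectors are identical).
#'
#' @param comparison a [paired_comparison()] or a numeric vector of
#'   differences (at least 2 pairs).
#' @param conf_level confidence level (default 0.95).
#' @return an object of class `paired_t_result` with fields `n`,
#'   `mean_diff`, `sd_diff`, `se_mean`, `ci_low`, `ci_high`, `t_statistic`,
#'   `df`, `p_two_tailed` and an optional `note`.
#' @export
paired_t_test <- function(comparison, conf_level = 0.95) {
  d <- .pair_diffs(comparison)
  n <- length(d)
  if (n < 2L)
    stop("paired t-test needs at least 2 pairs", call. = FALSE)
  m <- mean(d)
  s <- stats::sd(d)
  df <- n - 1L
  note <- NULL
  if (s == 0) {
    se <- 0
    if (m == 0) {
      tt <- 0; p <- 1
      note <- "exact tie: all differences are zero"
    } else {
      tt <- sign(m) * Inf; p <- 0
      note <- "exact tie: all differences identical and non-zero"
    }
    ci <- c(m, m)
  } else {
    se <- s / sqrt(n)
    tt <- m / se
    p <- 2 * stats::pt(-abs(tt), df)
    half <- stats::qt(1 - (1 - conf_level) / 2, df) * se
    ci <- c(m - half, m + half)
  }
  structure(list(n = n, mean_diff = m, sd_diff = s, se_mean = se,
                 ci_low = ci[1L], ci_high = ci[2L], t_statistic = tt,
                 df = df, p_two_tailed = p, conf_level = conf_level,
                 note = note),
            class = "paired_t_result")
}

#' @export
print.paired_t_result <- function(x, ...) {
  cat("Paired t-test (simulated - observed)\n")
  cat(sprintf("  n = %d, mean = %.3f, sd = %.3f, se = %.3f\n",
              x$n, x$mean_diff, x$sd_diff, x$se_mean))
  cat(sprintf("  %.0f%% CI (%.3f, %.3f); t = %.3f, df = %d, p = %.3f\n",
              100 * x$conf_level, x$ci_low, x$ci_high, x$t_statistic,
              x$df, x$p_two_tailed))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Bootstrap robustness check for the paired comparison
#'
#' Resamples the difference vector with replacement `n_boot` times and
#' summarises the bootstrap distribution of the mean: bias (mean of
#' bootstrap means minus the sample mean), standard error (sd of the
#' bootstrap means), a percentile confidence interval, and a two-sided
#' p-value from the shifted (null-centred) resampling distribution with the
#' usual (1 + #extreme)/(n_boot + 1) correction.
#'
#' @param comparison a [paired_comparison()] or numeric difference vector.
#' @param n_boot number of bootstrap resamples (>= 1; 1000 by convention).
#' @param seed optional integer seed for the resampling.
#' @param conf_level confidence level of the percentile interval.
#' @return an object of class `bootstrap_paired_result` with fields
#'   `mean_diff`, `bias`, `se`, `p_two_tailed`, `ci_low`, `ci_high`,
#'   `n_boot`, `seed`.
#' @export
bootstrap_paired <- function(comparison, n_boot = 1000L, seed = NULL,
                             conf_level = 0.95) {
  d <- .pair_diffs(comparison)
  n <- length(d)
  n_boot <- as.integer(n_boot)
  if (n < 1L || n_boot < 1L)
    stop("need at least one pair and n_boot >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  bm <- colMeans(matrix(d[idx], nrow = n))
  m <- mean(d)
  alpha <- 1 - conf_level
  ci <- stats::quantile(bm, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  centered <- bm - m                      # bootstrap null distribution
  p <- (1 + sum(abs(centered) >= abs(m))) / (n_boot + 1)
  structure(list(n = n, n_boot = n_boot, seed = seed,
                 mean_diff = m,
                 bias = mean(bm) - m,
                 se = stats::sd(bm),
                 p_two_tailed = p,
                 ci_low = ci[1L], ci_high = ci[2L],
                 conf_level = conf_level,
                 method = "percentile CI; shifted-resampling two-sided p"),
            class = "bootstrap_paired_result")
}

#' @export
print.bootstrap_paired_result <- function(x, ...) {
  cat(sprintf("Bootstrap check (%d resamples%s)\n", x$n_boot,
              if (is.null(x$seed)) "" else sprintf(", seed %d",
                                                   as.integer(x$seed))))
  cat(sprintf("  mean = %.3f, bias = %.3f, se = %.3f\n",
              x$mean_diff, x$bias, x$se))
  cat(sprintf("  %.0f%% percentile CI (%.3f, %.3f); two-sided p = %.3f\n",
              100 * x$conf_level, x$ci_low, x$ci_high, x$p_two_tailed))
  invisible(x)
}

#' Compare simulated and observed sex structure
#'
#' @param sim_pop,obs_pop non-empty `village_population` objects.
#' @return data frame with one row per sex: simulated share, observed
#'   share, signed and absolute difference.
#' @export
compare_sex_structure <- function(sim_pop, obs_pop) {
  s <- sex_ratio(sim_pop)
  o <- sex_ratio(obs_pop)
  data.frame(sex = c("male", "female"),
             simulated = unname(s),
             observed = unname(o),
             delta = unname(s - o),
             abs_delta = unname(abs(s - o)))
}
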