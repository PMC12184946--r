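## Simple base-graphics views: a back-to-back population pyramid and the
## age-structure share trends of a simulation.

#' Population pyramid of a roster
#'
#' Back-to-back horizontal bars of resident counts per age bin, males to
#' the left, females to the right.
#'
#' @param x a `village_population`.
#' @param bins an [age_bins()] partition (default [five_year_bins()]).
#' @param ... further arguments passed to [graphics::barplot()].
#' @return invisibly, the bins-by-sex count matrix.
#' @export
plot.village_population <- function(x, bins = five_year_bins(), ...) {
  tab <- aggregate_to_bins(x, bins)
  m <- tab$counts
  lim <- max(m, 1L)
  mids <- graphics::barplot(-m[, "M"], horiz = TRUE, xlim = c(-lim, lim),
                            col = "steelblue", border = NA, names.arg = "",
                            xlab = "residents", axes = FALSE,
                            main = sprintf("%s%s", x$village,
                                           ifelse(is.na(x$year), "",
                                                  sprintf(" (%d)", x$year))),
                            ...)
  graphics::barplot(m[, "F"], horiz = TRUE, add = TRUE, col = "indianred",
                    border = NA, names.arg = "", axes = FALSE)
  at <- pretty(c(0, lim))
  graphics::axis(1, at = c(-rev(at), at[-1L]),
                 labels = c(rev(at), at[-1L]))
  graphics::text(-lim, mids, labels = rownames(m), adj = 0, cex = 0.7)
  graphics::legend("topright", fill = c("steelblue", "indianred"),
                   legend = c("male", "female"), bty = "n")
  invisible(m)
}

#' Age-structure trends of a simulation
#'
#' Youth, working-age and elderly resident shares over the simulated
#' years.
#'
#' @param x a `sim_trajectory` or `sim_ensemble`.
#' @param ... further arguments passed to [graphics::matplot()].
#' @return invisibly, the [trajectory_structure()] data frame.
#' @export
plot.sim_trajectory <- function(x, ...) {
  ts <- trajectory_structure(x)
  graphics::matplot(ts$year, ts[, c("youth", "working", "elderly")],
                    type = "b", pch = 16, lty = 1,
                    col = c("seagreen", "steelblue", "indianred"),
                    xlab = "year", ylab = "share of residents", ...)
  graphics::legend("topleft", legend = c("youth (<=14)", "working (15-64)",
                                         "elderly (>=65)"),
                   col = c("seagreen", "steelblue", "indianred"),
                   pch = 16, lty = 1, bty = "n")
  invisible(ts)
}

#' @rdname plot.sim_trajectory
#' @export
plot.sim_ensemble <- plot.sim_trajectory
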