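# Derived headline statistics. All inputs are raw (unrounded) series;
# rounding happens only at display, half away from zero, matching the
# published tables' apparent convention: percentages and pound-billions to
# one decimal, pound-millions to the nearest million.

#' Headline summary statistics of a projection
#'
#' Computes the growth percentages, prevalences and cost change a
#' projection is usually summarised by. Growth is
#' `100 * (end - start) / start`; cost change is reported in pound
#' billions. All statistics are computed from the raw values and rounded
#' half-up only for display.
#'
#' @param pop_start,pop_end Total population at the horizon ends.
#' @param frail_start,frail_end Persons in any frailty state at the
#'   horizon ends.
#' @param cost_start_million,cost_end_million Optional annual cost (pound
#'   millions) at the horizon ends.
#' @return Object of class `summary_stats`: list with
#'   `population_growth_pct`, `frail_growth_pct`, `prevalence_start_pct`,
#'   `prevalence_end_pct` (1 dp), and, when costs are given,
#'   `cost_increase_billion` (1 dp).
#' @examples
#' summary_stats(23126258, 24021710, 16228687, 18269340)
#' @export
summary_stats <- function(pop_start, pop_end, frail_start, frail_end,
                          cost_start_million = NULL,
                          cost_end_million = NULL) {
  growth <- function(a, b) round_half_up(100 * (b - a) / a, 1)
  out <- list(
    population_growth_pct = growth(pop_start, pop_end),
    frail_growth_pct = growth(frail_start, frail_end),
    prevalence_start_pct = round_half_up(100 * frail_start / pop_start, 1),
    prevalence_end_pct = round_half_up(100 * frail_end / pop_end, 1))
  if (!is.null(cost_start_million) && !is.null(cost_end_million))
    out$cost_increase_billion <-
      round_half_up((cost_end_million - cost_start_million) / 1e3, 1)
  structure(out, class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat("<summary_stats>\n")
  cat(sprintf("population growth: %.1f%%\n", x$population_growth_pct))
  cat(sprintf("frail-count growth: %.1f%%\n", x$frail_growth_pct))
  cat(sprintf("frailty prevalence: %.1f%% -> %.1f%%\n",
              x$prevalence_start_pct, x$prevalence_end_pct))
  if (!is.null(x$cost_increase_billion))
    cat(sprintf("cost increase: %.1f pound bn\n", x$cost_increase_billion))
  invisible(x)
}

#' Summarise a projection bundle (and optional scenario comparisons)
#'
#' @param bundle A [run_pipeline()] baseline bundle.
#' @param comparisons Optional named list of [compare_projections()]
#'   reports; their cumulative savings (pound bn, 1 dp) and average annual
#'   savings (pound m, nearest million) are appended.
#' @return A `summary_stats` object with per-year prevalence (1 dp) under
#'   `prevalence_by_year` and a `scenario_savings` data frame when
#'   comparisons are supplied.
#' @export
summarize_projection <- function(bundle, comparisons = NULL) {
  ps <- prevalence_series(bundle$trajectory)
  n <- nrow(ps)
  costs <- bundle$costs
  cost_args <- if (!is.null(costs)) {
    tot <- costs$by_sector
    tot <- tot[tot$sector == "total", ]
    list(cost_start_million = tot$total[tot$year == ps$year[1]] / 1e6,
         cost_end_million = tot$total[tot$year == ps$year[n]] / 1e6)
  } else list(cost_start_million = NULL, cost_end_million = NULL)
  out <- summary_stats(ps$total_count[1], ps$total_count[n],
                       ps$frail_count[1], ps$frail_count[n],
                       cost_args$cost_start_million,
                       cost_args$cost_end_million)
  out$prevalence_by_year <- data.frame(
    year = ps$year,
    prevalence_pct = round_half_up(100 * ps$frail_fraction, 1))
  if (!is.null(comparisons)) {
    out$scenario_savings <- data.frame(
      scenario = names(comparisons),
      cumulative_saving_billion = vapply(comparisons, function(cm)
        round_half_up(cm$cumulative_saving / 1e9, 1), numeric(1)),
      average_annual_saving_million = vapply(comparisons, function(cm)
        round_half_up(cm$average_annual_saving / 1e6, 0), numeric(1)),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out
}
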