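# Containers for model inputs: annual rate parameters, stock vectors and
# entry schedules, with strict validation. All rates are annual per-capita
# probabilities of the corresponding flow.

#' Construct and validate a parameter set
#'
#' Bundles every annual rate governing the stock-and-flow update:
#'
#' * `transition` — per-capita rates of frailty progression, one per age
#'   band for each of the three stepwise moves fit->mild, mild->moderate
#'   and moderate->severe. Frailty never improves, so no reverse rates
#'   exist structurally.
#' * `mortality` — per-capita death rate for each of the 16 age x frailty
#'   strata.
#' * `ageing` — per-capita promotion rate from each non-terminal age band
#'   to the next. The default `1/width` (1/15, 1/10, 1/10) approximates a
#'   uniform age distribution within the band; the 85+ band has no ageing
#'   outflow.
#' * `entry_mix` — distribution over frailty states of people entering the
#'   model as they turn 50 (a probability simplex; frailty can already be
#'   present by the early 50s, so this is not forced to be all-fit).
#'
#' @param transition 4 x 3 numeric matrix, rows the age bands and columns
#'   `fit_mild`, `mild_moderate`, `moderate_severe`; all entries in
#'   \[0, 1\].
#' @param mortality 4 x 4 numeric matrix (age band x frailty state), all
#'   entries in \[0, 1\].
#' @param ageing Numeric vector of length 3 (promotion rates for the three
#'   non-terminal bands), in \[0, 1\].
#' @param entry_mix Numeric vector of length 4 over the frailty states,
#'   non-negative and summing to 1 (tolerance 1e-12).
#' @return An object of class `parameter_set`.
#' @seealso [step_population()], [run_projection()]
#' @export
parameter_set <- function(transition, mortality,
                          ageing = 1 / AGE_WIDTHS[1:3],
                          entry_mix = c(1, 0, 0, 0)) {
  transition <- as.matrix(transition)
  mortality <- as.matrix(mortality)
  ageing <- as.numeric(ageing)
  entry_mix <- as.numeric(entry_mix)
  errors <- character()
  if (!identical(dim(transition), c(4L, 3L)))
    errors <- c(errors, "transition must be a 4 x 3 matrix (band x type)")
  if (!identical(dim(mortality), c(4L, 4L)))
    errors <- c(errors, "mortality must be a 4 x 4 matrix (band x state)")
  if (length(ageing) != 3)
    errors <- c(errors, "ageing must have length 3 (non-terminal bands)")
  if (length(entry_mix) != 4)
    errors <- c(errors, "entry_mix must have length 4 (frailty states)")
  fail_all(errors, "parameter_set")
  errors <- check_finite(transition, "transition", errors)
  errors <- check_finite(mortality, "mortality", errors)
  errors <- check_finite(ageing, "ageing", errors)
  errors <- check_finite(entry_mix, "entry_mix", errors)
  fail_all(errors, "parameter_set")
  for (nm in c("transition", "mortality", "ageing")) {
    x <- get(nm)
    if (any(x < 0 | x > 1))
      errors <- c(errors, sprintf("%s rates must lie in [0, 1]", nm))
  }
  if (any(entry_mix < 0))
    errors <- c(errors, "entry_mix must be non-negative")
  if (abs(sum(entry_mix) - 1) > 1e-12)
    errors <- c(errors, sprintf(
      "entry_mix must sum to 1 (got %.15g)", sum(entry_mix)))
  fail_all(errors, "parameter_set")
  dimnames(transition) <- list(AGE_BANDS, TRANSITION_TYPES)
  dimnames(mortality) <- list(AGE_BANDS, FRAILTY_STATES)
  names(ageing) <- AGE_BANDS[1:3]
  names(entry_mix) <- FRAILTY_STATES
  structure(list(transition = transition, mortality = mortality,
                 ageing = ageing, entry_mix = entry_mix),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> annual per-capita rates\n")
  cat("transition (band x move):\n")
  print(round(x$transition, 4))
  cat("mortality (band x state):\n")
  print(round(x$mortality, 4))
  cat("ageing promotion:", paste(sprintf("%s=%.4g", names(x$ageing),
                                         x$ageing), collapse = ", "), "\n")
  cat("entry mix at 50: ", paste(sprintf("%s=%.4g", names(x$entry_mix),
                                         x$entry_mix), collapse = ", "), "\n")
  invisible(x)
}

#' Construct and validate a stock vector
#'
#' Person counts in the 16 age band x frailty state compartments at one
#' point in time.
#'
#' @param counts 4 x 4 numeric matrix (age band x frailty state) of
#'   non-negative, finite person counts, or a band-major named 16-vector
#'   as produced by [stratum_names()].
#' @param year Calendar year the counts refer to.
#' @return An object of class `stock_vector`: the validated 4 x 4 matrix
#'   with a `year` attribute.
#' @export
stock_vector <- function(counts, year) {
  if (is.null(dim(counts)) && length(counts) == 16)
    counts <- unflatten_stocks(as.numeric(counts))
  counts <- as.matrix(counts)
  errors <- character()
  if (!identical(dim(counts), c(4L, 4L)))
    errors <- c(errors, "counts must be a 4 x 4 matrix (band x state)")
  fail_all(errors, "stock_vector")
  errors <- check_finite(counts, "counts", errors)
  fail_all(errors, "stock_vector")
  if (any(counts < 0))
    errors <- c(errors, "stock counts must be non-negative")
  if (length(year) != 1 || !is.finite(year))
    errors <- c(errors, "year must be a single finite number")
  fail_all(errors, "stock_vector")
  dimnames(counts) <- list(AGE_BANDS, FRAILTY_STATES)
  structure(counts, year = as.integer(year), class = "stock_vector")
}

#' @export
print.stock_vector <- function(x, ...) {
  cat(sprintf("<stock_vector> year %d, total %.0f persons\n",
              attr(x, "year"), sum(x)))
  print(round(unclass(x)))
  invisible(x)
}

stock_year <- function(stocks) attr(stocks, "year")

#' Entry schedule of people turning 50
#'
#' @param years Calendar years covered.
#' @param entrants Non-negative persons turning 50 in each year (recycled
#'   if scalar).
#' @return Named numeric vector (names are years) of class
#'   `entry_schedule`.
#' @export
entry_schedule <- function(years, entrants) {
  entrants <- rep_len(as.numeric(entrants), length(years))
  errors <- character()
  errors <- check_finite(entrants, "entrants", errors)
  fail_all(errors, "entry_schedule")
  if (any(entrants < 0))
    fail_all("entrants must be non-negative", "entry_schedule")
  names(entrants) <- as.character(years)
  structure(entrants, class = "entry_schedule")
}

# look up the entrants for one year, erroring on a schedule gap
entrants_for <- function(entries, year) {
  v <- unclass(entries)[as.character(year)]
  if (is.na(v))
    stop(sprintf("entry schedule does not cover year %d", year),
         call. = FALSE)
  unname(v)
}
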