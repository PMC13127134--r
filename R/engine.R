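# Deterministic discrete-time stock-and-flow core. One step advances the 16
# compartments by one year: frailty progression (fit->mild->moderate->severe,
# never backwards), ageing promotion between bands, mortality, and entrants
# turning 50. All flows are computed simultaneously from start-of-year stocks
# (forward Euler, dt = 1 year); if the per-capita outflow rates of a stratum
# sum above 1 they are rescaled proportionally so stocks stay non-negative.

# effective (capped) per-cell outflow rates for a parameter set; the cap
# depends only on rates, never on stocks, so the annual update is affine
effective_rates <- function(params, ageing = NULL) {
  ageing <- ageing %||% params$ageing
  trans <- cbind(params$transition, severe = 0)  # band x state source rates
  age_rate <- matrix(c(ageing, 0), nrow = 4, ncol = 4)
  total <- params$mortality + trans + age_rate
  scale <- ifelse(total > 1, 1 / total, 1)
  list(mortality = params$mortality * scale, transition = trans * scale,
       ageing = age_rate * scale)
}

#' Advance the population by one year
#'
#' Computes all flows simultaneously from start-of-year stocks: deaths,
#' stepwise frailty transitions, ageing promotions; removes them; moves
#' transition flows one frailty state up and ageing flows one band up; then
#' adds the year's entrants to the 50-64 band, split across frailty states
#' by `entry_mix`. Outflow rates from any stratum that sum above 1 are
#' rescaled by the reciprocal of their sum, guaranteeing non-negative
#' stocks for any valid parameter set.
#'
#' @param stocks A [stock_vector()] (start-of-year counts).
#' @param params A [parameter_set()].
#' @param entrants_year Non-negative number of people turning 50 during the
#'   year.
#' @param ageing Optional length-3 override of the ageing promotion rates
#'   for this year (used to emulate year-specific counts of people turning
#'   65, 75 and 85).
#' @return A list with `stocks` (a `stock_vector` dated one year later) and
#'   `flows`, a flow record with elements `transitions` (band x move
#'   matrix, persons; the `fit_mild` column is the year's incident frailty),
#'   `deaths` (band x state), `ageing` (promotions out of the three
#'   non-terminal bands, band x state) and `entries` (persons per frailty
#'   state).
#' @export
step_population <- function(stocks, params, entrants_year, ageing = NULL) {
  if (!inherits(stocks, "stock_vector"))
    stop("stocks must be a stock_vector", call. = FALSE)
  if (!inherits(params, "parameter_set"))
    stop("params must be a parameter_set", call. = FALSE)
  if (length(entrants_year) != 1 || !is.finite(entrants_year) ||
      entrants_year < 0)
    stop("entrants_year must be a single non-negative number", call. = FALSE)
  s <- unclass(stocks)
  attr(s, "year") <- NULL
  if (any(!is.finite(s)) || any(s < 0))
    stop("stocks must be finite and non-negative", call. = FALSE)

  r <- effective_rates(params, ageing)
  deaths <- s * r$mortality
  trans <- s * r$transition          # outflow from each source state
  aged <- s * r$ageing               # promotion out of each band

  out <- s - deaths - trans - aged
  out[, 2:4] <- out[, 2:4] + trans[, 1:3]   # frailty moves one state up
  out[2:4, ] <- out[2:4, ] + aged[1:3, ]    # ageing moves one band up
  entries <- entrants_year * params$entry_mix
  out[1, ] <- out[1, ] + entries

  transitions <- trans[, 1:3, drop = FALSE]
  colnames(transitions) <- TRANSITION_TYPES
  flows <- list(transitions = transitions, deaths = deaths,
                ageing = aged[1:3, , drop = FALSE], entries = entries)
  list(stocks = stock_vector(out, stock_year(stocks) + 1L), flows = flows)
}

#' Build the affine one-year update map
#'
#' The annual update is affine in the stocks: `next = A s + n e`, where `A`
#' is a 16 x 16 rate matrix over the band-major strata, `n` the year's
#' entrants and `e` the entry-mix template. `A` is lower-triangular in the
#' frailty ordering within each band (no recovery) and its only off-band
#' entries sit on the ageing superdiagonal. Per-stratum outflow capping is
#' baked into `A` (the rescale factor depends only on rates), so iterating
#' this map reproduces [step_population()] exactly; the map serves as an
#' independent oracle for the step-by-step engine.
#'
#' @param params A [parameter_set()].
#' @return An object of class `affine_map`: list with `matrix` (16 x 16,
#'   dimnames [stratum_names()]) and `entry` (length-16 entry template
#'   summing to 1).
#' @export
build_affine_map <- function(params) {
  if (!inherits(params, "parameter_set"))
    stop("params must be a parameter_set", call. = FALSE)
  r <- effective_rates(params)
  idx <- function(a, s) (a - 1L) * 4L + s
  A <- matrix(0, 16, 16, dimnames = list(stratum_names(), stratum_names()))
  for (a in 1:4) for (s in 1:4) {
    k <- idx(a, s)
    A[k, k] <- 1 - r$mortality[a, s] - r$transition[a, s] - r$ageing[a, s]
    if (s < 4) A[idx(a, s + 1L), k] <- A[idx(a, s + 1L), k] + r$transition[a, s]
    if (a < 4) A[idx(a + 1L, s), k] <- A[idx(a + 1L, s), k] + r$ageing[a, s]
  }
  e <- numeric(16)
  e[idx(1L, 1:4)] <- params$entry_mix
  names(e) <- stratum_names()
  structure(list(matrix = A, entry = e), class = "affine_map")
}

#' Apply an affine update map
#'
#' @param map An `affine_map` from [build_affine_map()].
#' @param stocks A [stock_vector()].
#' @param entrants_year Persons turning 50 during the year.
#' @return A `stock_vector` one year later.
#' @export
apply_affine_map <- function(map, stocks, entrants_year) {
  v <- flatten_stocks(unclass(stocks))
  out <- as.vector(map$matrix %*% v) + entrants_year * map$entry
  stock_vector(unflatten_stocks(out), stock_year(stocks) + 1L)
}

#' Run a multi-year projection
#'
#' Applies [step_population()] iteratively from `start_year` to `end_year`.
#' Stocks are recorded for every year `start_year..end_year` inclusive;
#' flow records cover the year-steps `start_year..end_year - 1` (a
#' zero-length horizon returns the initial stocks only). The engine is
#' fully deterministic: identical inputs give bit-identical trajectories.
#'
#' @param initial A [stock_vector()] for `start_year`.
#' @param params A [parameter_set()].
#' @param entries An [entry_schedule()] covering every step year.
#' @param start_year,end_year Simulation horizon (calendar years,
#'   `end_year >= start_year`).
#' @param ageing_schedule Optional 3 x n matrix (columns = step years) of
#'   year-specific ageing promotion rates overriding `params$ageing`.
#' @return An object of class `frailty_trajectory`: list with `years`,
#'   `stocks` (4 x 4 x n array, band x state x year), and per-step flow
#'   arrays `transitions` (4 x 3 x n-1), `deaths` (4 x 4 x n-1), `ageing`
#'   (3 x 4 x n-1) and `entries` (4 x n-1, state x year).
#' @export
run_projection <- function(initial, params, entries, start_year, end_year,
                           ageing_schedule = NULL) {
  if (end_year < start_year)
    stop("end_year must not precede start_year", call. = FALSE)
  if (stock_year(initial) != start_year)
    stop("initial stocks must be dated start_year", call. = FALSE)
  years <- start_year:end_year
  n <- length(years)
  nstep <- n - 1L
  if (nstep > 0) {
    step_years <- years[seq_len(nstep)]
    missing <- setdiff(as.character(step_years), names(entries))
    if (length(missing))
      stop(sprintf("entry schedule missing years: %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    if (!is.null(ageing_schedule)) {
      ageing_schedule <- as.matrix(ageing_schedule)
      if (nrow(ageing_schedule) != 3 || ncol(ageing_schedule) < nstep)
        stop("ageing_schedule must be 3 x (number of step years)",
             call. = FALSE)
    }
  }
  stocks <- array(0, dim = c(4, 4, n),
                  dimnames = list(AGE_BANDS, FRAILTY_STATES, years))
  transitions <- array(0, dim = c(4, 3, max(nstep, 0)),
                       dimnames = list(AGE_BANDS, TRANSITION_TYPES,
                                       if (nstep) years[seq_len(nstep)]))
  deaths <- array(0, dim = c(4, 4, max(nstep, 0)),
                  dimnames = list(AGE_BANDS, FRAILTY_STATES,
                                  if (nstep) years[seq_len(nstep)]))
  ageing <- array(0, dim = c(3, 4, max(nstep, 0)),
                  dimnames = list(AGE_BANDS[1:3], FRAILTY_STATES,
                                  if (nstep) years[seq_len(nstep)]))
  entry_flows <- matrix(0, 4, max(nstep, 0),
                        dimnames = list(FRAILTY_STATES,
                                        if (nstep) years[seq_len(nstep)]))
  cur <- initial
  stocks[, , 1] <- unclass(initial)
  for (i in seq_len(nstep)) {
    yr <- years[i]
    st <- step_population(cur, params, entrants_for(entries, yr),
                          ageing = if (!is.null(ageing_schedule))
                            ageing_schedule[, i])
    cur <- st$stocks
    stocks[, , i + 1L] <- unclass(cur)
    transitions[, , i] <- st$flows$transitions
    deaths[, , i] <- st$flows$deaths
    ageing[, , i] <- st$flows$ageing
    entry_flows[, i] <- st$flows$entries
  }
  structure(list(years = years, stocks = stocks, transitions = transitions,
                 deaths = deaths, ageing = ageing, entries = entry_flows,
                 start_year = start_year, end_year = end_year),
            class = "frailty_trajectory")
}

#' @export
print.frailty_trajectory <- function(x, ...) {
  n <- length(x$years)
  cat(sprintf("<frailty_trajectory> %d-%d (%d years)\n",
              x$start_year, x$end_year, n))
  tot <- apply(x$stocks, 3, sum)
  cat(sprintf("total population: %.0f -> %.0f\n", tot[1], tot[n]))
  pv <- prevalence(trajectory_stocks(x, x$end_year))
  cat(sprintf("final frailty prevalence: %.1f%%\n", 100 * pv$frail_fraction))
  invisible(x)
}

#' Extract the stocks of one trajectory year
#'
#' @param traj A `frailty_trajectory`.
#' @param year A year inside the trajectory horizon.
#' @return A [stock_vector()].
#' @export
trajectory_stocks <- function(traj, year) {
  i <- match(year, traj$years)
  if (is.na(i)) stop(sprintf("year %d not in trajectory", year),
                     call. = FALSE)
  stock_vector(traj$stocks[, , i], year)
}

#' Annual incident frailty cases
#'
#' New cases of frailty per year and age band, counted as the fit->mild
#' flow (the model's stepwise transitions mean one annual step cannot skip
#' a state, so all incident frailty enters through the mild category).
#'
#' @param traj A `frailty_trajectory` with at least one year-step.
#' @param totals Append a `Total` row of column sums (default `TRUE`).
#' @return A data frame with columns `year` (character; last row
#'   `"Total"` when `totals`), the four age bands and `Overall` (row sum).
#' @export
annual_incidence <- function(traj, totals = TRUE) {
  nstep <- length(traj$years) - 1L
  if (nstep < 1L)
    stop("trajectory has no year-steps: no incidence to report",
         call. = FALSE)
  inc <- t(traj$transitions[, "fit_mild", , drop = TRUE])
  if (nstep == 1L) inc <- matrix(inc, nrow = 1,
                                 dimnames = list(NULL, AGE_BANDS))
  out <- data.frame(year = as.character(traj$years[seq_len(nstep)]),
                    inc, Overall = rowSums(inc),
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (totals) {
    tot <- c(year = "Total", as.list(colSums(out[, -1, drop = FALSE])))
    out <- rbind(out, as.data.frame(tot, check.names = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Frailty prevalence of a stock vector
#'
#' @param stocks A [stock_vector()].
#' @return List with `frail_count` (persons in mild, moderate or severe
#'   frailty, all bands), `total_count`, and `frail_fraction` in \[0, 1\]
#'   (`NaN`, with a warning, for an empty population — never a silent
#'   zero).
#' @export
prevalence <- function(stocks) {
  if (!inherits(stocks, "stock_vector"))
    stop("stocks must be a stock_vector", call. = FALSE)
  s <- unclass(stocks)
  frail <- sum(s[, c("mild", "moderate", "severe")])
  total <- sum(s)
  frac <- if (total == 0) {
    warning("prevalence undefined: total population is zero", call. = FALSE)
    NaN
  } else frail / total
  list(frail_count = frail, total_count = total, frail_fraction = frac)
}

#' Per-year prevalence series of a trajectory
#'
#' @param traj A `frailty_trajectory`.
#' @return Data frame with columns `year`, `frail_count`,
#'   `moderate_severe_count`, `total_count`, `frail_fraction`.
#' @export
prevalence_series <- function(traj) {
  frail <- apply(traj$stocks[, c("mild", "moderate", "severe"), ,
                             drop = FALSE], 3, sum)
  modsev <- apply(traj$stocks[, c("moderate", "severe"), , drop = FALSE],
                  3, sum)
  total <- apply(traj$stocks, 3, sum)
  data.frame(year = traj$years, frail_count = frail,
             moderate_severe_count = modsev, total_count = total,
             frail_fraction = frail / total)
}

#' Tidy export of a trajectory
#'
#' One row per (year, age band, frailty state) with the start-of-year stock
#' and the year's flows out of / into the stratum. The final horizon year
#' carries stocks only (`NA` flows).
#'
#' @param x A `frailty_trajectory`.
#' @param ... Unused.
#' @return A data frame with columns `year`, `age_band`, `frailty_state`,
#'   `stock`, `deaths`, `transition_out`, `transition_in`, `ageing_out`,
#'   `ageing_in`, `entries`.
#' @export
as.data.frame.frailty_trajectory <- function(x, ...) {
  n <- length(x$years)
  grid <- expand.grid(frailty_state = FRAILTY_STATES, age_band = AGE_BANDS,
                      year = x$years, stringsAsFactors = FALSE)
  grid <- grid[, c("year", "age_band", "frailty_state")]
  a <- match(grid$age_band, AGE_BANDS)
  s <- match(grid$frailty_state, FRAILTY_STATES)
  t_i <- match(grid$year, x$years)
  grid$stock <- x$stocks[cbind(a, s, t_i)]
  flow <- function(arr, ai, si, ti) {
    v <- rep(NA_real_, nrow(grid))
    ok <- ti <= n - 1L & !is.na(ai) & !is.na(si)
    v[ok] <- arr[cbind(ai[ok], si[ok], ti[ok])]
    v
  }
  grid$deaths <- flow(x$deaths, a, s, t_i)
  # transition out exists for fit/mild/moderate; in for mild/moderate/severe
  grid$transition_out <- flow(x$transitions, a, ifelse(s <= 3, s, NA), t_i)
  grid$transition_out[s == 4 & t_i <= n - 1L] <- 0
  grid$transition_in <- flow(x$transitions, a, ifelse(s >= 2, s - 1L, NA),
                             t_i)
  grid$transition_in[s == 1 & t_i <= n - 1L] <- 0
  grid$ageing_out <- flow(x$ageing, ifelse(a <= 3, a, NA), s, t_i)
  grid$ageing_out[a == 4 & t_i <= n - 1L] <- 0
  grid$ageing_in <- flow(x$ageing, ifelse(a >= 2, a - 1L, NA), s, t_i)
  grid$ageing_in[a == 1 & t_i <= n - 1L] <- 0
  ent <- rep(NA_real_, nrow(grid))
  ok1 <- a == 1 & t_i <= n - 1L
  ent[ok1] <- x$entries[cbind(s[ok1], t_i[ok1])]
  ent[a > 1 & t_i <= n - 1L] <- 0
  grid$entries <- ent
  grid
}
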