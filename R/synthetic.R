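# Seeded synthetic-data machinery: parameter sets, initial populations and
# engine-generated truth trajectories, so calibration and every downstream
# stage can be tested without any external data. Default magnitudes are
# chosen to produce prevalence plateaus in the mid-70s percent, so synthetic
# runs resemble the regime of the England projections; they are
# illustrative, not estimates.

#' Configuration for the synthetic-data generator
#'
#' All draws are uniform within the configured `[lo, hi]` ranges; a
#' degenerate range `[x, x]` yields exactly `x`. The same seed and
#' configuration always reproduce byte-identical artifacts.
#'
#' @param seed Integer RNG seed.
#' @param transition_range 2-column matrix (lo, hi) with 3 rows, one per
#'   transition type; annual rates.
#' @param mortality_range 4 x 2 matrix of (lo, hi) per age band; the drawn
#'   band level is scaled by `mortality_gradient` across frailty states.
#' @param mortality_gradient Length-4 multipliers (fit..severe) applied to
#'   the band mortality level, capped at 1.
#' @param age_gradient If `TRUE` (default), transition and mortality draws
#'   are sorted non-decreasing across age bands.
#' @param entry_mix_mean Simplex centre of the entry mix at age 50.
#' @param entry_mix_concentration Dirichlet-style concentration; larger
#'   means draws closer to the centre.
#' @param total_population Initial persons aged 50+.
#' @param band_shares Length-4 simplex of initial band populations.
#' @param frail_shares Length-4 within-band initial frail fractions.
#' @param frail_split Length-3 simplex splitting frail mass over
#'   mild/moderate/severe.
#' @param entrants_per_year People turning 50 each year (scalar).
#' @param service_rate_base 9 x 2 matrix (lo, hi) of annual contacts per
#'   FIT person per category; frail states are scaled up by
#'   `service_frailty_gradient`.
#' @param service_frailty_gradient Length-4 multipliers across frailty
#'   states.
#' @param unit_cost_range 9 x 2 matrix (lo, hi) of pounds per contact.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(
    seed = 1L,
    transition_range = cbind(lo = c(0.05, 0.06, 0.05),
                             hi = c(0.12, 0.14, 0.12)),
    mortality_range = cbind(lo = c(0.002, 0.008, 0.02, 0.08),
                            hi = c(0.008, 0.025, 0.06, 0.2)),
    mortality_gradient = c(0.7, 1, 1.5, 2.2),
    age_gradient = TRUE,
    entry_mix_mean = c(0.5, 0.35, 0.1, 0.05),
    entry_mix_concentration = 200,
    total_population = 1e6,
    band_shares = c(0.47, 0.25, 0.20, 0.08),
    frail_shares = c(0.55, 0.72, 0.85, 0.93),
    frail_split = c(0.5, 0.3, 0.2),
    entrants_per_year = 3e4,
    service_rate_base = cbind(lo = c(2, 0.02, 1, 0.2, 0.8, 0.1, 0.08,
                                     0.05, 0.002),
                              hi = c(4, 0.1, 2, 0.6, 1.6, 0.3, 0.2,
                                     0.2, 0.01)),
    service_frailty_gradient = c(1, 1.8, 2.8, 4),
    unit_cost_range = cbind(lo = c(30, 80, 12, 8, 100, 130, 2500, 1800,
                                   1200),
                            hi = c(45, 120, 20, 14, 160, 200, 4500, 3200,
                                   2200))) {
  cfg <- list(seed = as.integer(seed), transition_range = transition_range,
              mortality_range = mortality_range,
              mortality_gradient = mortality_gradient,
              age_gradient = age_gradient, entry_mix_mean = entry_mix_mean,
              entry_mix_concentration = entry_mix_concentration,
              total_population = total_population,
              band_shares = band_shares, frail_shares = frail_shares,
              frail_split = frail_split,
              entrants_per_year = entrants_per_year,
              service_rate_base = service_rate_base,
              service_frailty_gradient = service_frailty_gradient,
              unit_cost_range = unit_cost_range)
  errors <- character()
  rng_ok <- function(r, lo_min = 0, hi_max = 1)
    all(is.finite(r)) && all(r[, 1] <= r[, 2]) && all(r[, 1] >= lo_min) &&
      all(r[, 2] <= hi_max)
  if (!rng_ok(transition_range))
    errors <- c(errors, "transition_range must satisfy 0 <= lo <= hi <= 1")
  if (!rng_ok(mortality_range))
    errors <- c(errors, "mortality_range must satisfy 0 <= lo <= hi <= 1")
  if (!rng_ok(service_rate_base, hi_max = Inf))
    errors <- c(errors, "service_rate_base must satisfy 0 <= lo <= hi")
  if (!rng_ok(unit_cost_range, hi_max = Inf))
    errors <- c(errors, "unit_cost_range must satisfy 0 <= lo <= hi")
  if (abs(sum(band_shares) - 1) > 1e-9 || any(band_shares < 0))
    errors <- c(errors, "band_shares must be a simplex")
  if (abs(sum(frail_split) - 1) > 1e-9 || any(frail_split < 0))
    errors <- c(errors, "frail_split must be a simplex")
  if (any(frail_shares < 0 | frail_shares > 1))
    errors <- c(errors, "frail_shares must lie in [0, 1]")
  if (total_population < 0)
    errors <- c(errors, "total_population must be non-negative")
  fail_all(errors, "generator_config")
  structure(cfg, class = "generator_config")
}

runif_range <- function(n, lo, hi) lo + (hi - lo) * stats::runif(n)

#' Draw a random parameter set
#'
#' Transition and mortality rates are uniform within the configured
#' ranges; with `age_gradient` the four band draws of each rate are sorted
#' so rates never decrease with age. The entry mix is a Dirichlet-style
#' draw (normalised gamma variates) around the configured centre.
#'
#' @param cfg A [generator_config()].
#' @return A [parameter_set()].
#' @export
gen_parameter_set <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed, {
    transition <- sapply(1:3, function(j) {
      v <- runif_range(4, cfg$transition_range[j, 1],
                       cfg$transition_range[j, 2])
      if (cfg$age_gradient) sort(v) else v
    })
    level <- runif_range(4, cfg$mortality_range[, 1],
                         cfg$mortality_range[, 2])
    if (cfg$age_gradient) level <- sort(level)
    mortality <- pmin(outer(level, cfg$mortality_gradient), 1)
    a <- cfg$entry_mix_concentration * cfg$entry_mix_mean
    g <- stats::rgamma(4, shape = pmax(a, 1e-8))
    entry_mix <- g / sum(g)
    parameter_set(transition, mortality, entry_mix = entry_mix)
  })
}

#' Build initial stocks from a generator configuration
#'
#' Deterministic given the configuration: `stocks = total x band share x
#' within-band frailty mix` (no random draw is involved).
#'
#' @param cfg A [generator_config()].
#' @param year Calendar year of the initial stocks.
#' @return A [stock_vector()] summing to `total_population` within 1e-9.
#' @export
gen_initial_stocks <- function(cfg, year = 2025) {
  stopifnot(inherits(cfg, "generator_config"))
  m <- matrix(0, 4, 4)
  for (b in 1:4) {
    tot <- cfg$total_population * cfg$band_shares[b]
    phi <- cfg$frail_shares[b]
    m[b, ] <- c(tot * (1 - phi), tot * phi * cfg$frail_split)
  }
  stock_vector(m, year)
}

#' Draw random service rates and unit costs
#'
#' @param cfg A [generator_config()].
#' @return A [service_rate_set()].
#' @export
gen_service_rates <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed + 1L, {
    base <- runif_range(9, cfg$service_rate_base[, 1],
                        cfg$service_rate_base[, 2])
    r <- array(0, dim = c(4, 4, 9))
    for (k in 1:9)
      r[, , k] <- outer(rep(1, 4), cfg$service_frailty_gradient) * base[k]
    service_rate_set(r)
  })
}

#' @rdname gen_service_rates
#' @return `gen_unit_costs`: a [unit_cost_set()].
#' @export
gen_unit_costs <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  with_seed(cfg$seed + 2L, {
    unit_cost_set(runif_range(9, cfg$unit_cost_range[, 1],
                              cfg$unit_cost_range[, 2]))
  })
}

#' Generate a synthetic truth for recovery tests
#'
#' Draws a parameter set, runs the real engine on it over the horizon, and
#' overlays contacts and costs; returns both the generating truth and the
#' observables, so calibration tests can check that the truth parameters
#' are recovered and that the loss at truth is zero.
#'
#' @param cfg A [generator_config()].
#' @param start_year,end_year Horizon (defaults 2025-2041, giving 16 flow
#'   years).
#' @return List with `params` (the truth [parameter_set()]), `initial`,
#'   `entries`, `trajectory`, `contacts`, `costs`, `rates`, `unit_costs`.
#' @export
make_truth <- function(cfg, start_year = 2025, end_year = 2041) {
  params <- gen_parameter_set(cfg)
  initial <- gen_initial_stocks(cfg, start_year)
  entries <- entry_schedule(start_year:(end_year - 1),
                            cfg$entrants_per_year)
  rates <- gen_service_rates(cfg)
  unit_costs <- gen_unit_costs(cfg)
  traj <- run_projection(initial, params, entries, start_year, end_year)
  contacts <- project_contacts(traj, rates)
  costs <- project_costs(contacts, unit_costs)
  list(params = params, initial = initial, entries = entries,
       trajectory = traj, contacts = contacts, costs = costs,
       rates = rates, unit_costs = unit_costs)
}

#' A parameter-recovery calibration problem from a synthetic truth
#'
#' Frees the 12 frailty transition rates, fixes everything else at truth,
#' and targets the truth per-stratum stocks in every simulated year —
#' noiseless engine-generated targets whose loss at the truth parameters
#' is exactly zero.
#'
#' @param truth A [make_truth()] result.
#' @param start_factor Multiplier perturbing the truth transitions to form
#'   the starting point (clipped to bounds).
#' @return List with `problem` (a [calibration_problem()]) and `truth_theta`
#'   (the generating transition rates, in free-parameter order).
#' @export
recovery_problem <- function(truth, start_factor = 0.5) {
  grid <- expand.grid(band = AGE_BANDS, type = TRANSITION_TYPES,
                      stringsAsFactors = FALSE)
  nm <- sprintf("transition[%s,%s]", grid$band, grid$type)
  truth_theta <- truth$params$transition[cbind(grid$band, grid$type)]
  start <- pmin(pmax(truth_theta * start_factor, 1e-4), 0.5)
  free <- free_parameters(nm, lower = 0, upper = 0.5, start = start)
  traj <- truth$trajectory
  tg <- expand.grid(year = traj$years, band = AGE_BANDS,
                    state = FRAILTY_STATES, stringsAsFactors = FALSE)
  tg$value <- traj$stocks[cbind(match(tg$band, AGE_BANDS),
                                match(tg$state, FRAILTY_STATES),
                                match(tg$year, traj$years))]
  problem <- calibration_problem(
    base_params = truth$params, initial = truth$initial,
    entries = truth$entries, start_year = traj$start_year,
    end_year = traj$end_year, free = free,
    targets = list(target_stock(tg)))
  list(problem = problem, truth_theta = stats::setNames(truth_theta, nm))
}
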