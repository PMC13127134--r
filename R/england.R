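# A re-runnable England 2025-2040 baseline. The underlying transition,
# mortality and entry rates behind the published projections are not
# printed (they come from a multistate model fitted to primary-care
# records), so the packaged baseline recovers them by calibrating the
# engine against the published targets: the annual incidence table (16
# years x 4 bands) plus the printed 2025/2040 frail counts and the 2040
# population total. The initial 16-stock composition and the entry
# schedule are equally unpublished; band population shares are fixed at an
# ONS-flavoured assumption and the within-band frailty composition,
# entrant level/trend and ageing rates are freed alongside the rates.
# Matching is to a tolerance: the recovered rates are a calibration, not
# the unpublished estimates.

ENGLAND_BAND_SHARES <- c(0.470, 0.253, 0.192, 0.085)

#' The packaged England calibration problem
#'
#' Free parameters (with box bounds): the 12 frailty transition rates, the
#' 16 stratum mortality rates, the 4 entry-mix weights, the 3 ageing
#' promotion rates, the initial within-band frail shares and frail-split
#' shape, and the entrant level and annual trend. Targets: every annual
#' incidence cell of the published projection (2025-2040 by age band),
#' weight 1, and the printed 2025/2040 frail counts, 2040 population
#' total and 2040 moderate+severe baseline count, weight 400 (so the four
#' headline counts carry as much weight as the 64 incidence cells
#' combined and are matched essentially exactly). The simulation horizon
#' runs one year past 2040 so the 2040 incidence flow exists.
#'
#' @param total_2025 Initial population aged 50+ (defaults to the printed
#'   2025 total).
#' @return A [calibration_problem()].
#' @export
england_problem <- function(total_2025 = NULL) {
  fx <- load_fixture_tables()
  if (is.null(total_2025)) total_2025 <- unname(fx$scalars["population_2025"])
  band_totals <- total_2025 * ENGLAND_BAND_SHARES

  free <- rbind(
    free_parameters(sprintf("transition[%s,fit_mild]", AGE_BANDS),
                    0.001, 0.5, c(0.08, 0.07, 0.06, 0.05)),
    free_parameters(sprintf("transition[%s,mild_moderate]", AGE_BANDS),
                    0.001, 0.5, 0.09),
    free_parameters(sprintf("transition[%s,moderate_severe]", AGE_BANDS),
                    0.001, 0.5, 0.08),
    free_parameters(
      sprintf("mortality[%s,%s]",
              rep(AGE_BANDS, 4), rep(FRAILTY_STATES, each = 4)),
      0, 0.6,
      as.vector(pmin(outer(c(0.004, 0.012, 0.035, 0.12),
                           c(0.7, 1, 1.4, 2)), 0.5))),
    free_parameters(sprintf("entry_mix[%s]", FRAILTY_STATES),
                    0.001, 1, c(0.5, 0.35, 0.1, 0.05)),
    free_parameters(sprintf("init_frail_share[%s]", AGE_BANDS),
                    0.2, 0.99, c(0.55, 0.72, 0.85, 0.93)),
    free_parameters(c("init_frail_shape[moderate]",
                      "init_frail_shape[severe]"),
                    0.01, 2, c(0.6, 0.35)),
    free_parameters(sprintf("ageing[%s]", AGE_BANDS[1:3]),
                    0.02, 0.2, c(1 / 15, 1 / 10, 1 / 10)),
    free_parameters("entry_level", 3e5, 1.5e6, 7e5),
    free_parameters("entry_growth", -0.05, 0.05, 0),
    # year-resolved ageing promotion rates: the published model aged the
    # population with ONS year-specific counts of people turning 65, 75
    # and 85, so cohort waves show up in the incidence series; a
    # ridge-penalised per-year schedule around each band's base rate lets
    # the fit express them
    free_parameters(sprintf("ageing_wave[%s,%d]",
                            rep(AGE_BANDS[1:3], each = 16),
                            rep(2025:2040, 3)),
                    0.02, 0.25,
                    rep(c(1 / 15, 1 / 10, 1 / 10), each = 16)))

  inc <- fx$incidence
  inc <- inc[inc$year != "Total" & inc$band != "Overall", ]
  inc_target <- data.frame(year = as.integer(inc$year), band = inc$band,
                           value = inc$new_cases)
  frail_target <- data.frame(
    year = c(2025, 2040),
    value = unname(fx$scalars[c("frail_2025", "frail_2040")]))
  pop_target <- data.frame(year = 2040,
                           value = unname(fx$scalars["population_2040"]))
  modsev_target <- data.frame(
    year = 2040,
    value = unname(fx$scalars["scenario_b_modsev_2040_baseline"]))

  # placeholder base inputs; every consequential entry is freed above
  base_params <- parameter_set(
    transition = matrix(0.05, 4, 3),
    mortality = matrix(0.05, 4, 4),
    entry_mix = c(1, 0, 0, 0))
  initial <- stock_vector(matrix(band_totals / 4, 4, 4), 2025)
  entries <- entry_schedule(2025:2040, 7e5)

  calibration_problem(
    base_params = base_params, initial = initial, entries = entries,
    start_year = 2025, end_year = 2041, free = free,
    targets = list(target_incidence(inc_target, weight = 1),
                   target_frail_count(frail_target, weight = 400),
                   target_total_pop(pop_target, weight = 400),
                   target_modsev_count(modsev_target, weight = 400)),
    band_totals = band_totals, ridge_weight = 0.0025)
}

#' Calibrate the England baseline
#'
#' Runs the bounded least-squares fit of [england_problem()]. The result
#' carries the fitted, directly re-runnable engine inputs (`params`,
#' `initial`, `entries`).
#'
#' @param maxiter Maximum Levenberg-Marquardt iterations.
#' @return A `calibration_result`.
#' @export
calibrate_england <- function(maxiter = 400) {
  calibrate(england_problem(), maxiter = maxiter, ftol = 1e-8,
            ptol = 1e-8)
}

#' Calibrate aggregate service rates to published contact/cost tables
#'
#' The per-stratum contact rates and unit costs behind the published
#' service tables are not printed. For scenario accounting the package
#' recovers a coarse surrogate. For each sector the fit-group rate is a
#' least-squares slope of the published fit contact series on the fit
#' population; the frail-group rates follow a severity gradient
#' `level * gamma^(s-1)` over mild/moderate/severe, with `level` and
#' `gamma` fitted to the published frail contact series given the
#' trajectory's state composition (the published series grows faster than
#' the frail count because the frail population shifts to severer states,
#' which identifies the gradient). Sector-average cost per contact comes
#' Contacts are attributed to categories within each sector by fixed
#' shares; the unplanned-admission share of secondary & urgent contacts
#' is itself calibrated from the published scenario result that a 2.5%
#' yearly reduction in unplanned admissions avoids 2.48 million
#' admissions over the horizon (the only published quantity that
#' identifies the split). Unit costs per category start from
#' representative 2016/17 reference-cost magnitudes (a GP appointment
#' tens of pounds, an admission thousands) and are rescaled within each
#' sector so that the sector-average cost per contact reproduces the
#' published 2025 cost/contact ratio.
#'
#' @param traj A calibrated England `frailty_trajectory` covering
#'   2025-2040.
#' @param unplanned_share Share of secondary & urgent contacts that are
#'   unplanned admissions; `NULL` (default) calibrates it from the
#'   published scenario C admission count.
#' @return List with `rates` (a [service_rate_set()]), `unit_costs` (a
#'   [unit_cost_set()]), `group_rates` (the fitted per-person sector
#'   rates), `frail_gamma` (fitted severity gradients) and
#'   `unplanned_share`.
#' @export
calibrate_service_rates <- function(traj, unplanned_share = NULL) {
  fx <- load_fixture_tables()
  ps <- prevalence_series(traj)
  yrs <- 2025:2040
  fit_pop <- (ps$total_count - ps$frail_count)[match(yrs, ps$year)]
  frail_pop <- ps$frail_count[match(yrs, ps$year)]
  con <- fx$contacts
  obs_series <- function(sec, grp) {
    sel <- con$sector == sec & con$group == grp
    1e6 * con$contacts_millions[sel][match(yrs, con$year[sel])]
  }
  # per-state frail populations over the horizon
  state_pop <- sapply(c("mild", "moderate", "severe"), function(st)
    apply(traj$stocks[, st, , drop = FALSE], 3, sum)[match(yrs, traj$years)])
  group_rates <- list()
  frail_gamma <- c(primary = NA_real_, secondary_urgent = NA_real_)
  for (sec in c("primary", "secondary_urgent")) {
    obs_fit <- obs_series(sec, "fit")
    group_rates[[paste(sec, "fit", sep = ".")]] <-
      sum(obs_fit * fit_pop) / sum(fit_pop^2)  # slope through origin
    obs_frail <- obs_series(sec, "frail")
    sse <- function(gamma) {
      eff <- state_pop %*% gamma^(0:2)   # gradient-weighted frail persons
      level <- sum(obs_frail * eff) / sum(eff^2)
      sum((level * eff - obs_frail)^2)
    }
    gamma <- stats::optimize(sse, c(1, 6))$minimum
    eff <- state_pop %*% gamma^(0:2)
    level <- sum(obs_frail * eff) / sum(eff^2)
    group_rates[[paste(sec, "mild", sep = ".")]] <- level
    group_rates[[paste(sec, "moderate", sep = ".")]] <- level * gamma
    group_rates[[paste(sec, "severe", sep = ".")]] <- level * gamma^2
    frail_gamma[sec] <- gamma
  }
  # attribute sector rates to categories by fixed shares
  if (is.null(unplanned_share)) {
    # share s solves: 0.025 * s * (total secondary contacts over the
    # horizon) = published admissions avoided under the 2.5% reduction
    sec_tot <- sum(con$contacts_millions[con$sector == "secondary_urgent" &
                                           con$group == "total"])
    unplanned_share <- unname(
      fx$scalars["scenario_c_unplanned_admissions_avoided_million"] /
        (0.025 * sec_tot))
  }
  primary_shares <- c(gp_face_to_face = 0.55, gp_home_visit = 0.05,
                      gp_telephone = 0.3, gp_econsult = 0.1)
  # keep the calibrated unplanned share exact; the remaining categories
  # split the rest of the sector in fixed proportion
  other <- c(outpatient = 0.6, ed_attendance = 0.13,
             elective_admission = 0.04, critical_care = 0.03)
  other <- other * (1 - unplanned_share) / sum(other)
  secondary_shares <- c(other[c("outpatient", "ed_attendance",
                                "elective_admission")],
                        unplanned_admission = unname(unplanned_share),
                        critical_care = unname(other["critical_care"]))
  r <- array(0, dim = c(4, 4, 9))
  for (k in seq_len(9)) {
    cat_name <- SERVICE_CATEGORY_TABLE$category[k]
    sec <- SERVICE_CATEGORY_TABLE$sector[k]
    share <- if (sec == "primary") primary_shares[[cat_name]]
             else secondary_shares[[cat_name]]
    r[, 1, k] <- group_rates[[paste(sec, "fit", sep = ".")]] * share
    for (s in 2:4)
      r[, s, k] <- group_rates[[paste(sec, FRAILTY_STATES[s],
                                      sep = ".")]] * share
  }
  rates <- service_rate_set(r)
  # unit costs: representative 2016/17 reference-cost magnitudes,
  # rescaled within each sector so the share-weighted mean reproduces
  # the published 2025 cost per contact
  ref_costs <- c(gp_face_to_face = 38, gp_home_visit = 95,
                 gp_telephone = 15, gp_econsult = 10,
                 outpatient = 120, ed_attendance = 160,
                 elective_admission = 3750, unplanned_admission = 1600,
                 critical_care = 1900)
  cost25 <- fx$costs[fx$costs$year == 2025 & fx$costs$group == "total", ]
  con25 <- con[con$year == 2025 & con$group == "total", ]
  cpc <- function(sec)
    cost25$cost_millions[cost25$sector == sec] /
      con25$contacts_millions[con25$sector == sec]
  shares_of <- function(sec)
    if (sec == "primary") primary_shares else secondary_shares
  uc <- numeric(9)
  for (sec in c("primary", "secondary_urgent")) {
    ks <- which(SERVICE_CATEGORY_TABLE$sector == sec)
    sh <- shares_of(sec)[SERVICE_CATEGORY_TABLE$category[ks]]
    scale <- cpc(sec) / sum(sh * ref_costs[ks])
    uc[ks] <- ref_costs[ks] * scale
  }
  list(rates = rates, unit_costs = unit_cost_set(uc),
       group_rates = unlist(group_rates), frail_gamma = frail_gamma,
       unplanned_share = unplanned_share)
}
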