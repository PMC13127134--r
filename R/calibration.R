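# Calibration: recover unpublished rate parameters by fitting the engine's
# observable outputs (annual incidence, frail counts, population totals,
# per-stratum stocks) to target series. The loss is a weighted sum of
# squared RELATIVE residuals so person-count targets (millions) and cost
# targets can be mixed without manual rescaling. Optimisation is bounded
# Levenberg-Marquardt (minpack.lm::nls.lm) on the residual vector:
# deterministic given the starting point, and bound-feasible throughout.

#' Declare the free parameters of a calibration problem
#'
#' Free parameters are addressed by name:
#' * `transition[<band>,<type>]` e.g. `transition[50-64,fit_mild]`
#' * `mortality[<band>,<state>]`
#' * `ageing[<band>]` (non-terminal bands)
#' * `entry_mix[<state>]` — raw weights, renormalised to the simplex after
#'   every proposal (so the entry mix stays a distribution while each
#'   weight respects its box bounds)
#' * `init_frail_share[<band>]` — fraction of the band's initial
#'   population that is frail (requires `band_totals` in the problem)
#' * `init_frail_shape[moderate]`, `init_frail_shape[severe]` — initial
#'   frail split weights relative to mild = 1
#' * `entry_level`, `entry_growth` — entrants per year
#'   `level * (1 + growth)^(year - start)`
#' * `ageing_wave[<band>,<year>]` — year-specific ageing promotion rate
#'   override for one step year
#'
#' @param name Character vector of parameter names.
#' @param lower,upper Box bounds (recycled); rates must satisfy
#'   `0 <= lower <= upper <= 1`.
#' @param start Starting values (recycled), inside the bounds.
#' @return Data frame with columns `name`, `lower`, `upper`, `start`.
#' @export
free_parameters <- function(name, lower, upper, start) {
  out <- data.frame(name = name, lower = rep_len(lower, length(name)),
                    upper = rep_len(upper, length(name)),
                    start = rep_len(start, length(name)),
                    stringsAsFactors = FALSE)
  rate_like <- grepl("^(transition|mortality|ageing|entry_mix|init_frail_share|ageing_wave)\\[",
                     out$name)
  bad <- out$lower > out$upper | (rate_like & (out$lower < 0 | out$upper > 1))
  if (any(bad))
    stop(sprintf("invalid bounds for: %s",
                 paste(out$name[bad], collapse = ", ")), call. = FALSE)
  if (any(out$start < out$lower | out$start > out$upper))
    stop("starting values must lie inside the bounds", call. = FALSE)
  out
}

# --- target constructors ----------------------------------------------------

target_series <- function(type, data, weight) {
  stopifnot(is.data.frame(data), "value" %in% names(data))
  list(type = type, data = data, weight = weight)
}

#' Calibration targets
#'
#' Each target names an observable series the pipeline can emit, with the
#' values to match and a weight. Residuals are relative:
#' `(simulated - value) / max(|value|, 1e-8)`, scaled by `sqrt(weight)`.
#'
#' @param data Data frame with a `value` column plus the identifying
#'   columns of the observable: `year` + `band` for incidence (flow during
#'   that year), `year` + `band` + `state` for stocks, `year` alone for
#'   frail counts, moderate+severe counts and total population.
#' @param weight Positive weight applied to every row.
#' @return A target object for [calibration_problem()].
#' @name calibration-targets
NULL

#' @rdname calibration-targets
#' @export
target_incidence <- function(data, weight = 1)
  target_series("incidence", data, weight)

#' @rdname calibration-targets
#' @export
target_stock <- function(data, weight = 1)
  target_series("stock", data, weight)

#' @rdname calibration-targets
#' @export
target_frail_count <- function(data, weight = 1)
  target_series("frail_count", data, weight)

#' @rdname calibration-targets
#' @export
target_modsev_count <- function(data, weight = 1)
  target_series("modsev_count", data, weight)

#' @rdname calibration-targets
#' @export
target_total_pop <- function(data, weight = 1)
  target_series("total_pop", data, weight)

#' Assemble a calibration problem
#'
#' @param base_params A [parameter_set()] supplying every non-free
#'   parameter.
#' @param initial A [stock_vector()] (overridden in part when
#'   `init_frail_share` parameters are free).
#' @param entries An [entry_schedule()] (overridden when `entry_level` /
#'   `entry_growth` are free).
#' @param start_year,end_year Simulation horizon; flow targets may
#'   reference years up to `end_year - 1`.
#' @param free A [free_parameters()] frame (may have zero rows).
#' @param targets List of target objects (see [calibration-targets]); at
#'   least as many target rows as free parameters.
#' @param band_totals Optional length-4 initial band populations, required
#'   by `init_frail_share` parameters.
#' @param init_frail_shape Length-2 default mild-relative weights for
#'   moderate and severe used when `init_frail_share` is free but the
#'   shape is not.
#' @param ridge_weight Weight of the ridge penalty pulling each free
#'   `ageing_wave[...]` rate toward its band's base ageing rate (one
#'   penalty residual per wave parameter; 0 disables). Keeps a
#'   year-resolved ageing schedule identifiable without forcing it flat.
#' @return Object of class `calibration_problem`.
#' @export
calibration_problem <- function(base_params, initial, entries, start_year,
                                end_year, free, targets,
                                band_totals = NULL,
                                init_frail_shape = c(moderate = 0.6,
                                                     severe = 0.35),
                                ridge_weight = 0) {
  npts <- sum(vapply(targets, function(t) nrow(t$data), integer(1)))
  if (ridge_weight > 0)
    npts <- npts + sum(grepl("^ageing_wave\\[", free$name))
  if (npts < nrow(free))
    stop("fewer weighted target points than free parameters", call. = FALSE)
  structure(list(base_params = base_params, initial = initial,
                 entries = entries, start_year = start_year,
                 end_year = end_year, free = free, targets = targets,
                 band_totals = band_totals,
                 init_frail_shape = init_frail_shape,
                 ridge_weight = ridge_weight),
            class = "calibration_problem")
}

# parse "family[key1,key2]" names once
parse_free_names <- function(names) {
  m <- regmatches(names, regexec("^([a-z_]+)(?:\\[([^]]*)\\])?$", names))
  lapply(m, function(g) {
    if (length(g) < 2 || g[2] == "")
      stop(sprintf("unparseable free-parameter name"), call. = FALSE)
    keys <- if (length(g) >= 3 && nzchar(g[3]))
      strsplit(g[3], ",", fixed = TRUE)[[1]] else character()
    list(family = g[2], keys = keys)
  })
}

# materialise full engine inputs from a free-parameter vector
build_inputs <- function(problem, theta) {
  p <- problem$base_params
  transition <- p$transition
  mortality <- p$mortality
  ageing <- p$ageing
  entry_mix <- p$entry_mix
  initial <- unclass(problem$initial)
  attr(initial, "year") <- NULL
  entries <- problem$entries
  shape <- problem$init_frail_shape
  frail_share <- NULL
  entry_level <- NULL
  entry_growth <- 0
  ageing_wave <- list()

  entry_mix_touched <- FALSE
  parsed <- parse_free_names(problem$free$name)
  for (i in seq_along(theta)) {
    fam <- parsed[[i]]$family
    keys <- parsed[[i]]$keys
    val <- theta[i]
    switch(fam,
      transition = {
        transition[keys[1], keys[2]] <- val
      },
      mortality = {
        mortality[keys[1], keys[2]] <- val
      },
      ageing = {
        ageing[keys[1]] <- val
      },
      entry_mix = {
        entry_mix[keys[1]] <- val
        entry_mix_touched <- TRUE
      },
      init_frail_share = {
        if (is.null(frail_share)) {
          frail_share <- stats::setNames(rep(NA_real_, 4), AGE_BANDS)
        }
        frail_share[keys[1]] <- val
      },
      init_frail_shape = {
        shape[keys[1]] <- val
      },
      entry_level = {
        entry_level <- val
      },
      entry_growth = {
        entry_growth <- val
      },
      ageing_wave = {
        ageing_wave[[paste(keys, collapse = ",")]] <- val
      },
      stop(sprintf("unknown free-parameter family '%s'", fam),
           call. = FALSE)
    )
  }
  if (entry_mix_touched) entry_mix <- entry_mix / sum(entry_mix)
  if (!is.null(frail_share)) {
    if (is.null(problem$band_totals))
      stop("init_frail_share parameters require band_totals", call. = FALSE)
    w <- c(mild = 1, shape[c("moderate", "severe")])
    w <- w / sum(w)
    for (b in seq_along(AGE_BANDS)) {
      phi <- frail_share[b]
      if (is.na(phi)) {
        tot_b <- sum(initial[b, ])
        phi <- if (tot_b > 0)
          sum(initial[b, 2:4]) / tot_b else 0
      }
      tot <- problem$band_totals[b]
      initial[b, ] <- c(tot * (1 - phi), tot * phi * w)
    }
  }
  if (!is.null(entry_level)) {
    yrs <- problem$start_year:(problem$end_year - 1)
    entries <- entry_schedule(yrs,
                              entry_level * (1 + entry_growth)^(yrs - yrs[1]))
  }
  ageing_schedule <- NULL
  ridge_resid <- numeric(0)
  if (length(ageing_wave)) {
    nstep <- problem$end_year - problem$start_year
    ageing_schedule <- matrix(ageing, nrow = 3, ncol = nstep)
    ridge_resid <- numeric(length(ageing_wave))
    for (j in seq_along(ageing_wave)) {
      key <- names(ageing_wave)[j]
      parts <- strsplit(key, ",", fixed = TRUE)[[1]]
      band_i <- match(parts[1], AGE_BANDS[1:3])
      yr_i <- as.integer(parts[2]) - problem$start_year + 1L
      ageing_schedule[band_i, yr_i] <- ageing_wave[[key]]
      ridge_resid[j] <- (ageing_wave[[key]] - ageing[band_i]) /
        max(ageing[band_i], 1e-8)
    }
  }
  list(params = parameter_set(transition, mortality, ageing, entry_mix),
       initial = stock_vector(initial, problem$start_year),
       entries = entries, ageing_schedule = ageing_schedule,
       ridge_resid = ridge_resid)
}

# extract one target's simulated series from a trajectory
extract_observable <- function(traj, target) {
  d <- target$data
  switch(target$type,
    incidence = {
      yi <- match(d$year, traj$years)
      bi <- match(d$band, AGE_BANDS)
      traj$transitions[cbind(bi, 1L, yi)]
    },
    stock = {
      yi <- match(d$year, traj$years)
      traj$stocks[cbind(match(d$band, AGE_BANDS),
                        match(d$state, FRAILTY_STATES), yi)]
    },
    frail_count = {
      ps <- prevalence_series(traj)
      ps$frail_count[match(d$year, ps$year)]
    },
    modsev_count = {
      ps <- prevalence_series(traj)
      ps$moderate_severe_count[match(d$year, ps$year)]
    },
    total_pop = {
      ps <- prevalence_series(traj)
      ps$total_count[match(d$year, ps$year)]
    },
    stop(sprintf("unknown target type '%s'", target$type), call. = FALSE)
  )
}

# weighted relative residual vector at theta
calibration_residuals <- function(problem, theta) {
  inp <- build_inputs(problem, theta)
  traj <- run_projection(inp$initial, inp$params, inp$entries,
                         problem$start_year, problem$end_year,
                         inp$ageing_schedule)
  res <- lapply(problem$targets, function(tg) {
    sim <- extract_observable(traj, tg)
    if (anyNA(sim))
      stop("target references a year/stratum outside the simulation",
           call. = FALSE)
    obs <- tg$data$value
    sqrt(tg$weight) * (sim - obs) / pmax(abs(obs), 1e-8)
  })
  out <- unlist(res, use.names = FALSE)
  if ((problem$ridge_weight %||% 0) > 0 && length(inp$ridge_resid))
    out <- c(out, sqrt(problem$ridge_weight) * inp$ridge_resid)
  out
}

#' Evaluate the calibration loss
#'
#' Weighted sum of squared relative residuals over all targets.
#'
#' @param problem A [calibration_problem()].
#' @param theta Free-parameter vector (defaults to the starting point).
#' @return Non-negative scalar loss.
#' @export
calibration_loss <- function(problem, theta = problem$free$start) {
  sum(calibration_residuals(problem, theta)^2)
}

#' Calibrate free parameters against target series
#'
#' Bounded Levenberg-Marquardt least squares on the weighted relative
#' residual vector. Deterministic given the starting point; fitted values
#' never leave their declared bounds. The result always reports the
#' convergence status — a non-converged fit is flagged with a warning,
#' never returned silently — and near-flat (unidentifiable) directions of
#' the loss surface are detected from the curvature at the solution and
#' reported rather than masked.
#'
#' @param problem A [calibration_problem()].
#' @param start Optional alternative starting vector (defaults to
#'   `problem$free$start`).
#' @param maxiter Maximum LM iterations.
#' @param ftol,ptol Relative convergence tolerances on the loss and the
#'   parameters (see [minpack.lm::nls.lm.control()]).
#' @return Object of class `calibration_result`: list with `fitted` (named
#'   vector), `loss`, `residuals` (per-target-row data frame with `type`,
#'   identifiers, `observed`, `simulated`, `rel_residual`), `converged`,
#'   `message`, `start`, `flat_directions` (per-parameter relative
#'   curvature, with a `flat` flag), `params` / `initial` / `entries` /
#'   `ageing_schedule` (the fitted engine inputs, directly re-runnable;
#'   the schedule is `NULL` unless `ageing_wave` parameters were freed).
#' @export
calibrate <- function(problem, start = NULL, maxiter = 200,
                      ftol = 1e-12, ptol = 1e-12) {
  free <- problem$free
  if (nrow(free) == 0) {
    theta <- numeric(0)
    loss <- calibration_loss(problem, theta)
    inp <- build_inputs(problem, theta)
    return(structure(list(fitted = stats::setNames(numeric(0), character(0)),
                          loss = loss, residuals = residual_table(problem,
                                                                  theta),
                          converged = TRUE,
                          message = "no free parameters; loss evaluated",
                          start = theta, flat_directions = NULL,
                          params = inp$params, initial = inp$initial,
                          entries = inp$entries,
                          ageing_schedule = inp$ageing_schedule),
                     class = "calibration_result"))
  }
  theta0 <- start %||% free$start
  theta0 <- pmin(pmax(theta0, free$lower), free$upper)
  fit <- minpack.lm::nls.lm(
    par = theta0,
    lower = free$lower, upper = free$upper,
    fn = function(th) calibration_residuals(problem, th),
    control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                         maxfev = 10000 * (nrow(free) + 1),
                                         ftol = ftol, ptol = ptol))
  theta <- pmin(pmax(fit$par, free$lower), free$upper)
  names(theta) <- free$name
  converged <- fit$info %in% 1:4
  if (!converged)
    warning(sprintf("calibration did not converge: %s", fit$message),
            call. = FALSE)
  loss <- sum(calibration_residuals(problem, theta)^2)
  # identifiability diagnostic: diagonal curvature of J'J rescaled by
  # theta^2, i.e. the loss response to a relative change in each
  # parameter; a direction the targets cannot see has ~zero curvature
  curv <- diag(fit$hessian) * pmax(abs(theta), 1e-6)^2
  flat <- data.frame(name = free$name, relative_curvature = curv,
                     flat = curv < 1e-9 * (1 + loss),
                     stringsAsFactors = FALSE)
  if (any(flat$flat))
    warning(sprintf("flat (unidentifiable) directions: %s",
                    paste(flat$name[flat$flat], collapse = ", ")),
            call. = FALSE)
  inp <- build_inputs(problem, theta)
  structure(list(fitted = theta, loss = loss,
                 residuals = residual_table(problem, theta),
                 converged = converged, message = fit$message,
                 start = stats::setNames(theta0, free$name),
                 flat_directions = flat,
                 params = inp$params, initial = inp$initial,
                 entries = inp$entries,
                 ageing_schedule = inp$ageing_schedule),
            class = "calibration_result")
}

# per-row residual report
residual_table <- function(problem, theta) {
  inp <- build_inputs(problem, theta)
  traj <- run_projection(inp$initial, inp$params, inp$entries,
                         problem$start_year, problem$end_year,
                         inp$ageing_schedule)
  parts <- lapply(problem$targets, function(tg) {
    sim <- extract_observable(traj, tg)
    d <- tg$data
    id_cols <- setdiff(names(d), "value")
    out <- data.frame(type = rep(tg$type, nrow(d)),
                      stringsAsFactors = FALSE)
    for (cc in id_cols) out[[cc]] <- d[[cc]]
    out$observed <- d$value
    out$simulated <- sim
    out$rel_residual <- (sim - d$value) / pmax(abs(d$value), 1e-8)
    out
  })
  all_cols <- unique(unlist(lapply(parts, names)))
  parts <- lapply(parts, function(p) {
    for (cc in setdiff(all_cols, names(p))) p[[cc]] <- NA
    p[all_cols]
  })
  do.call(rbind, parts)
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration_result> %d free parameters, loss %.6g (%s)\n",
              length(x$fitted), x$loss,
              if (x$converged) "converged" else "NOT converged"))
  if (length(x$fitted)) {
    worst <- x$residuals[which.max(abs(x$residuals$rel_residual)), ]
    cat(sprintf("max |relative residual|: %.3g%% (%s)\n",
                100 * abs(worst$rel_residual), worst$type))
  }
  invisible(x)
}
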