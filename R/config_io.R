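# Structured plain-text configuration (YAML) for every model input, with a
# versioned schema and validation that reports every failing field at once,
# plus atomic output writing with a run manifest.

CONFIG_SCHEMA_VERSION <- 1L

#' Read and validate a run configuration
#'
#' The YAML schema (version 1) has a required `schema_version` field and
#' sections:
#'
#' ```yaml
#' schema_version: 1
#' parameters:
#'   transition:  {"50-64": {fit_mild: 0.08, mild_moderate: ..., ...}, ...}
#'   mortality:   {"50-64": {fit: 0.004, mild: ..., ...}, ...}
#'   ageing:      {"50-64": 0.0667, "65-74": 0.1, "75-84": 0.1}
#'   entry_mix:   {fit: 0.5, mild: 0.35, moderate: 0.1, severe: 0.05}
#' initial_stocks:
#'   year: 2025
#'   counts: {"50-64": {fit: ..., ...}, ...}
#' entries: {start_year: 2025, entrants: [700000, ...]}
#' service_rates:         # optional
#'   gp_face_to_face: {"50-64": {fit: 2.1, ...}, ...}
#' unit_costs:            # optional
#'   base_year: "2016/17"
#'   inflation_rate: 0.035
#'   costs: {gp_face_to_face: 37.4, ...}
#' ```
#'
#' Validation collects every missing or malformed field and reports them
#' all in one error.
#'
#' @param path Path to a YAML configuration file.
#' @return List with `params` ([parameter_set()]), `initial`
#'   ([stock_vector()]), `entries` ([entry_schedule()]) and, when present,
#'   `rates` ([service_rate_set()]) and `unit_costs` ([unit_cost_set()]).
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  errors <- character()
  if (is.null(cfg$schema_version))
    errors <- c(errors, "schema_version: missing")
  else if (cfg$schema_version != CONFIG_SCHEMA_VERSION)
    errors <- c(errors, sprintf("schema_version: expected %d, got %s",
                                CONFIG_SCHEMA_VERSION, cfg$schema_version))
  need_num <- function(section, keys1, keys2 = NULL, what) {
    # pull a grid of numbers out of nested lists, recording missing fields
    if (is.null(keys2)) {
      out <- vapply(keys1, function(k1) {
        v <- section[[k1]]
        if (is.null(v) || !is.numeric(v)) {
          errors <<- c(errors, sprintf("%s.%s: missing or non-numeric",
                                       what, k1))
          NA_real_
        } else as.numeric(v)
      }, numeric(1))
      return(out)
    }
    out <- matrix(NA_real_, length(keys1), length(keys2),
                  dimnames = list(keys1, keys2))
    for (k1 in keys1) for (k2 in keys2) {
      v <- section[[k1]][[k2]]
      if (is.null(v) || !is.numeric(v))
        errors <<- c(errors, sprintf("%s.%s.%s: missing or non-numeric",
                                     what, k1, k2))
      else out[k1, k2] <- as.numeric(v)
    }
    out
  }
  p <- cfg$parameters
  if (is.null(p)) {
    errors <- c(errors, "parameters: missing section")
    transition <- mortality <- NULL
  } else {
    transition <- need_num(p$transition, AGE_BANDS, TRANSITION_TYPES,
                           "parameters.transition")
    mortality <- need_num(p$mortality, AGE_BANDS, FRAILTY_STATES,
                          "parameters.mortality")
    ageing <- need_num(p$ageing, AGE_BANDS[1:3], what = "parameters.ageing")
    entry_mix <- need_num(p$entry_mix, FRAILTY_STATES,
                          what = "parameters.entry_mix")
  }
  ist <- cfg$initial_stocks
  if (is.null(ist) || is.null(ist$year) || is.null(ist$counts)) {
    errors <- c(errors, "initial_stocks: missing year or counts")
  } else {
    counts <- need_num(ist$counts, AGE_BANDS, FRAILTY_STATES,
                       "initial_stocks.counts")
  }
  ent <- cfg$entries
  if (is.null(ent) || is.null(ent$start_year) || is.null(ent$entrants))
    errors <- c(errors, "entries: missing start_year or entrants")
  fail_all(errors, sprintf("config '%s'", path))

  out <- list(
    params = parameter_set(transition, mortality, ageing, entry_mix),
    initial = stock_vector(counts, ist$year),
    entries = entry_schedule(
      ent$start_year + seq_along(ent$entrants) - 1L,
      as.numeric(ent$entrants)))
  if (!is.null(cfg$service_rates)) {
    r <- array(NA_real_, dim = c(4, 4, 9))
    for (k in seq_len(9)) {
      cat_name <- SERVICE_CATEGORY_TABLE$category[k]
      r[, , k] <- need_num(cfg$service_rates[[cat_name]], AGE_BANDS,
                           FRAILTY_STATES,
                           sprintf("service_rates.%s", cat_name))
    }
    fail_all(errors, sprintf("config '%s'", path))
    out$rates <- service_rate_set(r)
  }
  if (!is.null(cfg$unit_costs)) {
    uc <- need_num(cfg$unit_costs$costs, SERVICE_CATEGORY_TABLE$category,
                   what = "unit_costs.costs")
    fail_all(errors, sprintf("config '%s'", path))
    out$unit_costs <- unit_cost_set(
      uc, base_year = cfg$unit_costs$base_year %||% "2016/17",
      inflation_rate = cfg$unit_costs$inflation_rate %||% 0.035)
  }
  out
}

#' Write a run configuration
#'
#' Inverse of [read_config()]: a write/read round trip is lossless.
#'
#' @param inputs List with `params`, `initial`, `entries` and optionally
#'   `rates`, `unit_costs` (the [read_config()] layout).
#' @param path Destination YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(inputs, path) {
  nest <- function(m) {
    # matrix -> named nested list, preserving full precision
    out <- lapply(rownames(m), function(r)
      as.list(stats::setNames(m[r, ], colnames(m))))
    stats::setNames(out, rownames(m))
  }
  p <- inputs$params
  cfg <- list(
    schema_version = CONFIG_SCHEMA_VERSION,
    parameters = list(
      transition = nest(p$transition),
      mortality = nest(p$mortality),
      ageing = as.list(p$ageing),
      entry_mix = as.list(p$entry_mix)),
    initial_stocks = list(
      year = stock_year(inputs$initial),
      counts = nest(unclass(inputs$initial))),
    entries = list(
      start_year = as.integer(names(inputs$entries)[1]),
      entrants = as.numeric(unclass(inputs$entries))))
  if (!is.null(inputs$rates)) {
    r <- unclass(inputs$rates)
    cfg$service_rates <- stats::setNames(
      lapply(seq_len(9), function(k) nest(r[, , k])),
      SERVICE_CATEGORY_TABLE$category)
  }
  if (!is.null(inputs$unit_costs)) {
    uc <- inputs$unit_costs
    cfg$unit_costs <- list(base_year = uc$base_year,
                           inflation_rate = uc$inflation_rate,
                           costs = as.list(uc$costs))
  }
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Write pipeline outputs with a run manifest
#'
#' Writes the tidy trajectory, the sector-level contact and cost series
#' (raw units and display-rounded millions), a JSON summary and a manifest
#' (input hashes, package version, timestamp). Files are written to
#' temporary names and renamed into place, so a crashed run never leaves
#' a truncated output.
#'
#' @param bundle A [run_pipeline()] bundle.
#' @param dir Output directory (created if needed).
#' @param config_path Optional path of the config that produced the run,
#'   hashed into the manifest.
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(bundle, dir, config_path = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  atomically <- function(write_fn, file) {
    tmp <- paste0(file, ".tmp")
    write_fn(tmp)
    file.rename(tmp, file)
    file
  }
  written <- character()
  written <- c(written, atomically(function(f)
    utils::write.csv(as.data.frame(bundle$trajectory), f,
                     row.names = FALSE),
    file.path(dir, "trajectory.csv")))
  round_m <- function(df) {
    df$fit_millions <- round_half_up(df$fit / 1e6, 1)
    df$frail_millions <- round_half_up(df$frail / 1e6, 1)
    df$total_millions <- round_half_up(df$total / 1e6, 1)
    df
  }
  if (!is.null(bundle$contacts))
    written <- c(written, atomically(function(f)
      utils::write.csv(round_m(bundle$contacts$by_sector), f,
                       row.names = FALSE),
      file.path(dir, "contacts.csv")))
  if (!is.null(bundle$costs))
    written <- c(written, atomically(function(f)
      utils::write.csv(round_m(bundle$costs$by_sector), f,
                       row.names = FALSE),
      file.path(dir, "costs.csv")))
  summ <- summarize_projection(bundle)
  written <- c(written, atomically(function(f)
    jsonlite::write_json(unclass(summ), f, auto_unbox = TRUE, digits = NA),
    file.path(dir, "summary.json")))
  manifest <- list(
    package = "frailtydyn",
    version = as.character(utils::packageVersion("frailtydyn")),
    scenario = bundle$scenario,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config_md5 = if (!is.null(config_path))
      unname(tools::md5sum(config_path)) else NULL)
  written <- c(written, atomically(function(f)
    jsonlite::write_json(manifest, f, auto_unbox = TRUE),
    file.path(dir, "manifest.json")))
  invisible(written)
}
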