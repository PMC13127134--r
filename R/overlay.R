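# Service-use and cost overlay. Annual contact rates per person are applied
# to the prevalent stocks of each year; unit costs per contact are applied
# to contacts. Outputs are split fit vs frail (mild+moderate+severe) and
# primary vs secondary & urgent care, mirroring the projection tables.
# Costs are reported in constant base-year (2016/17) pounds: the inflation
# operation exists only to harmonise unit costs quoted in other base years.

#' Annual service-use rates per person
#'
#' @param rates 4 x 4 x 9 numeric array (age band x frailty state x
#'   service category, categories ordered as [service_categories()]):
#'   expected annual contacts per person, all finite and non-negative.
#' @return Object of class `service_rate_set`.
#' @export
service_rate_set <- function(rates) {
  rates <- as.array(rates)
  errors <- character()
  if (!identical(dim(rates), c(4L, 4L, 9L)))
    errors <- c(errors,
                "rates must be a 4 x 4 x 9 array (band x state x category)")
  fail_all(errors, "service_rate_set")
  errors <- check_finite(rates, "rates", errors)
  fail_all(errors, "service_rate_set")
  if (any(rates < 0))
    fail_all("service rates must be non-negative", "service_rate_set")
  dimnames(rates) <- list(AGE_BANDS, FRAILTY_STATES,
                          SERVICE_CATEGORY_TABLE$category)
  structure(rates, class = "service_rate_set")
}

#' Unit costs per service contact
#'
#' @param costs Named numeric vector of cost per contact in pounds, one
#'   entry per service category (order/names as [service_categories()]).
#' @param base_year Label of the price base (default `"2016/17"`, the NHS
#'   reference-cost base used throughout).
#' @param inflation_rate Annual inflation used when re-basing costs quoted
#'   in other years; 0.035 by default.
#' @return Object of class `unit_cost_set`.
#' @export
unit_cost_set <- function(costs, base_year = "2016/17",
                          inflation_rate = 0.035) {
  costs <- as.numeric(costs)
  errors <- character()
  if (length(costs) != 9)
    errors <- c(errors, "costs must have one entry per service category (9)")
  fail_all(errors, "unit_cost_set")
  errors <- check_finite(costs, "costs", errors)
  fail_all(errors, "unit_cost_set")
  if (any(costs < 0))
    fail_all("unit costs must be non-negative", "unit_cost_set")
  names(costs) <- SERVICE_CATEGORY_TABLE$category
  structure(list(costs = costs, base_year = base_year,
                 inflation_rate = inflation_rate), class = "unit_cost_set")
}

# sum a (year, category, fit, frail) data frame to sector level, appending
# an all-sector "total" row per year
aggregate_sectors <- function(df) {
  agg <- aggregate(cbind(fit, frail) ~ year + sector, data = df, FUN = sum)
  tot <- aggregate(cbind(fit, frail) ~ year, data = df, FUN = sum)
  tot$sector <- "total"
  out <- rbind(agg, tot[, c("year", "sector", "fit", "frail")])
  out$total <- out$fit + out$frail
  out[order(out$year, match(out$sector,
                            c("primary", "secondary_urgent", "total"))), ,
      drop = FALSE]
}

#' Project annual service contacts from a trajectory
#'
#' For every trajectory year, contacts in a category are the sum over
#' strata of stock x rate; the fit group is the fit column of each band,
#' the frail group pools mild, moderate and severe.
#'
#' @param traj A `frailty_trajectory`.
#' @param rates A [service_rate_set()].
#' @return Object of class `contact_series`: list with `by_category`
#'   (columns `year`, `category`, `sector`, `fit`, `frail`, `total`;
#'   contacts in persons x contacts) and `by_sector` (sector totals plus an
#'   all-sector `"total"` row per year).
#' @export
project_contacts <- function(traj, rates) {
  if (!inherits(rates, "service_rate_set"))
    stop("rates must be a service_rate_set", call. = FALSE)
  r <- unclass(rates)
  n <- length(traj$years)
  cats <- SERVICE_CATEGORY_TABLE$category
  by_cat <- expand.grid(category = cats, year = traj$years,
                        stringsAsFactors = FALSE)[, c("year", "category")]
  fit <- frail <- numeric(nrow(by_cat))
  for (i in seq_len(n)) {
    s <- traj$stocks[, , i]
    contacts <- r * as.vector(s)          # broadcast band x state over cats
    rows <- which(by_cat$year == traj$years[i])
    fit[rows] <- apply(contacts[, 1, , drop = FALSE], 3, sum)
    frail[rows] <- apply(contacts[, 2:4, , drop = FALSE], 3, sum)
  }
  by_cat$sector <- SERVICE_CATEGORY_TABLE$sector[match(by_cat$category, cats)]
  by_cat$fit <- fit
  by_cat$frail <- frail
  by_cat$total <- fit + frail
  structure(list(by_category = by_cat,
                 by_sector = aggregate_sectors(by_cat),
                 years = traj$years),
            class = "contact_series")
}

#' Project annual service costs from contacts
#'
#' Multiplies category-resolved contacts by unit costs and aggregates to
#' sector level. Costs are reported at base-year prices (constant 2016/17
#' pounds by default); no year-on-year inflation is applied to
#' projections.
#'
#' @param contacts A [project_contacts()] result.
#' @param unit_costs A [unit_cost_set()].
#' @return Object of class `cost_series`: list with `by_category` and
#'   `by_sector` data frames (same layout as [project_contacts()], values
#'   in pounds) and `base_year`.
#' @export
project_costs <- function(contacts, unit_costs) {
  if (!inherits(contacts, "contact_series"))
    stop("contacts must be a contact_series", call. = FALSE)
  if (!inherits(unit_costs, "unit_cost_set"))
    stop("unit_costs must be a unit_cost_set", call. = FALSE)
  by_cat <- contacts$by_category
  uc <- unit_costs$costs[by_cat$category]
  by_cat$fit <- by_cat$fit * uc
  by_cat$frail <- by_cat$frail * uc
  by_cat$total <- by_cat$fit + by_cat$frail
  structure(list(by_category = by_cat,
                 by_sector = aggregate_sectors(by_cat),
                 years = contacts$years, base_year = unit_costs$base_year),
            class = "cost_series")
}

#' Re-base a cost between price years
#'
#' Compounds an amount from one price base year to another at a constant
#' annual inflation rate: `amount * (1 + rate)^(to_year - from_year)`.
#' Used to harmonise unit costs quoted in years other than 2016/17 before
#' they enter [unit_cost_set()].
#'
#' @param amount Cost in pounds.
#' @param from_year,to_year Price base years.
#' @param rate Annual inflation rate (> -1); default 0.035.
#' @return Re-based amount in pounds.
#' @examples
#' adjust_cost_base(100, 2016, 2017)  # 103.5
#' @export
adjust_cost_base <- function(amount, from_year, to_year, rate = 0.035) {
  if (any(rate <= -1)) stop("rate must exceed -1", call. = FALSE)
  amount * (1 + rate)^(to_year - from_year)
}

#' @export
print.contact_series <- function(x, ...) {
  cat(sprintf("<contact_series> %d-%d, contacts (millions):\n",
              min(x$years), max(x$years)))
  bs <- x$by_sector
  bs[c("fit", "frail", "total")] <- lapply(bs[c("fit", "frail", "total")],
                                           function(v) round(v / 1e6, 1))
  print(utils::head(bs, 9), row.names = FALSE)
  if (length(x$years) > 3) cat("...\n")
  invisible(x)
}

#' @export
print.cost_series <- function(x, ...) {
  cat(sprintf("<cost_series> %d-%d, base %s prices (pound millions):\n",
              min(x$years), max(x$years), x$base_year))
  bs <- x$by_sector
  bs[c("fit", "frail", "total")] <- lapply(bs[c("fit", "frail", "total")],
                                           function(v) round(v / 1e6, 1))
  print(utils::head(bs, 9), row.names = FALSE)
  if (length(x$years) > 3) cat("...\n")
  invisible(x)
}
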