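# Packaged machine-readable copies of the published projection tables:
# annual incident frailty cases (by age band), service contacts and costs
# (fit/frail x primary/secondary & urgent), and the headline scalar
# results, each cell exactly as printed and carrying a provenance note.
# Totals are stored as printed, including the 65-74 incidence column total
# (2 509 209) that exceeds the column's rounded annual sum (2 509 200):
# published totals were evidently computed before rounding, and the
# fixtures preserve the print rather than "fixing" it.

fixture_files <- c(incidence = "table1_incidence.csv",
                   contacts = "table2_contacts.csv",
                   costs = "table3_costs.csv",
                   scalars = "printed_results.csv")

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "frailtydyn")
  if (p == "") stop(sprintf("packaged fixture '%s' not found", file),
                    call. = FALSE)
  p
}

#' Load the packaged projection-table fixtures
#'
#' Reads the packaged CSV copies of the published baseline projection
#' tables and scalar results, verifying each file's MD5 checksum against
#' the packaged manifest first (a mismatch is an error, never a silent
#' repair).
#'
#' @return Object of class `fixture_tables`: list with
#'   * `incidence` — long data frame (`year` as character, `"Total"` for
#'     the printed totals row; `band` including `"Overall"`; `new_cases`;
#'     `source`),
#'   * `contacts` — `year`, `sector`, `group` (fit/frail/total),
#'     `contacts_millions`, `source`,
#'   * `costs` — `year`, `sector` (primary/secondary_urgent/total),
#'     `group`, `cost_millions`, `source`,
#'   * `scalars` — named numeric vector of the headline printed results
#'     (population and frail totals, prevalences, growth percentages,
#'     scenario reductions and savings), plus `scalar_table` with units
#'     and provenance.
#' @export
load_fixture_tables <- function() {
  checks <- utils::read.csv(fixture_path("fixture_checksums.csv"),
                            stringsAsFactors = FALSE)
  for (f in fixture_files) {
    actual <- unname(tools::md5sum(fixture_path(f)))
    expected <- checks$md5[checks$file == f]
    if (length(expected) != 1 || !identical(actual, expected))
      stop(sprintf("checksum mismatch for packaged fixture '%s'", f),
           call. = FALSE)
  }
  rd <- function(key) utils::read.csv(fixture_path(fixture_files[[key]]),
                                      stringsAsFactors = FALSE,
                                      check.names = FALSE)
  inc <- rd("incidence")
  inc$year <- as.character(inc$year)
  scal <- rd("scalars")
  structure(list(incidence = inc, contacts = rd("contacts"),
                 costs = rd("costs"),
                 scalars = stats::setNames(scal$value, scal$quantity),
                 scalar_table = scal),
            class = "fixture_tables")
}

#' @export
print.fixture_tables <- function(x, ...) {
  cat("<fixture_tables> packaged published projection tables\n")
  cat(sprintf("incidence rows: %d; contact rows: %d; cost rows: %d; scalars: %d\n",
              nrow(x$incidence), nrow(x$contacts), nrow(x$costs),
              length(x$scalars)))
  invisible(x)
}

#' Incidence fixture in wide (year x band) form
#'
#' @param fx A [load_fixture_tables()] result.
#' @param totals Keep the printed `"Total"` row (default `FALSE`).
#' @return Data frame with `year` and one column per band plus `Overall`.
#' @export
fixture_incidence_wide <- function(fx, totals = FALSE) {
  inc <- fx$incidence
  if (!totals) inc <- inc[inc$year != "Total", ]
  wide <- stats::reshape(inc[, c("year", "band", "new_cases")],
                         idvar = "year", timevar = "band",
                         direction = "wide")
  names(wide) <- sub("^new_cases\\.", "", names(wide))
  wide <- wide[, c("year", AGE_BANDS, "Overall")]
  rownames(wide) <- NULL
  wide
}
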