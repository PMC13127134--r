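test_that("display rounding is half away from zero at the display digit", {
  expect_equal(round_half_up(76.05, 1), 76.1)
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(round_half_up(-2.5, 0), -3)
  expect_equal(round_half_up(12.575, 1), 12.6)
  expect_equal(round_half_up(1234.5, -1), 1230)
  expect_equal(round_half_up(1235, -1), 1240)
})

test_that("summary statistics reproduce printed growth and prevalence maths", {
  st <- summary_stats(23126258, 24021710, 16228687, 18269340,
                      cost_start_million = 45728.6,
                      cost_end_million = 55745.5)
  expect_equal(st$population_growth_pct, 3.9)
  expect_equal(st$frail_growth_pct, 12.6)
  expect_equal(st$prevalence_start_pct, 70.2)
  expect_equal(st$prevalence_end_pct, 76.1)
  expect_equal(st$cost_increase_billion, 10.0)
  # rounding locality: raw and displayed differ by < one display unit
  raw <- 100 * (24021710 - 23126258) / 23126258
  expect_lt(abs(st$population_growth_pct - raw), 0.05)
})

test_that("summarize_projection derives stats from a pipeline bundle", {
  r <- seeded_run(20, nyears = 6)
  rates <- gen_service_rates(r$cfg)
  ucost <- gen_unit_costs(r$cfg)
  bundle <- run_pipeline(r$initial, r$params, r$entries, 2025, 2031,
                         rates = rates, unit_costs = ucost)
  ps <- prevalence_series(bundle$trajectory)
  st <- summarize_projection(bundle)
  expect_equal(st$population_growth_pct,
               round_half_up(100 * (ps$total_count[7] / ps$total_count[1]
                                    - 1), 1))
  expect_equal(nrow(st$prevalence_by_year), 7)
  expect_true(all(abs(st$prevalence_by_year$prevalence_pct -
                        100 * ps$frail_fraction) <= 0.05))
})

test_that("config write/read round trip is lossless", {
  tr <- make_truth(generator_config(seed = 77), end_year = 2030)
  inputs <- list(params = tr$params, initial = tr$initial,
                 entries = tr$entries, rates = tr$rates,
                 unit_costs = tr$unit_costs)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(inputs, path)
  back <- read_config(path)
  expect_equal(back$params, tr$params)
  expect_equal(unclass(back$initial), unclass(tr$initial),
               ignore_attr = TRUE)
  expect_equal(as.numeric(back$entries), as.numeric(tr$entries))
  expect_equal(unclass(back$rates), unclass(tr$rates),
               ignore_attr = TRUE)
  expect_equal(back$unit_costs$costs, tr$unit_costs$costs)
})

test_that("config validation names every failing field", {
  tr <- make_truth(generator_config(seed = 78), end_year = 2028)
  inputs <- list(params = tr$params, initial = tr$initial,
                 entries = tr$entries)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(inputs, path)
  cfg <- yaml::read_yaml(path)
  cfg$parameters$mortality[["75-84"]][["moderate"]] <- NULL
  cfg$parameters$transition[["50-64"]][["fit_mild"]] <- "oops"
  path2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path2)
  err <- tryCatch(read_config(path2), error = conditionMessage)
  expect_match(err, "parameters.mortality.75-84.moderate", fixed = TRUE)
  expect_match(err, "parameters.transition.50-64.fit_mild", fixed = TRUE)
  expect_error(read_config(withr::local_tempfile()), "not found")
})

test_that("outputs rerun byte-identically apart from the manifest timestamp", {
  r <- seeded_run(21, nyears = 4)
  rates <- gen_service_rates(r$cfg)
  ucost <- gen_unit_costs(r$cfg)
  bundle <- run_pipeline(r$initial, r$params, r$entries, 2025, 2029,
                         rates = rates, unit_costs = ucost)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_outputs(bundle, d1)
  write_outputs(bundle, d2)
  for (f in c("trajectory.csv", "contacts.csv", "costs.csv",
              "summary.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  m1 <- jsonlite::read_json(file.path(d1, "manifest.json"))
  expect_equal(m1$package, "frailtydyn")
  expect_true(!is.null(m1$timestamp))
})
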