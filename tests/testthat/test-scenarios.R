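test_that("built-in scenarios alter exactly the advertised rates", {
  sc <- builtin_scenarios()
  # A: fit->mild x0.95 in all bands, nothing else
  expect_equal(unname(sc$A$flow_multipliers[, "fit_mild"]), rep(0.95, 4))
  expect_true(all(sc$A$flow_multipliers[, c("mild_moderate",
                                            "moderate_severe")] == 1))
  expect_true(all(sc$A$service_multipliers == 1))
  # B: exactly two flow multipliers changed, in all bands
  expect_equal(unname(sc$B$flow_multipliers[, "mild_moderate"]),
               rep(0.90, 4))
  expect_equal(unname(sc$B$flow_multipliers[, "moderate_severe"]),
               rep(0.95, 4))
  expect_true(all(sc$B$flow_multipliers[, "fit_mild"] == 1))
  changed_cols <- apply(sc$B$flow_multipliers != 1, 2, any)
  expect_equal(sum(changed_cols), 2)
  expect_true(all(sc$B$service_multipliers == 1))
  # C: population flows untouched, one service category scaled
  expect_true(all(sc$C$flow_multipliers == 1))
  expect_equal(unname(sc$C$service_multipliers["unplanned_admission"]),
               0.975)
  expect_equal(sum(sc$C$service_multipliers != 1), 1)
  expect_true(all(vapply(sc, function(s) s$mode, "") == "constant"))
})

test_that("applying a scenario multiplies targeted rates and nothing else", {
  p <- tiny_params()
  rates <- gen_service_rates(generator_config(2))
  ones <- scenario_spec("null")
  out <- apply_scenario(p, rates, ones)
  expect_identical(out$params, p)       # bit-identical pass-through
  expect_identical(out$rates, rates)
  A <- builtin_scenarios()$A
  out <- apply_scenario(p, rates, A)
  expect_equal(out$params$transition[, "fit_mild"],
               p$transition[, "fit_mild"] * 0.95)
  expect_identical(out$params$transition[, -1], p$transition[, -1])
  expect_identical(out$params$mortality, p$mortality)
  expect_identical(out$rates, rates)
  # compounding: factor^t over the years
  comp <- scenario_spec("c", service_multipliers = c(rep(1, 7), 0.975, 1),
                        mode = "compounding")
  f <- vapply(1:3, function(t)
    apply_scenario(p, rates, comp, years_elapsed = t)$rates[1, 1, 8] /
      rates[1, 1, 8], numeric(1))
  expect_equal(round(f, 6), c(0.975, 0.950625, 0.926859))
  expect_error(scenario_spec("bad", flow_multipliers = matrix(0, 4, 3)),
               "strictly positive")
})

test_that("the all-ones scenario reproduces baseline bit-identically", {
  r <- seeded_run(9, nyears = 8)
  rates <- gen_service_rates(r$cfg)
  ucost <- gen_unit_costs(r$cfg)
  base <- run_pipeline(r$initial, r$params, r$entries, 2025, 2033,
                       rates = rates, unit_costs = ucost)
  null_scen <- run_pipeline(r$initial, r$params, r$entries, 2025, 2033,
                            rates = rates, unit_costs = ucost,
                            scenario = scenario_spec("null"))
  expect_identical(base$trajectory$stocks, null_scen$trajectory$stocks)
  expect_identical(base$contacts$by_sector, null_scen$contacts$by_sector)
  expect_identical(base$costs$by_sector, null_scen$costs$by_sector)
  cmp <- compare_projections(base, null_scen)
  expect_true(all(cmp$by_year$frail_delta == 0))
  expect_equal(cmp$cumulative_saving, 0)
})

test_that("scenario dominance: each scenario lowers its target every year", {
  for (seed in c(3, 12, 21)) {
    r <- seeded_run(seed, nyears = 10)
    rates <- gen_service_rates(r$cfg)
    ucost <- gen_unit_costs(r$cfg)
    base <- run_pipeline(r$initial, r$params, r$entries, 2025, 2035,
                         rates = rates, unit_costs = ucost)
    sc <- builtin_scenarios()
    for (nm in names(sc)) {
      scen <- run_pipeline(r$initial, r$params, r$entries, 2025, 2035,
                           rates = rates, unit_costs = ucost,
                           scenario = sc[[nm]])
      cmp <- compare_projections(base, scen)
      if (nm == "A")
        expect_true(all(cmp$by_year$frail_delta >= -1e-9))
      if (nm == "B")
        expect_true(all(cmp$by_year$moderate_severe_delta >= -1e-9))
      if (nm == "C") {
        ba <- base$contacts$by_category
        sa <- scen$contacts$by_category
        un_b <- ba$total[ba$category == "unplanned_admission"]
        un_s <- sa$total[sa$category == "unplanned_admission"]
        expect_true(all(un_s <= un_b + 1e-9))
        expect_identical(base$trajectory$stocks, scen$trajectory$stocks)
      }
      expect_gte(cmp$cumulative_saving, -1e-6)
    }
  }
})

test_that("comparison reports average annual saving over the horizon", {
  r <- seeded_run(14, nyears = 16)
  rates <- gen_service_rates(r$cfg)
  ucost <- gen_unit_costs(r$cfg)
  base <- run_pipeline(r$initial, r$params, r$entries, 2025, 2040,
                       rates = rates, unit_costs = ucost)
  scen <- run_pipeline(r$initial, r$params, r$entries, 2025, 2040,
                       rates = rates, unit_costs = ucost,
                       scenario = builtin_scenarios()$A)
  cmp <- compare_projections(base, scen)
  expect_equal(cmp$horizon_years, 16)
  expect_equal(cmp$cumulative_saving, sum(cmp$by_year$cost_delta))
  expect_equal(cmp$average_annual_saving, cmp$cumulative_saving / 16)
  short <- run_pipeline(r$initial, r$params, r$entries, 2025, 2030,
                        rates = rates, unit_costs = ucost)
  expect_error(compare_projections(base, short), "horizons differ")
})
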