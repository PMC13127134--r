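test_that("loss at the generating parameters is zero on noiseless targets", {
  tr <- make_truth(generator_config(seed = 31), end_year = 2035)
  rp <- recovery_problem(tr)
  expect_lt(calibration_loss(rp$problem, rp$truth_theta), 1e-12)
})

test_that("free transition rates are recovered from engine-generated targets", {
  for (seed in c(41, 42, 43)) {
    tr <- make_truth(generator_config(seed = seed), end_year = 2035)
    rp <- recovery_problem(tr)
    res <- calibrate(rp$problem)
    expect_true(res$converged)
    expect_lt(max(abs(res$fitted - rp$truth_theta) / rp$truth_theta), 0.01)
    # fitted values respect the declared bounds
    expect_true(all(res$fitted >= rp$problem$free$lower - 1e-15))
    expect_true(all(res$fitted <= rp$problem$free$upper + 1e-15))
  }
})

test_that("the recovered optimum is stable to a perturbed start", {
  tr <- make_truth(generator_config(seed = 55), end_year = 2035)
  rp <- recovery_problem(tr)
  res1 <- calibrate(rp$problem)
  start2 <- pmin(pmax(rp$truth_theta * 1.5, rp$problem$free$lower),
                 rp$problem$free$upper)
  res2 <- calibrate(rp$problem, start = start2)
  expect_lt(max(abs(res1$fitted - res2$fitted)), 1e-4)
})

test_that("zero free parameters returns the fixed inputs with a direct loss", {
  tr <- make_truth(generator_config(seed = 7), end_year = 2030)
  traj <- tr$trajectory
  tg <- data.frame(year = traj$years, value = apply(traj$stocks, 3, sum))
  problem <- calibration_problem(
    tr$params, tr$initial, tr$entries, traj$start_year, traj$end_year,
    free = free_parameters(character(0), numeric(0), numeric(0),
                           numeric(0)),
    targets = list(target_total_pop(tg)))
  res <- calibrate(problem)
  expect_true(res$converged)
  expect_lt(res$loss, 1e-20)
  expect_identical(res$params, tr$params)
})

test_that("flat loss directions are flagged, not masked", {
  # with mortality uniform across frailty states, transitions conserve
  # persons exactly, so a total-population target carries no information
  # about them: the problem is unidentifiable
  tr <- make_truth(generator_config(seed = 13), end_year = 2030)
  p0 <- parameter_set(tr$params$transition,
                      matrix(rep(rowMeans(tr$params$mortality), 4), 4, 4),
                      tr$params$ageing, tr$params$entry_mix)
  traj <- run_projection(tr$initial, p0, tr$entries, 2025, 2030)
  tg <- data.frame(year = traj$years, value = apply(traj$stocks, 3, sum))
  free <- free_parameters(c("transition[50-64,fit_mild]",
                            "transition[65-74,mild_moderate]"),
                          0, 0.5, c(0.1, 0.1))
  problem <- calibration_problem(
    p0, tr$initial, tr$entries, traj$start_year, traj$end_year,
    free = free, targets = list(target_total_pop(tg)))
  expect_warning(res <- calibrate(problem), "flat")
  expect_true(all(res$flat_directions$flat))
})

test_that("problem construction enforces its preconditions", {
  tr <- make_truth(generator_config(seed = 2), end_year = 2028)
  free <- free_parameters(sprintf("transition[%s,fit_mild]",
                                  age_bands()$label), 0, 0.5, 0.1)
  tg <- data.frame(year = 2026, value = 1)
  expect_error(
    calibration_problem(tr$params, tr$initial, tr$entries, 2025, 2028,
                        free = free,
                        targets = list(target_total_pop(tg))),
    "fewer weighted target points")
  expect_error(free_parameters("transition[50-64,fit_mild]", 0.2, 0.1, 0.15),
               "invalid bounds")
  expect_error(free_parameters("mortality[85+,severe]", 0, 1.5, 0.1),
               "invalid bounds")
  expect_error(free_parameters("entry_level", 0, 1e6, 2e6),
               "inside the bounds")
})

test_that("the packaged England problem is well-formed", {
  pr <- england_problem()
  expect_s3_class(pr, "calibration_problem")
  # the printed-table targets: 64 incidence cells plus 4 headline counts
  npts <- sum(vapply(pr$targets, function(t) nrow(t$data), integer(1)))
  expect_equal(npts, 68)
  # initial population pinned to the printed 2025 total by construction
  inp <- frailtydyn:::build_inputs(pr, pr$free$start)
  expect_equal(sum(inp$initial), 23126258, tolerance = 1e-9)
  expect_equal(prevalence(inp$initial)$total_count, 23126258,
               tolerance = 1e-9)
  # loss at the start point is finite and positive (nothing fitted yet)
  l0 <- calibration_loss(pr)
  expect_true(is.finite(l0) && l0 > 0)
})
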