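test_that("a single step does the expected arithmetic", {
  # zero rates, zero entrants: nothing moves
  zero <- parameter_set(matrix(0, 4, 3), matrix(0, 4, 4),
                        ageing = c(0, 0, 0))
  s0 <- tiny_stocks()
  st <- step_population(s0, zero, 0)
  expect_equal(unclass(st$stocks), unclass(s0), ignore_attr = TRUE)
  expect_true(all(st$flows$transitions == 0))
  expect_true(all(st$flows$deaths == 0))

  # 1000 fit persons, fit->mild 0.1, everything else zero
  tr <- matrix(0, 4, 3)
  tr[1, 1] <- 0.1
  p <- parameter_set(tr, matrix(0, 4, 4), ageing = c(0, 0, 0))
  m <- matrix(0, 4, 4)
  m[1, 1] <- 1000
  st <- step_population(stock_vector(m, 2025), p, 0)
  expect_equal(unclass(st$stocks)["50-64", "fit"], 900)
  expect_equal(unclass(st$stocks)["50-64", "mild"], 100)
  expect_equal(st$flows$transitions["50-64", "fit_mild"], 100)
})

test_that("step rejects invalid stocks and entrants", {
  expect_error(step_population(tiny_stocks(), tiny_params(), -1),
               "non-negative")
  expect_error(step_population(tiny_stocks(), tiny_params(), NaN),
               "non-negative")
  expect_error(step_population(unclass(tiny_stocks()), tiny_params(), 0),
               "stock_vector")
})

test_that("affine map structure encodes the model's flows", {
  # all-zero rates: identity matrix, zero-impact entry template
  zero <- parameter_set(matrix(0, 4, 3), matrix(0, 4, 4),
                        ageing = c(0, 0, 0))
  map <- build_affine_map(zero)
  expect_equal(map$matrix, diag(16), ignore_attr = TRUE)

  p <- tiny_params()
  map <- build_affine_map(p)
  A <- map$matrix
  idx <- function(a, s) (a - 1) * 4 + s
  for (a in 1:4) for (s in 1:4) {
    k <- idx(a, s)
    # outflow from the stratum (1 - diagonal) equals mortality +
    # applicable transition + ageing rates; the column as a whole only
    # loses the deaths (transitions and ageing stay in the system)
    outflow <- 1 - A[k, k]
    expected <- p$mortality[a, s] +
      (if (s < 4) p$transition[a, s] else 0) +
      (if (a < 4) p$ageing[a] else 0)
    expect_equal(outflow, unname(expected), tolerance = 1e-12)
    expect_equal(1 - sum(A[, k]), unname(p$mortality[a, s]),
                 tolerance = 1e-12)
    # no recovery: no entry into a lower frailty state of the same band
    if (s > 1) for (s2 in seq_len(s - 1)) expect_equal(A[idx(a, s2), k], 0)
    # no band demotion and no band skipping
    if (a > 1) for (a2 in seq_len(a - 1)) for (s2 in 1:4)
      expect_equal(A[idx(a2, s2), k], 0)
    if (a < 3) for (s2 in 1:4) expect_equal(A[idx(a + 2, s2), k], 0)
  }
  expect_error(build_affine_map(list(transition = 2)), "parameter_set")
})

test_that("run matches the affine-map oracle on seeded parameter sets", {
  for (seed in 1:25) {
    r <- seeded_run(seed, nyears = 16)
    final <- oracle_final_stocks(r$params, r$initial,
                                 r$cfg$entrants_per_year, 16)
    expect_rel_equal(unclass(final),
                     r$traj$stocks[, , 17], tol = 1e-9)
  }
})

test_that("population is conserved: total changes only by deaths and entries", {
  for (seed in c(2, 11, 29)) {
    r <- seeded_run(seed, nyears = 12)
    tot <- apply(r$traj$stocks, 3, sum)
    deaths <- apply(r$traj$deaths, 3, sum)
    ent <- colSums(r$traj$entries)
    expect_rel_equal(tot[-1], tot[-length(tot)] - deaths + ent, tol = 1e-9)
  }
  # zero mortality, zero entrants: total population constant
  p <- tiny_params()
  p0 <- parameter_set(p$transition, matrix(0, 4, 4),
                      entry_mix = p$entry_mix)
  traj <- run_projection(tiny_stocks(), p0,
                         entry_schedule(2025:2034, 0), 2025, 2035)
  tot <- apply(traj$stocks, 3, sum)
  expect_rel_equal(tot, rep(tot[1], length(tot)), tol = 1e-12)
})

test_that("outflow capping rescales proportionally and keeps stocks non-negative", {
  tr <- matrix(0.5, 4, 3)
  mort <- matrix(0.9, 4, 4)
  p <- parameter_set(tr, mort, ageing = c(0.2, 0.2, 0.2))
  s0 <- tiny_stocks()
  st <- step_population(s0, p, 100)
  expect_true(all(unclass(st$stocks) >= 0))
  # fit stratum of band 1: rates 0.9 + 0.5 + 0.2 = 1.6 > 1, rescaled by 1/1.6
  n <- unclass(s0)[1, 1]
  expect_equal(st$flows$deaths[1, 1], n * 0.9 / 1.6)
  expect_equal(st$flows$transitions[1, 1], n * 0.5 / 1.6)
  # deaths never exceed the start-of-year stock
  expect_true(all(st$flows$deaths <= unclass(s0) + 1e-12))
  # conservation still holds under capping
  expect_equal(sum(st$stocks),
               sum(s0) - sum(st$flows$deaths) + 100, tolerance = 1e-12)
  # the capped update is still affine: oracle agrees
  final <- oracle_final_stocks(p, s0, 100, 5)
  traj <- run_projection(s0, p, entry_schedule(2025:2029, 100), 2025, 2030)
  expect_rel_equal(unclass(final), traj$stocks[, , 6], tol = 1e-9)
})

test_that("zero-length horizon returns only the initial stocks", {
  traj <- run_projection(tiny_stocks(), tiny_params(),
                         entry_schedule(2025, 0), 2025, 2025)
  expect_equal(length(traj$years), 1)
  expect_equal(dim(traj$transitions)[3], 0)
  expect_error(annual_incidence(traj), "no year-steps")
  expect_error(run_projection(tiny_stocks(), tiny_params(),
                              entry_schedule(2025, 0), 2025, 2024),
               "precede")
})

test_that("raising one transition rate never lowers downstream frail stocks", {
  downstream <- list(fit_mild = c("mild", "moderate", "severe"),
                     mild_moderate = c("moderate", "severe"),
                     moderate_severe = "severe")
  for (seed in c(5, 17)) {
    r <- seeded_run(seed, nyears = 10)
    for (type in colnames(r$params$transition)) {
      band <- (seed %% 4) + 1
      p2 <- r$params
      tr <- p2$transition
      tr[band, type] <- min(tr[band, type] + 0.1, 1)
      p2 <- parameter_set(tr, p2$mortality, p2$ageing, p2$entry_mix)
      t2 <- run_projection(r$initial, p2, r$entries, 2025, 2035)
      down <- apply(r$traj$stocks[, downstream[[type]], , drop = FALSE],
                    3, sum)
      down2 <- apply(t2$stocks[, downstream[[type]], , drop = FALSE],
                     3, sum)
      expect_true(all(down2 >= down - 1e-9 * pmax(down, 1)))
    }
  }
})

test_that("annual incidence tabulates the fit->mild flow with totals", {
  r <- seeded_run(4, nyears = 6)
  inc <- annual_incidence(r$traj)
  expect_equal(nrow(inc), 7)        # 6 flow years + totals row
  expect_equal(inc$year[7], "Total")
  expect_equal(inc$Overall, rowSums(inc[, age_bands()$label]))
  expect_equal(unlist(inc[7, -1]), colSums(inc[1:6, -1]),
               ignore_attr = TRUE)
  expect_equal(inc[1, "50-64"],
               unname(r$traj$transitions["50-64", "fit_mild", 1]))
  # zero fit->mild rates: all entries zero
  p <- tiny_params()
  tr <- p$transition
  tr[, 1] <- 0
  p0 <- parameter_set(tr, p$mortality, p$ageing, p$entry_mix)
  traj <- run_projection(tiny_stocks(), p0, entry_schedule(2025:2029, 10),
                         2025, 2030)
  expect_true(all(annual_incidence(traj)[, -1] == 0))
})

test_that("prevalence sums frail states and flags an empty population", {
  m <- matrix(0, 4, 4)
  m[, 1] <- 100                      # everyone fit
  expect_equal(prevalence(stock_vector(m, 2025))$frail_fraction, 0)
  m[2, 3] <- 300
  pv <- prevalence(stock_vector(m, 2025))
  expect_equal(pv$frail_count, 300)
  expect_equal(pv$total_count, 700)
  expect_equal(pv$frail_fraction, 3 / 7)
  expect_warning(pv0 <- prevalence(stock_vector(matrix(0, 4, 4), 2025)),
                 "undefined")
  expect_true(is.nan(pv0$frail_fraction))
})

test_that("tidy trajectory export balances stocks against flows", {
  r <- seeded_run(8, nyears = 5)
  df <- as.data.frame(r$traj)
  expect_equal(nrow(df), 16 * 6)
  expect_true(all(c("stock", "deaths", "transition_in", "ageing_out",
                    "entries") %in% names(df)))
  # reconstruct next-year stocks from the flow ledger
  for (yr in 2025:2029) {
    cur <- df[df$year == yr, ]
    nxt <- df[df$year == yr + 1, ]
    rebuilt <- cur$stock - cur$deaths - cur$transition_out -
      cur$ageing_out + cur$transition_in + cur$ageing_in + cur$entries
    expect_rel_equal(rebuilt, nxt$stock, tol = 1e-9)
  }
  # final year carries no flows
  expect_true(all(is.na(df$deaths[df$year == 2030])))
})
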