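# shared builders for tests; everything is generated in code

# a small, hand-specified parameter set with mild rates
tiny_params <- function() {
  parameter_set(
    transition = matrix(c(0.08, 0.07, 0.06, 0.05,
                          0.09, 0.09, 0.08, 0.07,
                          0.07, 0.07, 0.08, 0.08), 4, 3),
    mortality = matrix(rep(c(0.005, 0.015, 0.04, 0.12), 4), 4, 4) *
      rep(c(0.8, 1, 1.5, 2), each = 4),
    entry_mix = c(0.5, 0.35, 0.1, 0.05))
}

tiny_stocks <- function(year = 2025, total = 1e5) {
  stock_vector(matrix(total / 16, 4, 4), year)
}

# run a short projection under seeded random parameters
seeded_run <- function(seed, nyears = 16, total = 1e6) {
  cfg <- generator_config(seed = seed, total_population = total)
  params <- gen_parameter_set(cfg)
  initial <- gen_initial_stocks(cfg, 2025)
  entries <- entry_schedule(2025:(2025 + nyears - 1),
                            cfg$entrants_per_year)
  list(cfg = cfg, params = params, initial = initial, entries = entries,
       traj = run_projection(initial, params, entries, 2025,
                             2025 + nyears))
}

# iterate the affine-map oracle over a horizon
oracle_final_stocks <- function(params, initial, entrants, nsteps) {
  map <- build_affine_map(params)
  cur <- initial
  for (i in seq_len(nsteps)) cur <- apply_affine_map(map, cur, entrants)
  cur
}

`%||%` <- function(a, b) if (is.null(a)) b else a

expect_rel_equal <- function(actual, expected, tol = 1e-9) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
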