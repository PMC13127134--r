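# frailtydyn

Deterministic system-dynamics simulation of frailty in a population aged
50 and over, for health-service planners and researchers who need to
project how frailty prevalence, service demand and costs evolve as a
population ages — and how much policy interventions on frailty onset,
progression or unplanned admissions could save.

## The model

The population is stratified into four age bands (50–64, 65–74, 75–84,
85+) crossed with four electronic Frailty Index categories (fit, mild,
moderate, severe; eFI cut-points 0.12 / 0.24 / 0.36), giving 16 stocks
N<sub>a,s</sub>(t) advanced in annual steps:

- stepwise frailty progression fit → mild → moderate → severe at annual
  per-capita rates (no recovery, structurally);
- ageing promotion between bands (default rate 1/band-width, or an
  explicit year-specific schedule);
- frailty- and age-graded mortality;
- entrants turning 50, distributed over frailty states by an entry mix.

All flows are computed simultaneously from start-of-year stocks
(forward Euler, dt = 1 year), with proportional rescaling whenever a
stratum's outflow rates sum above 1, so the update is exactly affine:
N(t+1) = A·N(t) + n<sub>t</sub>·e. The explicit affine map doubles as an
independent oracle for the engine in the test suite. On top of the
population core sit:

- a **service/cost overlay** (contacts = stocks × per-person rates over
  nine primary and secondary/urgent care categories; costs in constant
  2016/17 £);
- a **scenario engine** (multiplicative interventions: A = fit→mild
  ×0.95; B = mild→moderate ×0.90 and moderate→severe ×0.95; C =
  unplanned admissions ×0.975) with baseline comparison reports;
- **bounded least-squares calibration** (Levenberg–Marquardt on weighted
  relative residuals) to recover unpublished rates from published
  targets, including a packaged, re-runnable England 2025–2040 baseline;
- a **seeded synthetic-data generator** so every stage is testable
  without external data.

See the vignette (`vignettes/frailty-projection-model.Rmd`) for the full
account of the model, the calibration design and its identifiability
limits.

## Worked example

A synthetic population of one million people aged 50+, with seeded
random rates, projected 2025–2040 and compared against the frailty
prevention scenario:

```r
library(frailtydyn)
cfg     <- generator_config(seed = 42)
params  <- gen_parameter_set(cfg)
initial <- gen_initial_stocks(cfg, 2025)
entries <- entry_schedule(2025:2040, cfg$entrants_per_year)
rates   <- gen_service_rates(cfg)
costs   <- gen_unit_costs(cfg)

bundle <- run_pipeline(initial, params, entries, 2025, 2040,
                       rates = rates, unit_costs = costs)
summarize_projection(bundle)
#> <summary_stats>
#> population growth: -10.4%
#> frail-count growth: 1.2%
#> frailty prevalence: 68.3% -> 77.2%
#> cost increase: 0.1 pound bn

scenA <- run_pipeline(initial, params, entries, 2025, 2040,
                      rates = rates, unit_costs = costs,
                      scenario = builtin_scenarios()$A)
compare_projections(bundle, scenA)
#> <comparison_report> scenario A vs baseline, 16 years
#> final-year frail reduction: 6872 persons
#> final-year moderate+severe reduction: 3426 persons
#> cumulative saving: 103.5 pound m (6.5 pound m / year)
```

Reading the output: this synthetic cohort shrinks (entrants do not
offset deaths at the configured rates) while prevalence still climbs
from 68.3% to 77.2% — ageing concentrates the survivors in frailer
states. A 5% cut in frailty incidence leaves 6 872 fewer people frail in
2040 and saves £103.5m cumulatively over the 16 years at the generated
unit costs.

For the England baseline: `calibrate_england()` recovers transition,
mortality, entry and ageing parameters from the packaged published
targets (the annual incidence table and headline 2025/2040 counts) and
returns directly re-runnable inputs; `calibrate_service_rates()` fits
the service overlay to the published contact/cost series. Every fitting
target is reproduced within 0.9% relative (the published rates
themselves are not public, so this is a calibration, not a
reconstruction).

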