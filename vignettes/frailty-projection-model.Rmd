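---
title: "Modelling frailty dynamics, service use and costs in an ageing population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling frailty dynamics, service use and costs in an ageing population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailtydyn)
```

## The model

`frailtydyn` is a deterministic system-dynamics (stock-and-flow) model of
frailty in a population aged 50 and over. The population is divided into
four age bands (50–64, 65–74, 75–84, 85+) crossed with four frailty
severity categories defined on the electronic Frailty Index (eFI): fit
(eFI 0 to <0.12), mild (0.12 to <0.24), moderate (0.24 to <0.36) and
severe (0.36+). That gives 16 *stocks* — person counts $N_{a,s}(t)$ —
advanced year by year under four kinds of *flows*:

* **frailty progression**: stepwise transitions fit→mild→moderate→severe
  at annual per-capita rates $\tau_{a}^{(s \to s+1)}$; frailty never
  improves (the eFI cannot reliably detect reversal, so no reverse flows
  exist structurally);
* **ageing**: promotion from each band to the next at per-capita rate
  $g_a$, default $1/\text{width}$ (1/15, 1/10, 1/10), which is exact for
  a uniform within-band age distribution; the 85+ band has no ageing
  outflow;
* **mortality**: per-capita rate $\mu_{a,s}$ for each stratum;
* **entry**: people turning 50 join the 50–64 band, distributed over
  frailty states by an entry mix $\pi$ (not hard-coded to all-fit:
  at a 2025 prevalence above 70%, substantial frailty is already present
  by the early 50s).

The update is annual forward Euler with $dt = 1$ year, matching the
yearly transition rates and the annual output tables; all flows are
computed simultaneously from start-of-year stocks and applied together,
which avoids any order-dependence among flows. If the per-capita outflow
rates of a stratum sum to $s > 1$, all of that stratum's flows are
rescaled by $1/s$; this guarantees non-negative stocks for *any* valid
rate set. Because the rescaling depends only on rates, never on stocks,
the one-year update remains exactly affine,

$$N(t+1) = A\,N(t) + n_t\,e,$$

and `build_affine_map()` constructs $(A, e)$ explicitly. Iterating the
map is used throughout the test suite as an independent oracle for the
step-by-step engine (`run_projection()`), with agreement required to
1e-9 relative over 100 seeded random rate sets.

Two accounting conventions matter downstream:

* **Incidence** is counted as the fit→mild flow. An eFI category can in
  principle jump from fit to moderate or severe between observations,
  but with stepwise annual transitions one step cannot skip a state, so
  all incident frailty enters through mild. This is a documented
  simplification.
* A run from `start_year` to `end_year` stores stocks for every year
  inclusive and flow records for the steps `start_year..end_year - 1`.
  Where 16 flow-years are needed (the incidence table, scenario
  accounting over 2025–2040) the pipeline simulates one year past the
  horizon end.

## Service use and costs

Annual service contacts are overlaid on prevalent stocks: contacts in
category $c$ are $\sum_{a,s} N_{a,s}(t)\, r_{a,s,c}$ with per-person
annual rates $r$. Nine categories split into primary care (GP
face-to-face, home visits, telephone, e-consultations) and secondary &
urgent care (outpatient, ED attendance, elective and unplanned
admissions, critical care). Costs multiply contacts by unit costs per
contact and are reported in constant 2016/17 pounds; the 3.5%-per-year
inflation operation (`adjust_cost_base()`) exists only to harmonise unit
costs quoted in other base years before they enter the model — no
year-on-year inflation is applied to projections. Reported tables are
rounded for display only (contacts to 0.1 million, costs to 0.1 million
pounds, half away from zero); internal arithmetic is never rounded.

## Policy scenarios

Scenarios multiply selected rates by fixed factors
(`scenario_spec()`), and are compared year-by-year against an
identically configured baseline:

* **A** — frailty prevention: fit→mild ×0.95 in all bands;
* **B** — slowed progression: mild→moderate ×0.90 *and*
  moderate→severe ×0.95 in all bands (the one scenario changing two
  rates at once);
* **C** — admission prevention: unplanned-admission service rate
  ×0.975, acting on the overlay only, with no feedback into the
  population flows.

"Per year" phrasing for a rate reduction is ambiguous between a constant
multiplier applied every year and a factor compounding yearly. The
default is the constant reading — it matches how the prevention scenario
is phrased and keeps the three scenarios structurally parallel — and a
`compounding` mode (factor$^t$ in horizon year $t$) is provided as an
option; neither is presented as the certified reading. Savings are the
yearly baseline-minus-scenario cost differences; the average annual
saving divides the cumulative saving by the number of simulated years
(16 for 2025–2040).

A point worth noting when interpreting scenario B: slowing progression
keeps people alive longer in milder states (mortality rises with
severity), so the *all-frailty* headcount can exceed baseline even while
the moderate+severe headcount falls. Cost savings under B therefore
depend critically on how steeply service use rises with severity.

## Calibration

The transition, mortality and entry rates behind published projections
of this kind are estimated from individual-level primary-care records
and are typically not published. `calibrate()` recovers free parameters
by bounded least squares: the loss is a weighted sum of squared
*relative* residuals, $\sum_i w_i\,((y_i^{sim}-y_i)/|y_i|)^2$, so
person-count targets (millions) and cost targets (pound millions) mix
without manual rescaling. The optimiser is Levenberg–Marquardt with box
bounds (`minpack.lm::nls.lm`) on the residual vector: deterministic
given the starting point, bound-feasible throughout. A non-converged fit
is always flagged, and near-flat directions of the loss surface —
parameters the targets cannot see — are detected from the curvature at
the solution ($\mathrm{diag}(J^\top J)\cdot\theta^2$, a scale-invariant
measure) and reported rather than masked.

The parameter-recovery harness (`recovery_problem()`) frees the 12
transition rates, targets the engine's own noiseless per-stratum stock
series, and requires recovery within 1% relative (observed: machine
precision) across 20 seeded problems, with zero loss at the generating
truth.

## The England 2025–2040 baseline

`england_problem()` packages a re-runnable England baseline calibrated
to the published projection: 64 annual incidence cells (16 years × 4
bands, weight 1) plus the published 2025/2040 frail counts, 2040
population total and 2040 moderate+severe count (weight 400, so the four
headline counts together carry as much weight as the incidence table and
are matched essentially exactly). Free parameters: 12 transitions, 16
mortality rates, the entry mix, the three base ageing rates, the initial
within-band frail shares and frail-split shape, and the entrant level
and trend. Quantities that had to be assumed rather than fitted are few
and documented: the initial band population shares (0.470, 0.253, 0.192,
0.085 of the published 23 126 258 — an ONS-flavoured split) and the
2016/17 cost base.

Two further design choices deserve explanation:

* **Year-resolved ageing rates.** The published model aged its
  population using year-specific official counts of people turning 65,
  75 and 85, so cohort waves (post-war birth cohorts) show up as
  non-monotone wiggles in the published incidence series that no
  constant-rate model can reproduce. The calibration therefore frees a
  per-year ageing promotion rate for each band boundary
  (`ageing_wave[...]`), ridge-penalised toward the band's base rate
  (weight 0.0025) so the schedule stays identifiable without being
  forced flat. With these, every fitting target is matched within 0.9%
  relative, comfortably inside the 2% the calibration aims for.
* **Iteration cap as the stopping rule.** With 91 free parameters the
  penalised surface has genuinely flat directions, so the
  relative-reduction stopping test never fires; the fit runs to the
  `maxiter` cap (400 by default, about three minutes) and reports the
  cap honestly as non-convergence alongside the achieved residuals.
  Between 150 and 400 iterations the incidence residuals barely move
  while the four headline counts tighten from ~0.3% to <0.02%.

What the fit does *not* identify matters as much: the published
aggregates pin stocks, not flows. Mortality by stratum, the entry mix
and the split of progression intensity between mild→moderate and
moderate→severe are only weakly constrained, so scenario experiment
magnitudes computed from the recovered baseline approximate, but do not
reproduce, the published ones (e.g. the prevention scenario's 2040 frail
reduction comes out within a few percent of the published 195 473, while
the progression scenario's cost saving is substantially smaller than
published because the within-frail severity gradient of service use is
essentially unidentifiable from fit/frail aggregates).

The service overlay surrogate (`calibrate_service_rates()`) follows the
same logic: sector-level per-person contact rates for the fit group
(least-squares slope on the published fit series), a severity-graded
rate $\text{level}\cdot\gamma^{s-1}$ for the frail states fitted to the
published frail series, category shares within each sector fixed at
plausible values — except the unplanned-admission share, which is
calibrated from the one published quantity that identifies it (2.48
million admissions avoided under a 2.5% reduction) — and unit costs that
start from representative 2016/17 reference-cost magnitudes and are
rescaled so each sector's average cost per contact reproduces the
published 2025 ratio.

## The synthetic-data generator

`generator_config()` / `make_truth()` exist so that every stage is
testable without any external data. Defaults draw annual transition
rates in 0.05–0.14, frailty- and age-graded mortality (band levels
0.002–0.2 scaled by 0.7–2.2 across severity), an entry mix centred on
(0.50, 0.35, 0.10, 0.05), and a 1-million-person initial population
whose within-band frail shares (0.55–0.93) produce prevalence plateaus
in the mid-70s percent — the regime of the England projection. These
magnitudes are illustrative, not estimates. The generator emulates
aggregate stocks and rates only: it does not emulate individual-level GP
records, eFI deficit codes, covariate structure (sex, ethnicity,
deprivation), secular trends in rates, or observation noise. Passing
recovery tests on its noiseless output therefore demonstrates that the
calibration machinery is correct and well-conditioned, not that real
published targets identify every parameter — the England fit above shows
they do not.

## Numerical choices

* Tolerances: conservation and oracle equivalence at 1e-9 relative;
  entry-mix simplex at 1e-12; loss-at-truth at 1e-12.
* Display rounding is half away from zero (`round_half_up()`), applied
  only at display; printed values differ from raw by less than one unit
  of display precision.
* Degenerate inputs: a zero total population makes prevalence `NaN`
  with a warning (never a silent zero); a zero-length horizon returns
  the initial stocks only; an all-ones scenario reproduces the baseline
  bit-identically.
* The packaged copies of the published tables store every cell exactly
  as printed, including two pre-rounding artefacts (the 65–74 incidence
  total of 2 509 209 against a rounded column sum of 2 509 200, and a
  0.2 inconsistency in the 2035 cost row); integrity tests compare at
  printed precision with those documented exceptions rather than
  "fixing" the print.

Problem sizes used by the test suite — 16-year horizons, 100 seeded rate
sets for the oracle sweep, 20 seeded recovery problems, a single
400-iteration England fit — are the package's chosen defaults for a
thorough but quick check; all scale up linearly if heavier verification
is wanted.

## Limitations

The model is an aggregate cohort simulation: no individual-level
heterogeneity beyond age × frailty, no covariate stratification, no
frailty reversal, no continuous-time solver (sub-annual dynamics are not
represented), and service scenarios do not feed back into population
flows. Costs cover publicly funded primary and secondary/urgent care
only — no social care, community care, privately funded or informal
care. Rates are held constant over the projection horizon; the baseline
is a "current trends continue" counterfactual, not a forecast.
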