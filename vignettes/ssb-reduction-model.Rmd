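---
title: "Modelling the health and cost impact of reduced sugar-sweetened beverage consumption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the health and cost impact of reduced sugar-sweetened beverage consumption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssbimpact)
```

## The model in one paragraph

`ssbimpact` projects, over a ten-year horizon (2013--2022), how a reduction
in sugar-sweetened beverage (SSB) consumption in an adult population of
California's scale and composition would change the incidence of type 2
diabetes and coronary heart disease (CHD), myocardial infarctions (MI), CHD
and all-cause mortality, and direct medical costs. The causal chain is: an
excise tax raises price; price elasticity of demand turns that into a
consumption change; the consumption change acts on disease risk through
three channels -- a direct per-serving diabetes relative risk, a direct
per-serving systolic blood pressure (SBP) effect, and an energy-balance
channel in which removed calories lower body-mass index (BMI) and thereby
SBP, LDL, HDL and diabetes risk; the shifted risk-factor profile then drives
an annual-cycle state-transition simulation of diabetes and CHD whose
baseline is calibrated to anticipated case counts; finally, averted
person-state-years and events are valued at unit medical costs, converted to
2012 dollars and discounted at 3% per year.

## Tax, elasticity, and the consumption scenarios

A volumetric excise tax of $t$ dollars per fluid ounce on a container of $v$
ounces and pre-tax price $p$ raises the price by $tv/p$; with demand
elasticity $\varepsilon \le 0$ the proportional consumption reduction is
$|\varepsilon| \, t v / p$, capped at 1. With the published elasticity range
$-0.79$ to $-1.00$, a penny-per-ounce tax on a 12-ounce, \$1.00 beverage
yields a 9.5--12% reduction, and a 32-ounce container a 25%+ reduction
(`consumption_reduction_from_tax()`). The simulation scenarios therefore use
a 10% reduction as the base case, with 20% and 50% as sensitivity levels
(`scenario_spec()`); the 50% level represents taxation combined with
education and labelling efforts rather than a tax alone.

## The risk-factor cascade

All effect sizes live in one object, `effect_parameters()`, and are applied
by `apply_intervention()` per population cell:

* **Diabetes, direct.** The total per-serving-per-day relative risk of
  diabetes is 1.35 (95% CI 1.14--1.59). Half of it is assumed to be mediated
  through body weight, so the direct component is taken on the log-RR scale:
  $\mathrm{RR}_{direct} = \exp\!\big((1-m)\ln \mathrm{RR}_{total}\big)$ with
  $m = 0.5$, i.e. the square root (`direct_diabetes_rr()`). This
  apportionment is the one consistent with the adjusted per-serving RRs of
  1.07 (from 1.14) and 1.26 (from 1.59) used at the CI bounds. The RR is
  applied continuously as $\mathrm{RR}_{direct}^{\Delta s}$ for a serving
  change $\Delta s \le 0$, so the diabetes hazard ratio of a cell always
  lies in $(0, 1]$.
* **SBP, direct.** $-0.78$ mmHg per serving reduced in men, $-0.61$ in
  women (95% CIs (0.09, 1.47) and (-0.27, 1.48) in the beneficial
  direction). Linearity in fractional serving changes is assumed.
* **Energy and BMI.** Each 12-oz serving is assigned 150 kcal (a typical
  regular soda; the source estimates do not fix this value, so every
  calorie-dependent output is conditional on it and it is configurable).
  Three BMI scenarios span the genuine uncertainty about caloric
  compensation: *strong* (all removed calories count), *moderate* (39%
  compensated, 61% net -- replacing a third of removed SSB with water, a
  third with diet drinks, a third with other caloric beverages), and *none*.
  Net calories convert to weight at 3500 kcal/lb, accrued over the first
  simulated year and then held (a static steady state; the package
  deliberately avoids committing to a dynamic energy-balance model, which is
  a documented extension point). Weight converts to BMI at the average
  height per sex (defaults 1.76 m men, 1.62 m women, configurable).
* **BMI-mediated effects.** Per unit BMI: SBP 1.43/1.24 mmHg, LDL 2.75/2.24
  mg/dl, HDL $-1.55$/$-0.77$ mg/dl, diabetes RR 1.26/1.30 (men/women),
  applied linearly (multiplicatively for the RR) to the BMI change
  (`mediated_deltas()`). No SSB effect on lipids independent of BMI is
  modelled: the evidence for such an effect being independent of adiposity
  is equivocal, which, if anything, makes the CHD projections conservative.
* **Bound selection and truncation.** Sensitivity runs pick `min`/`max` CI
  bounds for the diabetes RR and direct SBP effect simultaneously (the
  worst/best-case corners), never one at a time. Lower bounds that would
  make SSB consumption protective are truncated at zero
  (`truncate_protective()`): at the minimal corner the SBP effect survives
  in men only (0.09 mmHg), and the women's $-0.27$ bound becomes 0. The
  per-BMI-unit coefficients are not varied (their interval estimates are
  not part of the shipped configuration).

## The synthetic population

No survey microdata ship with the package; `generate_population()` instead
draws a seeded synthetic population matching declarative targets
(`population_config()`), and `validate_marginals()` checks every target
against its realisation (defaults: 2% relative for means, 0.5 percentage
points for prevalences).

* **Demographics.** Ages 35--94 (1-year resolution) with an exponentially
  decaying age pyramid (rate 0.025/year). The adult-onset outcome
  relationships motivate the lower bound; both are configurable. Sex is
  allocated by exact proportional rounding -- a design margin rather than a
  sampled quantity -- while everything else is a seeded random draw.
* **SSB consumption** is zero-inflated gamma: a 30% point mass of
  non-consumers plus a gamma (shape 1.2) among consumers, scaled to the
  target mean. Surveys report daily frequency with many non-consumers but
  publish only subgroup means, so the zero fraction and shape are modelling
  choices. Consumers are grouped into consumption deciles for cell
  aggregation (cells are age x sex x health state x SSB decile).
* **Subgroup targets** (`subgroup_profile()`): mean servings/day 0.47
  (white), 0.51 (African American), 0.59 (Mexican American), 0.70 (low
  income, <200% of the federal poverty level); diabetes prevalence 6.7%,
  11.5%, 9.2% respectively, 7.8% statewide. Two values the surveys do not
  publish had to be fixed once: the all-California SSB mean (0.50, a
  population-weighted blend of the subgroup means) and the low-income
  diabetes prevalence (8.0%, consistent with an income gradient above the
  white prevalence and with the published ordering of subgroup projections,
  whose rate drop for the low-income group falls between the Mexican
  American and African American groups). BMI means are raised in the
  subgroups with higher reported obesity burden.
* **Risk factors** (BMI, SBP, LDL, HDL) are truncated normals per sex,
  drawn independently within age/sex strata: the source surveys publish no
  correlation structure, and imposing one would manufacture information.
  Within a stratum the risk-factor means are shared across health states;
  diabetes still enters the CHD hazard as a state indicator, so the
  first-order diabetes-CHD dependence is preserved.
* **Prevalence curves.** Baseline diabetes (and CHD, default 5.5%)
  prevalence follows a log-linear age curve (slope 0.05/year) normalised so
  the population-weighted prevalence hits the scalar target; individuals are
  then assigned by Bernoulli draws, which is what makes the realised
  prevalence a genuine binomial quantity for validation.

Identical `(config, seed)` input yields a bit-identical population, and
populations round-trip through CSV with a JSON sidecar recording their
config (`write_population()` / `read_population()`).

## The disease simulation

`step_year()` advances a strata table one annual cycle with events in a
fixed order: diabetes incidence, CHD incidence (of which a fixed fraction
are MIs) plus recurrent MI in the pre-existing CHD pool, CHD death (acute MI
case fatality plus chronic CHD mortality), non-CVD death (diabetes
multiplier 1.8), then ageing. Health states are `well`, `diabetes`, `chd`,
`diabetes_and_chd`, `dead_chd`, `dead_other`; incident CHD is absorbing into
CHD history. Hazards become annual probabilities via $1 - e^{-h}$, so any
non-negative hazard yields a valid probability; negative hazards abort with
the offending stratum identified. Competing risks are resolved sequentially
within the cycle, with no half-cycle correction -- at the annual hazards
involved ($\ll 0.1$) the correction is far below the uncertainty of the
effect sizes. Person-years use a full-year convention for everyone alive at
the start of a cycle, and baseline-arm person-years are the denominators for
all rate comparisons. Total persons are conserved across alive + dead states
every cycle by construction, and tests assert it. Stroke is not simulated;
its omission slightly understates the projected benefit.

The true coefficients and case-fatality tables of the established
cardiovascular policy simulators are not public, so `hazard_model()` ships
documented Framingham-style log-linear defaults *as configuration*: a
log-linear CHD hazard in age, sex, SBP, LDL, HDL, diabetes and smoking;
log-linear diabetes incidence in age and sex; Gompertz non-CVD mortality.
Their absolute levels are explicitly treated as unknowns:
`calibrate_baseline()` rescales five per-outcome multipliers so the
simulated ten-year baseline matches anticipated case counts -- defaults
666,000 incident diabetes, 1,140,000 incident CHD, 560,000 total MI,
336,000 CHD deaths, 1,668,000 deaths for a 16-million-adult reference
population, scaled linearly to the synthetic population's size
(`calibration_targets()`). Because each count responds nearly linearly to
its own multiplier, a damped proportional fixed point (one deterministic
cohort run per sweep; the all-cause target is matched net of the CHD deaths
already produced) converges to within 0.5% in about six sweeps. Percent
changes and rate differences -- not absolute counts -- are the scientific
surface of the model.

Subgroup runs regenerate the population from the subgroup profile and
re-calibrate: the diabetes target is scaled by the subgroup-to-statewide
prevalence ratio (prevalence standing proxy for the unpublished subgroup
incidence baselines), the other targets by population size only.

Two solvers share this event structure. The default expected-value cohort
solver moves fractional counts and is fully deterministic -- grid reruns are
bit-identical. `run_microsim()` draws per-person Bernoulli transitions under
a seed and serves as the independent stochastic cross-check: the test suite
requires every cumulative tally to sit within 3 Monte-Carlo standard errors
(Poisson bound $3\sqrt{E}$, which dominates the Bernoulli-sum variance) of
the cohort expectation at $n = 10{,}000$.

## Costs

`savings_report()` values person-state-years: non-CHD diabetes years at the
diabetes unit costs, CHD years (including diabetes with co-morbid CHD) at
the CHD unit costs, by decade-of-age band. Unit costs are converted between
dollar years with a medical-care CPI series (approximate published index
levels; only ratios matter) to a 2012 base, and streams are discounted at
3%/year to 2013, the first simulated year (the discount base is an
assumption and configurable). The third category, diabetes-related CHD,
prices the averted diabetes-attributable CHD events: within diabetic cells
the excess fraction $(\mathrm{RR}-1)/\mathrm{RR}$ of CHD incidence is
attributed to diabetes, and each averted event is costed over a mean CHD
care duration (default 5 years). This is one defensible operationalisation
of "excess CHD avoided through avoided diabetes"; alternatives (e.g.
tracking flagged sub-states) would change levels, not orderings. The unit
cost defaults are documented placeholders -- the underlying state cost
surveys are not published with the model -- so the informative outputs are
the orderings across scenarios and the exact linearity in unit costs, both
of which are asserted by tests.

## Scenario grids and reporting

`run_grid()` crosses reduction levels x BMI scenarios x effect bounds x
subgroups, calibrating once per subgroup; a failing grid point is recorded
and the rest still run. `min_max_envelope()` summarises the worst/best-case
corners and checks that they bracket the main estimate for every outcome;
`subgroup_table()` assembles rate drops per million person-years.
Presentation rounding (counts to the nearest 100 or 1,000, fixed percent
decimals) happens only in `format_count()`/`format_count_percent()`; stored
values are never mutated. `load_config()` reads strict YAML overrides --
unknown keys and malformed numerics are rejected by name -- and
`run_manifest()` records config hash, seeds, package version and
calibration residuals next to every run.

## Numerical choices and degenerate inputs

* Hazard-to-probability via $1-e^{-h}$ throughout; case fatality capped at
  0.95; CHD deaths capped at the CHD pool (relevant only under extreme
  calibration multipliers).
* A zero-count population is a valid, empty result; an empty population is
  rejected by the simulator and validator with a clear message.
* Calibration aborts after 60 sweeps reporting residuals; targets must be
  positive and all-cause deaths must exceed CHD deaths.
* The consumption reduction from a tax is capped at 1; reduction fraction 0
  is the exact identity on every cell (asserted to machine precision).
* Seeds are plain integers fed to `set.seed()`; all randomness in a run
  derives from the population seed(s) and the microsimulation seed.

## Problem sizes

The shipped analyses use a 100,000-person statewide population and
50,000-person subgroup populations; the test suite uses 10,000--100,000
persons depending on what a check needs (the marginal-fidelity test at
100,000, the solver cross-check at 10,000). These sizes put sampling noise
well below the tolerances being asserted while keeping every script's
runtime in seconds; percent reductions are invariant to uniform population
scaling (asserted exactly), so population size is a precision knob, not a
result knob.

## What the synthetic data does and does not show

The generator reproduces *marginal* structure: subgroup consumption means,
prevalences, risk-factor means and dispersions, and an age pyramid. It does
not reproduce risk-factor correlations, survey weights, household or
geographic structure, secular trends (the population is closed: no ageing-in
cohorts, births or migration), or reporting biases in self-reported
consumption. Passing tests therefore demonstrate that the *method* --
cascade, simulation, calibration, costing -- behaves correctly and that the
qualitative conclusions (subgroup ordering, dose-response, envelope
bracketing) follow from the published effect sizes under a defensible
population; they do not certify the absolute Californian case counts, which
depend on proprietary model internals and microdata that are not public.
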