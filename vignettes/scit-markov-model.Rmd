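---
title: "Modelling SCIT policy scenarios with scitmodel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling SCIT policy scenarios with scitmodel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scitmodel)
```

## The model in one paragraph

`scitmodel` is a deterministic Markov cohort model of allergic rhinitis
(AR) and allergic asthma (AA) in the population aged 6–65, run in yearly
cycles from 2011 to 2050. Expected person-counts (real-valued, because a
cohort model propagates expectations, not individuals) occupy six states —
mild AR (A), moderate/severe AR (B), moderate/severe AR with mild AA (C),
severe AR with moderate/severe AA (D), healthy (E) and death (F, absorbing)
— and are stratified by age group, allergy type and treatment arm. Policy
scenarios decide, year by year, which untreated patients start a three-year
course of subcutaneous immunotherapy (SCIT); statutory-payer costs accrue
per state-year and per SCIT therapy-year, are discounted to 2011, and
scenarios are compared by their incremental cost-effectiveness ratio
against the status quo.

## States, strata and the yearly cycle

Severity is ordered A < B < C < D; C and D are the asthma states, E and F
sit outside the severity order. A stratum is one sub-cohort
`(age group, allergy type, arm)`: children 6–12, adolescents 13–18, adults
19–65; seasonal or perennial disease; arms `ST` (symptomatic therapy),
`SCIT1`–`SCIT3` (the three therapy years) and `POST` (completed course).
Transition dynamics differ by age group, allergy type and SCIT-vs-ST, i.e.
12 distinct 6×6 matrices cover the 30 strata; the three SCIT years share
one matrix, and `POST` follows the ST matrix.

Each modelled year after the base year executes, in order:

1. therapy-year promotion (`SCIT3 -> POST`, `SCIT2 -> SCIT3`,
   `SCIT1 -> SCIT2`);
2. one Markov cycle per stratum, $v_{t+1} = v_t P$;
3. ageing between groups: uniform-age fractions 1/7 of children,
   1/6 of adolescents move up, 1/47 of adults leave the modelled age range
   (all states alike — the Markov state space does not carry single ages,
   so a uniform-age approximation replaces explicit age book-keeping);
4. insertion of the year's calibrated incident entrants;
5. SCIT allocation for the year;
6. cost accrual on end-of-year occupancy, discounted to the base year.

No half-cycle correction is applied anywhere: occupancies and costs are
end-of-cycle quantities. That is a deliberate simplification — with 40
yearly cycles and smooth trajectories, the half-cycle offset shifts levels
slightly but cancels almost entirely in the scenario *differences* that the
cost-effectiveness results are built from.

## Parameters, units, defaults

| parameter | unit | default | origin |
|---|---|---|---|
| AR prevalence (chi/ado/adu) | proportion | 0.047 / 0.169 / 0.1795 | published point values |
| AA prevalence (chi/ado/adu) | proportion | 0.036 / 0.057 / 0.039 | published point values |
| seasonal share | proportion | 0.60 | published point value |
| state costs A–D | Euro/person-year | 27/119/282/446 (chi), 18/97/259/442 (ado), 8/79/227/442 (adu) | published point values |
| SCIT cost, preseasonal | Euro/year | 262 / 262 / 262 | published prices |
| SCIT cost, perennial | Euro/year | 502 / 480 / 480 | published prices |
| discount rate | /year | 0.02 | published point value |
| 2011 supply rates | proportion | seasonal 0.05/0.15/0.20, perennial 0.05/0.10/0.20 | published expert consensus |
| transition matrices | probability/year | synthetic generator | **not published — synthetic** |
| prevalent-pool severity splits (A:B, C:D) | proportion | 0.5 : 0.5 | **not published — synthetic** |
| onset-state split of new cases (A:B) | proportion | 0.5 : 0.5 | **not published — synthetic** |

The default SCIT drug cost charges every treated patient the arithmetic
mean of the preseasonal and perennial price — 382 Euro in therapy year 1
and 371 Euro in years 2–3, which is exactly how the published mean values
arise ((262+502)/2 = 382). A `mean_mode = "by_type"` switch instead prices
seasonal strata preseasonally and perennial strata perennially, for
sensitivity analyses weighted by the 60/40 split.

Probabilistic sensitivity analysis draws each parameter independently and
uniformly from its published range (e.g. discount 1.5–2.5% p.a., children
AR prevalence 3–7%). Uniform is the least-informative distribution
consistent with printed bounds; nothing beyond the bounds was published.
Parameters are drawn once per replicate and held constant over the 40
years. Transition-matrix perturbation is available
(`transition_perturbation` scales a multiplicative row jitter followed by
renormalisation) but defaults to off, since no dispersion for the
transition probabilities is on record.

## What the synthetic generators emulate — and what they do not

Two of the model's inputs exist only in non-public form, so the package
generates stand-ins that are tagged `provenance: "synthetic"` in every
parameter object and output file.

**Population projection.** `generate_population_projection()` produces a
2011–2050 × age 0–100 table whose population under risk follows a chosen
geometric trend exactly, optionally with a youth-declining age profile
(ages 6–18 shrinking 1%/year faster than 19–65) to mimic an ageing
population. The desk fixture uses 64 million persons aged 6–65 and a
−0.4%/year youth-declining trend — a plausible stylisation of the German
demographic outlook of the early 2010s. It does *not* reproduce the real
single-age structure, migration or birth dynamics; only the monotone trend
matters to the model, because incidence is calibrated against it.

**Transition matrices.** `default_transition_params()` builds yearly
matrices from field-plausible base rates (worsening 6–10%/year along
A→B→C→D, one-step improvement 4–5%, remission to E of 1–6%, small relapse
from E, small absorbing mortality) modified by age group and allergy type,
with SCIT matrices derived from ST by scaling remission up
(×(1 + 2·effect), improvement ×(1 + effect)) and progression/relapse down
(×(1 − 0.7·effect)). The construction guarantees: `effect_size = 0` makes
SCIT identical to ST; remission under SCIT is monotone in `effect_size`;
every matrix is row-stochastic with absorbing death. The default
`effect_size = 0.5` encodes a clearly beneficial but not curative therapy,
which reproduces the expected qualitative scenario ordering (wider
eligibility ⇒ fewer diseased). What passing tests show, therefore, is that
the *machinery* is correct under dynamics with the right structure — not
that absolute patient numbers or cost levels match any real population.
The published headline aggregates depend on the unpublished inputs and are
treated as qualitative calibration references only.

## Calibration, numerics and degenerate inputs

**Incidence calibration.** The model's incidence assumption is that without
SCIT the diseased total tracks the population under risk:
$D_y / D_{2011} = N_y / N_{2011}$. `calibrate_incidence()` realises it by a
fixed-point iteration in Gauss–Seidel form: each sweep simulates the
no-SCIT baseline forward and sets each year's entrants to the residual
against that year's target before moving on. Because entrants inserted in
year *y* count towards year *y*'s total directly, one sweep lands on target
whenever the non-negativity clamp does not bind, and the verification run
confirms convergence (tolerance 0.5% relative, maximum 100 iterations; a
requested tolerance of exactly 0 is rejected as unattainable). Entrants are
clamped at zero — if natural dynamics leave *more* diseased persons than
the target, negative incidence would be required and calibration reports
non-convergence rather than inventing it. New cases enter the children
strata in states A/B (configurable split): onset at the youngest modelled
ages, with ageing carrying them into the older groups.

**Other numerical choices.** Transition matrices are validated to row sums
within 1e-9 and absorbing death; cohort propagation conserves totals to
machine precision because it is a plain matrix product. Supply rates are
linear between the 2011 and target-year values and constant afterwards.
Zero prevalence, zero incidence, empty strata and degenerate (point) PSA
ranges are all legal inputs and produce exact zeros rather than special
cases. Monetary summary tables round to integer Euro; per-year CSVs keep
full precision. PSA replicates use deterministic per-replicate sub-seeds,
so a longer run extends a shorter one replicate-for-replicate and all
scenarios within a replicate share one parameter draw and one recalibrated
incidence schedule (common random numbers — scenario differences are never
sampling noise).

## Design choices where the design was open

* **Stock vs. flow supply rates.** "Proportion of patients receiving SCIT"
  is ambiguous. The default reads it as a yearly *flow*: the rate applies
  to the currently untreated (ST) pool in eligible states. Re-treating the
  same stock each year would overcount three-year courses as the rate
  ramps. A `allocation = "stock"` switch implements the other reading
  (top up the treated share to the rate) for sensitivity.
* **One course per patient.** Completers move to a dedicated `POST` arm
  with ST dynamics, no drug cost and no re-eligibility. A plain return to
  the ST arm would silently re-treat them under flow allocation.
* **AR/AA overlap.** AA patients also have AR, and the asthma states C/D
  include AR; AA-prevalent persons are therefore placed in C/D and
  subtracted from the AR count to avoid double-counting, leaving AR-only
  persons in A/B.
* **"Healed" as prevalence difference.** The effect measure is the
  difference in mean yearly occupancy of state E versus the status quo
  (healed and avoided cases are the same aggregate in this accounting).
  An incidence-style alternative (newly healed per year) would need a flow
  decomposition the state totals do not determine uniquely.
* **Mean-annual figures are discounted.** Reported means average the 40
  discounted yearly values, keeping the cost differences and the ICER on
  one consistent present-value scale; `report_undiscounted = TRUE` switches
  the basis.
* **SCIT cost while healed or dead.** Persons in a SCIT arm who reach E
  continue (and pay for) the course to completion; persons who die stop.
* **Interface.** The package's surface is R functions plus the
  configuration and report writers (`run_report()`, `psa_report()`,
  `icer_table()`, `write_model_config()`); its users script analyses in R,
  so no shell entry point is shipped.

## Problem sizes used by the test suite

The bundled fixtures are sized for exact checking rather than realism: the
`toy` configuration (3 years, one populated age group, 1,000 persons per
single age) is small enough to verify trajectories against hand-written
matrix products, and the `desk` configuration runs the full 2011–2050
horizon with all strata. The test suite exercises the PSA at 50 replicates
on the desk fixture — dispersion estimates stabilise enough there to check
bounds and monotonicity, while the reference analysis's 1,000 replicates
remain the package default for real use.

## Known limitations

* Transition probabilities and the demographic projection are synthetic;
  absolute outputs are not estimates for Germany.
* No migration, sex stratification, contraindication modelling (severe
  asthma), indirect/societal costs, or outpatient visit costs (excluded
  under the payer perspective, where outpatient budgets are capitated).
* Uniform-age ageing fractions approximate cohort ageing; single-age
  structure inside the state space is not carried.
* Severity splits of the prevalent pool and of incident cases are
  unpublished; results that depend on them (notably the scenario-3/4
  eligibility effects) should be read through the sensitivity switches.

```{r example, eval = FALSE}
params <- make_fixture_config("desk", seed = 1)
results <- run_scenarios(builtin_scenarios(), params)
compare_to_status_quo(results)
run_psa(builtin_scenarios(), params, n_reps = 1000, seed = 1)
```
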