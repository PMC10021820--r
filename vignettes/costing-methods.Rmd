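---
title: "Ingredient-based incremental costing: model, assumptions and design choices"
author: "pencost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ingredient-based incremental costing: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pencost)
```

## The costing model

`pencost` implements bottom-up, ingredient-based incremental costing
for a multi-protocol primary-care NCD-prevention program piloted in two
districts. *Incremental* means only expenditure introduced specifically
for the program is counted — the facility's pre-existing activities are
outside the boundary, as are hospitality expenses and the laboratory
analysis of cancer-screening samples. Every ledger item is tagged by
institutional level (national ministry vs district), accounting
category (capital vs recurrent), item kind, and the protocols it serves
(one, several, or non-specific overhead).

The annualization rules are:

* **Equipment.** A purchase of $u$ units at unit cost $c$ with useful
  life $L$ years becomes an annual cost $uc / a(L, r)$, where
  $a(L,r) = \frac{(1+r)^L - 1}{r(1+r)^L}$ is the present value of a
  unit annuity — equivalently, $uc$ times the capital recovery factor.
  The default discount rate is $r = 0.10$/year. $L$ may be non-integer
  (the formula is defined for real $L$); at $r = 0$ the factor is the
  analytic limit $L$, i.e. straight-line depreciation. The
  implementation uses the `expm1`/`log1p` form, which is stable as
  $r \to 0$ where the naive expression cancels catastrophically.
* **Supplies.** Expenditure observed over the pilot window of $m$
  months is scaled by $12/m$. The pilot window defaults to 13 months
  (February 2016 through March 2017, both inclusive); the program's own
  reports never state the month count they used, so it is a
  configurable constant.
* **Retraining and material revision.** Divided by the 5-year revision
  cycle, then — being ministry expenditure — by the number of medical
  universities.
* **National apportionment.** All national-level items are divided by
  62, the number of Universities of Medical Sciences, so each district
  carries one university's equal share. The operation errors on
  district-level items rather than silently passing them through.
* **Personnel.** For each provider role (physician, midwife, community
  health worker), the mean observed per-visit task time $\bar t$ times
  average daily visits $v$ over the working day $W$ (default 480 min)
  gives the worktime fraction $f = \bar t v / W$; the program's annual
  salary bill for a roster row is $f \times \text{salary} \times 12
  \times \text{headcount}$. Fractions above 1 are clamped to 1 with a
  warning: over-allocation signals noisy timesheets, not an invalid
  pipeline state.

Cost classes follow the coverage-dependence rule: supplies and
personnel are **variable**, everything else **fixed**. Equipment is
arguably semi-variable; it is held fixed over the implementation
horizon, an assumption inherited from the program's own accounting.

### Protocol attribution

Specific items land on their protocol. Items tagged with several
protocols (shared supplies such as disposable gloves) are split equally
*between those protocols only*. Non-specific overhead — introduction,
supervision, customization, consultancy — is split equally across all
five protocols. Personnel cost is attributed to protocols in proportion
to each role's total observed service-minutes per protocol; the program
documentation states that task times attribute staffing cost to
protocols but gives no formula, and proportionality to observed minutes
is this package's design choice (it conserves role totals exactly and
is invariant to observation order). Equipment with no protocol tag at
all is treated as non-specific with a warning rather than an error,
since the published allocation rule is silent on that case.

Two bookkeeping choices worth knowing: the ledger kind `meeting` folds
into the consultancy column when capital (the initial
meetings/workshops/consultancy family) and into recurrent supervision
when recurrent (the annual meetings family), because the published
breakdown has no separate meetings column; and `supervision` keeps
distinct capital and recurrent columns, as in the published table. A
`personnel` ledger row is rejected: personnel cost is derived from
task-time observations, never read from the ledger.

### Per-capita costs

Fixed costs are divided by the eligible population, variable costs by
the covered population, per protocol; protocol totals are reported with
and without the introduction component, which is a one-off cost of the
first implementation year. The default denominator mode gives each
protocol its own eligible/covered pair (protocols target different
demographics — female cancers most obviously); a single program-wide
pair is available as `mode = "program_denominators"`. Internal
arithmetic is at full floating precision; rounding to 2 decimals
happens only in the CSV report writers, because several published cells
are visibly truncations rather than roundings (e.g. 1979.39/5 =
395.878 printed as 395.87) — which is also why comparisons against
printed cells throughout the tests use an absolute ±0.01 band.

## Coverage estimation

Coverage is defined as the share of eligible individuals who used at
least one program service. The survey design is two-stage stratified
cluster sampling: within each district, 25 clusters are allocated to
the urban and rural strata proportionally to population using
largest-remainder (Hamilton) rounding — the program description says
only "proportional", and largest-remainder with ties broken toward the
larger stratum is this package's choice — then blocks are drawn at
random within strata and 10 families invited per block, interviewing
every eligible family member. The estimator is the plain ratio of
users to eligible respondents, exactly as the coverage definition
states: no design weights, no finite-population correction (none are
described by the program). A weighted variant exists behind
`weighted = TRUE` but is off by default.

The published overall coverage (40.74%) does not equal the ratio of the
published counts (265 users / 637 eligible = 41.60%), and no weighting
scheme reconciling them is documented; the package implements the
stated definition and leaves the discrepancy as a property of the
source report. Randomness flows from one integer seed through
deterministic per-cluster substreams, so enlarging a design by one
cluster never perturbs the draws of earlier clusters.

## The synthetic scenario generator

The generator's role is to make every stage verifiable without any
external data. A scenario fixes the study conditions: two districts
with urban/rural strata; five protocols; per-protocol annual cost
levels for supplies, personnel and equipment; overhead totals;
direct-observation design (2 urban + 2 rural sites per district, 10–20
patients per site in the stochastic design); per-visit time
distributions (lognormal, parameterized by mean and coefficient of
variation — positive and right-skewed, as service times are); and a
survey frame of postal blocks with per-protocol eligibility fractions
and a true usage probability.

Ground truth is closed-form (`expected_outputs()`), never simulated:
category cells are the configured levels plus equal splits of overhead,
per-capita values follow from the scenario's denominators, and true
coverage is the configured usage probability. Two generator regimes
matter:

* **Degenerate** (`time_cv = 0`, balanced observation design: one
  observation per site × role × protocol): realized task-time means and
  protocol minute-shares equal their expectations exactly, so the full
  pipeline must reproduce `expected_outputs()` to floating-point
  round-off (the end-to-end recovery tests assert 1e-6).
* **Stochastic** (`time_cv > 0`, 10–20 patients per site with uniformly
  sampled role and protocol): outputs converge to the ground truth as
  sample sizes grow but individual runs vary.

The per-protocol true mean task time is `time_scale_minutes` × the
protocol's share of the personnel total (default scale 60 minutes,
giving means of roughly 3–18 minutes per visit across protocols, with
an all-protocol mean of 12 minutes — realistic primary-care visit
lengths), which makes the minutes-proportional personnel attribution
analytically invertible. Provider headcounts default to 48 per
district-stratum roster row (≈ 192 providers program-wide, matching the
scale of the pilot's roster); salaries are back-solved from the
scenario's personnel targets rather than configured directly.

What the generator does **not** emulate: the real microdata's
distributions (unpublished), demand seasonality (the costing assumes
constant visit demand throughout, as the program's own analysis did),
geographic structure beyond strata, and item-level price heterogeneity.
Passing recovery tests therefore demonstrates the pipeline's arithmetic
and allocation logic, not the field realism of any particular input.

### Calibration to the published program

`pen_scenario_published()` loads a scenario whose category cost levels are
the published annual totals of the two-district pilot, with degenerate
times. The published per-capita table cannot be inverted directly: its
per-protocol component cells do not sum to its printed protocol totals
(the MI & stroke components sum to ≈ 12.27 against a printed total of
7.45), back-solved denominators differ across cells within one
protocol, and the eligible/covered counts were never published. The
package therefore reproduces only the internally consistent arithmetic
— category totals, shares, equal-split overhead cells, and program
totals as sums of protocol totals — and `calibrate_denominators()`
closes the underdetermined per-capita system with one assumption: a
single program-wide coverage ratio $\rho = C_k/E_k$ for every protocol,
solved by `uniroot` so that the per-capita introduction components sum
to the published gap between the with- and without-introduction program
totals (0.42), giving $E_k = (V_k/\rho + F_k)/t_k$. The solution,
$\rho \approx 0.76$ with eligible populations of roughly 32–60
thousand per protocol, satisfies $C_k \le E_k$ everywhere; counts are
rounded to integers, shifting per-capita totals by well under the 0.01
comparison band. Two published figures also disagree with each other at
the cent level (the per-capita table's total row reads 24.91/25.33
against column sums of 24.90/25.32; the report's abstract gives category
shares 74.97%/15.76% against the table's 74.98%/15.77%): rounding
accumulation in the source, and the package follows the table/column-sum
orientation in both cases.

## Numerical and degenerate-input choices

* Equal splits conserve totals exactly (division happens once, no
  per-share rounding); conservation is tested to 1e-6 on random
  ledgers.
* A zero discount rate, zero-cost items, empty ledgers, and all-zero
  breakdowns are all defined (zero results), but a positive variable
  cost with zero covered population, a zero grand total in share
  computation, and a missing denominator for a protocol with nonzero
  cost are errors — each signals a misconfigured run, not a boundary
  case to smooth over.
* Currency conversion is guarded by a per-row currency tag so no value
  can be converted twice; all downstream arithmetic is in USD.
* Ledger validation collects all invariant breaches into a report
  (duplicated ids are warnings); the pipeline refuses to run while
  errors are present.

## Problem sizes used in the test suite

The recovery tests run the full pipeline on the calibrated scenario
(32 ledger items, 120 balanced observations, 12 roster rows). The
estimator-unbiasedness check simulates 2000 replicate surveys of 25
clusters × 10 families (≈ 500 eligible respondents each) against a true
usage probability of 0.40, asserting the Monte-Carlo mean lies within 3
standard errors of the truth; the frame's eligibility structure is held
fixed while usage and the sample draw are redrawn each replicate, which
keeps the estimator exactly unbiased by construction and the simulation
inexpensive.

## Known limitations

* The calibrated per-capita denominators are a modelling closure,
  not data; any downstream use of the absolute eligible/covered counts
  should treat them as illustrative.
* Coverage variance (cluster-robust standard errors) is out of scope;
  the package reports point estimates only.
* Only equal-split apportionment is implemented; activity-based or
  usage-weighted allocation of overhead is not.
* One currency pair (IRR→USD) at one fixed rate; no inflation or PPP
  adjustment.
```{r}
sessionInfo()
```
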