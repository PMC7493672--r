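---
title: "Modelling chronic-care patient journeys: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling chronic-care patient journeys: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carejourney)
```

## The model

`carejourney` implements a generic operational model of how a regional
population of chronically ill patients flows through a care network and
what that flow costs. Five entities define a model:

* **Demand.** The patient population is partitioned into mutually
  exclusive *demand segments* — disease/treatment stages that share a
  common demand for services. In the bundled Type 2 Diabetes model these
  are: at-risk (DS1), lifestyle treatment (DS2), lifestyle plus oral
  medication (DS3), insulin therapy (DS4), and complicated disease under
  hospital specialist care (DS5). Regional demand is a population count
  and an annual incidence of newly diagnosed patients.
* **Services and service elements.** A *service element* is the atomic
  delivery unit (a follow-up visit, a lab analysis, a dispensed pill)
  with fixed per-delivery resource requirements in minutes or items. A
  *service* bundles element usages, each with an annual recommended
  frequency and a *utilization rate* — the fraction of patients in the
  segment who actually receive it, capturing behaviour such as no-shows.
* **Structure.** Resources are typed (human, facility, device,
  consumable) and priced per minute or per item. A joint visit delivered
  by a GP/practice-nurse pair is modelled as a single composite resource
  with its own tariff, because that is how such visits are priced.
* **Behaviour and outcomes.** Each segment may carry declared outcome and
  behaviour profiles (satisfaction 1–7, self-rated health 0–100, %
  HbA1c in control, % smokers, ...). Scales are metadata; values are
  validated against them and never rescaled implicitly.
* **Transitions.** An annual stochastic matrix over segments plus
  absorbing states (at minimum `exit`; in the diabetes model also DS5,
  since specialist care is outside the primary-care scope but referral
  volumes remain reportable). Only leaving probabilities are stored; the
  stay probability is implied as the remainder, which makes rows that sum
  past one a validation finding rather than a silent modelling error.

## Costing

Costs follow activity-based costing with service elements as the
activities. For one element usage and one required resource,

$$q = \text{frequency} \times \text{utilization} \times
      \text{quantity per delivery},$$

rounded **half-up to a whole unit** (minute or item), then priced at the
resource's unit cost; element costs sum resource costs, service costs sum
element costs, and so on up the hierarchy. Every aggregation level
conserves cents exactly: a node's cost is by construction the sum of its
children's.

The whole-unit rounding convention is load-bearing, not cosmetic. In the
diabetes model the diet consultation in maintenance care (1/year at 10%
uptake, 45 min) yields 4.5 → 5 expected minutes and foot care 0.5 → 1
minute; with rounding the maintenance service totals €53.10 per
patient-year, without it €52.69. Both conventions are first-class
(`round_quantities = FALSE`), rounding is the default because it is the
accounting actually used for the published worked figures. Currency is
held as integer cents internally and rendered with two decimals, so
element- and service-level totals are exact.

Resources without a published tariff (oral medication, insulin, test
kits in the bundled model) are *uncosted*: they contribute zero and set a
`partial` flag on every enclosing total. A partial cost is therefore
visible as a lower bound, never silently read as complete — which is also
why the published annual costs of the medication-bearing segments (€419
and €1666) are not reproducible from the model and are carried only as
observed profile data.

Two segment-cost modes exist because the source accounting and the
transition model imply different tenure weights:

* `deterministic` (default) time-weights the scheduled services over the
  declared expected tenure: DS2 spends 1 of 3 years in the diagnosis
  service and 2 in maintenance, giving
  $(276.12 + 2 \times 53.10)/3 = 127.44$ €/patient-year.
* `markov` weights tenure years by the geometric sojourn implied by the
  annual leaving probability (DS2: first-year weight $0.375 = 1/2.667$),
  giving €136.73. The declared mean durations (3/9/10 years) and the
  geometric means implied by the transition rows (2.67 years for DS2) are
  mutually inconsistent in the source material; the package carries both
  and documents rather than resolves the tension. Deterministic mode
  drives cost reproduction, markov mode drives projection.

Journey costs sum expected years per segment times segment annual cost.
The deterministic journey follows the main progression pathway (from
each segment, its most probable onward segment) with declared durations;
the markov journey uses the absorbing-chain expected visits.

Regional costs are straight products of patient counts and per-patient
costs, cents-exact. The published regional cost column for the diabetes
model is internally inconsistent with its own per-patient totals
(911 × €276.12 = €251,545.32, not the printed regional figure), so the
engine reports the product and the printed regional totals are not
reproduction targets.

## The cohort engine

The time step is one year: services are consumed during a year of
occupancy, transitions apply at year end, entrants join at year start.
Segments with phased schedules (a distinct first-year package, e.g.
insulin stabilization in DS4) are expanded into tenure year-states;
staying advances the phase, leaving probabilities are identical across
phases, so marginalizing phases recovers the segment-level matrix exactly
— a property the tests check row by row.

On the expanded chain with transient submatrix $Q$:

* mean sojourn in a segment is $1/\sum(\text{leaving probabilities})$
  (geometric);
* expected years per state for one entrant solve
  $(I - Q^\top)v = e_{\text{entry}}$ (fundamental matrix; a linear
  solve, never a simulation);
* steady-state occupancy under constant incidence solves the balance
  equations $(I - Q^\top)x = \text{inflow}$ and equals incidence ×
  expected visits (Little's law) as well as the limit of the year-by-year
  projection — both identities are tested on randomly generated models;
* the projection conserves patients at every year: cumulative inflow
  equals transient occupancy plus cumulative absorptions (within
  $10^{-9}$ relative).

A singular system (a state with no path to absorption) is reported as an
immortal-state error; the validator flags the same condition structurally
before any computation.

## Microsimulation as the oracle

`simulate_trajectories()` advances each patient annually by sampling the
expanded-chain row; `simulate_service_use()` delivers each element of the
occupied state's service with probability equal to its utilization rate.
Utilization is interpreted as an annual all-or-nothing block (a patient
takes all `frequency` deliveries or none), matching how a recommended
frequency pairs with a user-level uptake percentage; a per-delivery
Bernoulli option exists and has the same expectation. Realized use is
priced per delivery without expectation rounding, so at 100% utilization
the realized cost equals the un-rounded closed form exactly.

Every deterministic output has a stochastic counterpart that must agree
with it within three standard errors: geometric sojourn means, expected
years per segment, markov segment costs, realized service costs, and the
transition matrix itself (maximum-likelihood row frequencies from
simulated trajectories, tenure phases marginalized back to segments).
The test suite runs these at $n = 10^5$ patients for the bundled model
and on randomly generated models (2–6 segments, leaving probabilities in
[0.05, 0.95], 1–5 elements per service, unit costs €0.10–2.00/min) under
fixed seeds; one explicit seed per run makes every simulation output
bit-reproducible.

What the simulation does *not* emulate: individual covariates, risk
equations, time-varying transition rates, competing risks beyond the
annual matrix, or behaviour change. Passing tests therefore show
arithmetic and distributional self-consistency of the engine, not
clinical validity of any particular model fed to it.

## Conventions and open choices in the bundled diabetes model

* **Population figure.** The regional population appears in the source
  material both as 443,109 and 443,281; the model uses 443,281, the
  figure consistent with the published incidence (0.21%) and prevalence
  (2.76%) percentages.
* **Transition rows.** Only the DS2 row (0.313 to DS3, 0.05 to DS5,
  0.012 exit) is published. The DS3 and DS4 rows are placeholders flagged
  `assumed` in the model file: their total leaving probabilities are the
  reciprocals of the declared mean stage durations (1/9 and 1/10), with
  0.01 each to specialist referral and exit and the remainder to
  progression. They affect markov-mode projections only.
* **Professional hours.** `include_lab = TRUE` (default) counts
  laboratory minutes as professional care alongside human resources;
  this reproduces the published 3.1 h/patient-year for DS2
  ((406 + 78 + 78 minutes)/3 years). The published DS3/DS4 hours match
  no single lab-inclusion convention and are not asserted. Items (pills,
  kits) never count as professional time. Hours report to one decimal,
  rates to two (period decimal separator).
* **Zero-usage elements.** Two defined elements carry no recommended
  frequency in any service (the GP-office lab test and generic
  specialized care); they ship with zero usage so the catalogue stays
  complete without affecting costs. An uncosted resource with zero
  expected quantity does not raise the partial flag.
* **Entry and DS1.** Entrants enter DS2 at diagnosis. DS1 (at-risk,
  screening) is modelled as a segment outside the transition chain; it
  can be wired in as a pre-segment but is off by default since the
  documented flow covers DS2–DS5.
* **Observed segment counts** (2687/8084/1451) are registry pass-through
  data: they are reported in `segment_report()` but are not — and do not
  match — steady-state arithmetic from the published DS2 row, so they are
  never used as a reproduction target.

## Problem sizes

The test suite uses $10^5$ simulated patients (about $1.7 \times 10^6$
patient-years) for the bundled-model microsimulation checks,
$2 \times 10^4$ patients for random-model property checks, and up to
$10^6$ draws for the independent geometric oracles; the whole suite runs
in well under a minute on one core. These sizes put three standard
errors at roughly 0.3–1% of the checked quantities, comfortably below
the smallest modelling effect the package distinguishes.

## Limitations

No discounting, inflation or currency conversion; no payer/tariff
modelling; no age/sex stratification; no geographic travel modelling; no
inferential statistics on outcome differences (group values are reported
as given). The engine models expected flows and costs of a declared
care-delivery design — it does not estimate that design from data beyond
the transition-matrix recovery used as a consistency check.
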