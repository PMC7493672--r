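# carejourney

An R engine for **operational models of chronic-care patient journeys**:
capacity and cost planning for a regional care network, built from five
declarative entities — demand (patient segments), services, structure
(resources), behaviour (utilization rates), and outcomes.

A model declares:

- **resources** with unit costs (e.g. a GP at €1.10/min, laboratory at
  €0.42/min); resources without a published tariff are legal and flagged
  *uncosted*;
- **service elements**, the atomic deliveries (a follow-up visit = 20 min
  of GP & practice-nurse time), composed into **services** with annual
  frequencies and utilization rates (the fraction of patients who actually
  take up a recommended element);
- **demand segments** — disease/treatment stages — each with a
  tenure-phased service schedule (e.g. one diagnosis year, then open-ended
  maintenance care) and optional outcome/behaviour profiles;
- an **annual Markov transition model** between segments with absorbing
  states (specialist referral, exit), the stay probability implied as one
  minus the leaving probabilities;
- **regional demand**: population, annual incidence, prevalent patients.

From this the package computes, by activity-based costing and the
absorbing-chain closed forms:

- expected annual quantities and costs per element, service, segment-year,
  full patient journey, and region (`expected_annual_quantity()`,
  `service_annual_cost()`, `segment_annual_cost()`, `journey_cost()`,
  `region_annual_cost()`); expected annual minutes/items are rounded
  half-up to whole units before pricing (switchable);
- sojourn times, tenure-expanded cohort projections, steady states and
  expected journey occupancies (`mean_sojourn()`, `expand_tenure()`,
  `cohort_project()`, `steady_state_occupancy()`, `expected_visits()`);
- professional-care hours, regional resource loads,
  incidence/prevalence rates, sojourn-weighted outcomes and a per-segment
  summary table (`professional_hours()`, `resource_load()`,
  `demand_rates()`, `journey_outcome()`, `segment_report()`);
- individual-level microsimulation of trajectories and realized service
  use, plus maximum-likelihood recovery of the transition matrix — the
  stochastic cross-check for every closed-form result
  (`simulate_trajectories()`, `simulate_service_use()`,
  `estimate_transition_matrix()`).

The package ships a complete worked model of **Type 2 Diabetes primary
care** in the Dutch NWN&DWO region (care group ZEL, reference year 2009),
both as code (`t2d_model()`) and as a YAML file
(`inst/extdata/t2d_nwn_dwo.yaml`) that doubles as the schema example.

## Worked example

```r
library(carejourney)
m <- t2d_model()   # or read_care_model("inst/extdata/t2d_nwn_dwo.yaml")

cost_total(service_annual_cost(m, "S2"))   # 276.12  (diagnosis year)
cost_total(service_annual_cost(m, "S3"))   # 53.1    (lifestyle maintenance)
cost_total(segment_annual_cost(m, "DS2"))  # 127.44  (= (276.12 + 2*53.10)/3)
professional_hours(m, "DS2")               # 3.1     (hours/patient/year)
mean_sojourn(m, "DS2")                     # 2.666667 years
demand_rates(m)
#> incidence:  0.21% (910 new patients / 443,281 population / year)
#> prevalence: 2.76% (12218 patients / 443,281 population)
```

A patient diagnosed into segment DS2 (lifestyle treatment) costs €276.12
in the one-year diagnosis service and €53.10/year in maintenance care, so
the segment averages €127.44 per patient-year over its 3-year expected
tenure, consuming 3.1 hours of professional care per patient-year. The
DS2 transition row (0.313 to oral medication, 0.05 to specialist care,
0.012 exit) implies a mean geometric sojourn of 2.67 years.

Cohort planning and simulation:

```r
p <- cohort_project(m, incidence = 910, horizon = 30)
plot(p)                                     # occupancy per segment
steady_state_occupancy(m, 910)              # long-run expected counts
tr <- simulate_trajectories(m, n = 10000, horizon = 100, seed = 1)
estimate_transition_matrix(tr)$rows$DS2     # recovers ~0.313 / 0.05 / 0.012
```

A command-line driver wraps the same functions
(`validate`, `cost`, `project`, `simulate`, `report`):

```sh
Rscript $(Rscript -e 'cat(system.file("cli/carejourney.R", package="carejourney"))') \
  cost inst/extdata/t2d_nwn_dwo.yaml --service S2 -o s2.csv
```

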