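Package: carejourney
Title: Operational Modelling of Chronic-Care Patient Journeys
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A declarative engine for operational models of chronic-care
    delivery networks. A model defines demand segments of a patient
    population, services composed of resource-consuming service elements,
    activity-based costs, and an annual Markov transition model over
    disease stages. The package computes expected per-patient and regional
    costs, professional-care hours, sojourn times, cohort occupancy
    projections and steady states, simulates individual patient
    trajectories and service use as a stochastic cross-check, and ships a
    fully worked Type 2 Diabetes primary-care model. Models are read from
    and written to a documented YAML schema; results export as CSV/JSON,
    and a command-line driver wires the pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    yaml,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
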