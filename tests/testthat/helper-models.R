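# Small hand-built models used across tests.

# One segment, one open-phase service costing `annual_eur` per patient-year
# (one element, one resource, frequency 1, utilization 1), annual leaving
# probability `leave` straight to exit.
toy_single_segment <- function(leave = 0.25, annual_eur = 10,
                               total_duration = 4, outcome = NULL) {
  care_model(
    resources = list(list(id = "R1", name = "Staff", kind = "human",
                          cost_basis = "per_minute",
                          unit_cost_cents = 100)),
    elements = list(list(id = "E1", name = "Visit",
                         requirements = data.frame(resource = "R1",
                                                   quantity = annual_eur,
                                                   stringsAsFactors = FALSE))),
    services = list(list(id = "S1", name = "Care",
                         usages = data.frame(element = "E1", frequency = 1,
                                             utilization = 1,
                                             stringsAsFactors = FALSE))),
    segments = list(list(id = "G1", name = "Only segment",
                         schedule = list(
                           phases = data.frame(service = "S1",
                                               years = NA_real_,
                                               stringsAsFactors = FALSE),
                           expected_total_duration = total_duration),
                         outcomes = outcome, behaviors = NULL)),
    transitions = list(entry = "G1", states = "G1", absorbing = "exit",
                       rows = list(G1 = c(exit = leave)),
                       assumed = character(0)),
    region = list(population = 1000, annual_incidence = 10,
                  total_patients = 100, observed_segment_counts = NULL),
    metadata = list(name = "toy", currency = "EUR", year = 2026))
}

# Forward chain A -> B -> exit. Leaving A splits between B (p_ab) and exit
# (p_a_exit); B leaves to exit with p_b. Annual service costs in euros.
toy_two_segment <- function(p_ab = 0.3, p_a_exit = 0.1, p_b = 0.25,
                            cost_a = 10, cost_b = 40,
                            outcome_a = NULL, outcome_b = NULL) {
  svc <- function(id, eur) list(
    id = id, name = id,
    usages = data.frame(element = paste0("E", id), frequency = 1,
                        utilization = 1, stringsAsFactors = FALSE))
  elem <- function(id, eur) list(
    id = paste0("E", id), name = paste0("E", id),
    requirements = data.frame(resource = "R1", quantity = eur,
                              stringsAsFactors = FALSE))
  seg <- function(id, s, total, outcome) list(
    id = id, name = id,
    schedule = list(phases = data.frame(service = s, years = NA_real_,
                                        stringsAsFactors = FALSE),
                    expected_total_duration = total),
    outcomes = outcome, behaviors = NULL)
  care_model(
    resources = list(list(id = "R1", name = "Staff", kind = "human",
                          cost_basis = "per_minute", unit_cost_cents = 100)),
    elements = list(elem("SA", cost_a), elem("SB", cost_b)),
    services = list(svc("SA", cost_a), svc("SB", cost_b)),
    segments = list(seg("A", "SA", 3, outcome_a), seg("B", "SB", 4, outcome_b)),
    transitions = list(entry = "A", states = c("A", "B"),
                       absorbing = "exit",
                       rows = list(A = c(B = p_ab, exit = p_a_exit),
                                   B = c(exit = p_b)),
                       assumed = character(0)),
    region = list(population = 1000, annual_incidence = 10,
                  total_patients = 100, observed_segment_counts = NULL),
    metadata = list(name = "toy2", currency = "EUR", year = 2026))
}

# Recursively check the cost-conservation invariant: every node with
# children has cost exactly equal to the sum of its children's costs.
expect_cost_conservation <- function(bd) {
  walk <- function(node) {
    if (length(node$children)) {
      kids <- sum(vapply(node$children, function(c) c$cost_cents,
                         numeric(1)))
      expect_identical(node$cost_cents, kids)
      for (c in node$children) walk(c)
    }
  }
  walk(bd)
  invisible(bd)
}
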