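#' The bundled Type 2 Diabetes primary-care model
#'
#' The worked operational model for Type 2 Diabetes care in the NWN&DWO
#' region (primary-care organization ZEL, reference year 2009): five
#' demand segments following the disease/treatment stages
#' \describe{
#'   \item{DS1}{at high risk of developing T2D (screening only)}
#'   \item{DS2}{T2D treated with lifestyle advice}
#'   \item{DS3}{T2D treated with lifestyle advice and oral medication}
#'   \item{DS4}{T2D treated with insulin, possibly combined with oral
#'     medication (first year with insulin stabilization)}
#'   \item{DS5}{complicated T2D under specialist (hospital) care}
#' }
#' with services S1-S7 composed of 20 service elements, per-minute unit
#' costs for the costed resources (GP 1.10, GP & practice nurse 0.71,
#' laboratory 0.42, dietician 0.53, optometrist 1.10, practice nurse 0.29,
#' diabetic nurse 0.58, lifestyle consultant 0.58 EUR/min), annual
#' transition probabilities between segments (DS2 row: 0.313 to DS3, 0.05
#' to DS5, 0.012 exit), regional demand (population 443,281; 910 newly
#' diagnosed patients per year; 12,218 prevalent patients) and per-segment
#' outcome and behaviour profiles from the patient survey.
#'
#' Medication, insulin and test-kit resources carry no published unit
#' cost and are deliberately uncosted: any total touching them is flagged
#' partial rather than silently read as complete. The DS3 and DS4
#' transition rows are not published; they are placeholders flagged
#' `assumed`, calibrated so total leaving probabilities equal the
#' reciprocals of the declared mean stage durations (9 and 10 years).
#'
#' The same model ships as a YAML file:
#' `system.file("extdata", "t2d_nwn_dwo.yaml", package = "carejourney")`.
#'
#' @return a validated [care_model()]
#' @examples
#' m <- t2d_model()
#' cost_total(service_annual_cost(m, "S2"))       # 276.12
#' cost_total(segment_annual_cost(m, "DS2"))      # 127.44
#' mean_sojourn(m, "DS2")                         # 2.667
#' @export
t2d_model <- function() {
  res <- function(id, name, kind, basis, eur = NA_real_)
    list(id = id, name = name, kind = kind, cost_basis = basis,
         unit_cost_cents = if (is.na(eur)) NA_real_ else eur_to_cents(eur))
  resources <- list(
    res("lab", "Laboratory", "facility", "per_minute", 0.42),
    res("gp", "General practitioner", "human", "per_minute", 1.10),
    res("doctor_assistant", "Doctor assistant", "human", "per_minute"),
    res("gp_nurse", "GP & practice nurse", "human", "per_minute", 0.71),
    res("dietician", "Dietician", "human", "per_minute", 0.53),
    res("optometrist", "Optometrist", "human", "per_minute", 1.10),
    res("practice_nurse", "Practice nurse", "human", "per_minute", 0.29),
    res("diabetic_nurse", "Diabetic nurse", "human", "per_minute", 0.58),
    res("lifestyle_consultant", "Life style consultant", "human",
        "per_minute", 0.58),
    res("district_nurse", "District nurse", "human", "per_minute"),
    res("pharmacist", "Pharmacist", "human", "per_minute"),
    res("specialist", "Diabetes specialist", "human", "per_minute"),
    res("test_kit", "Glucose self-test kit", "consumable", "per_item"),
    res("oral_medication", "Oral medication", "consumable", "per_item"),
    res("insulin", "Insulin", "consumable", "per_item")
  )

  el <- function(id, name, ...) {
    req <- list(...)
    list(id = id, name = name,
         requirements = data.frame(
           resource = vapply(req, `[[`, character(1), 1),
           quantity = as.numeric(vapply(req, `[[`, character(1), 2)),
           stringsAsFactors = FALSE))
  }
  elements <- list(
    el("SE1", "Screening visit", c("gp", "20")),
    el("SE2", "Lab test in GP office", c("doctor_assistant", "5")),
    el("SE3", "Lab-test sampling", c("lab", "5")),
    el("SE4", "Lab-test analysis", c("lab", "1")),
    el("SE5", "First visit", c("gp", "20")),
    el("SE6", "Visit for diagnosis and care plan", c("gp", "20")),
    el("SE7", "Follow-up visit", c("gp_nurse", "20")),
    el("SE8", "Diet consultation", c("dietician", "45")),
    el("SE9", "Eye care", c("optometrist", "5")),
    el("SE10", "Foot care", c("practice_nurse", "5")),
    el("SE11", "Self-test glucose monitoring", c("test_kit", "1")),
    el("SE12", "Oral medication", c("oral_medication", "1")),
    el("SE13", "Insulin medication", c("insulin", "1")),
    el("SE14", "Education", c("diabetic_nurse", "20")),
    el("SE15", "Specialized care", c("specialist", "10")),
    el("SE16", "Life style program", c("lifestyle_consultant", "20")),
    el("SE17", "Insulin injection by professional",
       c("district_nurse", "5"), c("insulin", "1")),
    el("SE18", "Delivering medication by professional",
       c("pharmacist", "5")),
    el("SE19", "Prescription medicine", c("gp", "5")),
    el("SE20", "Education for using insulin", c("diabetic_nurse", "20"))
  )

  usages <- function(...) {
    u <- list(...)
    data.frame(element = vapply(u, `[[`, character(1), 1),
               frequency = as.numeric(vapply(u, `[[`, character(1), 2)),
               utilization = as.numeric(vapply(u, `[[`, character(1), 3)),
               stringsAsFactors = FALSE)
  }
  services <- list(
    list(id = "S1", name = "Screening",
         usages = usages(c("SE1", "1", "1"))),
    # SE2 is defined for the diagnosis pathway but carries no recommended
    # frequency; it is kept with zero usage.
    list(id = "S2", name = "Diagnosis",
         usages = usages(c("SE2", "0", "0"), c("SE3", "1", "1"),
                         c("SE4", "1", "1"), c("SE5", "1", "1"),
                         c("SE6", "3", "1"), c("SE14", "4", "1"),
                         c("SE16", "12", "1"))),
    list(id = "S3", name = "Chronic treatment with lifestyle advice",
         usages = usages(c("SE3", "1", "1"), c("SE4", "1", "1"),
                         c("SE7", "4", "0.8"), c("SE8", "1", "0.1"),
                         c("SE9", "1", "0.4"), c("SE10", "1", "0.1"))),
    list(id = "S4",
         name = "Chronic treatment with lifestyle advice and oral medication",
         usages = usages(c("SE3", "1", "1"), c("SE4", "1", "1"),
                         c("SE7", "4", "0.8"), c("SE8", "1", "0.01"),
                         c("SE9", "1", "0.4"), c("SE10", "1", "0.65"),
                         c("SE12", "365", "1"), c("SE18", "4", "1"),
                         c("SE19", "4", "0.2"))),
    list(id = "S5",
         name = "Insulin therapy, first year (insulin stabilization)",
         usages = usages(c("SE3", "1", "1"), c("SE4", "1", "1"),
                         c("SE7", "4", "1"), c("SE8", "1", "0.01"),
                         c("SE9", "1", "0.4"), c("SE10", "1", "0.65"),
                         c("SE11", "100", "1"), c("SE12", "365", "0.9"),
                         c("SE13", "365", "1"), c("SE17", "365", "0.02"),
                         c("SE18", "4", "1"), c("SE20", "8", "1"))),
    list(id = "S6", name = "Insulin therapy, after the first year",
         usages = usages(c("SE3", "1", "1"), c("SE4", "1", "1"),
                         c("SE7", "4", "1"), c("SE8", "1", "0.01"),
                         c("SE9", "1", "0.4"), c("SE10", "1", "0.65"),
                         c("SE11", "100", "1"), c("SE12", "365", "0.9"),
                         c("SE13", "365", "1"), c("SE17", "365", "0.02"),
                         c("SE18", "4", "1"))),
    # hospital-delivered specialist care: not elaborated in primary care,
    # carried with zero usage
    list(id = "S7", name = "Specialized (hospital) care",
         usages = usages(c("SE15", "0", "0")))
  )

  seg <- function(id, name, phases, total, outcomes = NULL,
                  behaviors = NULL)
    list(id = id, name = name,
         schedule = list(phases = phases, expected_total_duration = total),
         outcomes = outcomes, behaviors = behaviors)
  phases <- function(...) {
    p <- list(...)
    data.frame(service = vapply(p, `[[`, character(1), 1),
               years = as.numeric(vapply(p, `[[`, character(1), 2)),
               stringsAsFactors = FALSE)
  }
  segments <- list(
    seg("DS1", "At high risk of developing T2D",
        phases(c("S1", NA)), 1),
    seg("DS2", "T2D, lifestyle advice",
        phases(c("S2", "1"), c("S3", NA)), 3,
        outcomes = c(satisfaction_services = 5.9, own_health = 77.1,
                     satisfaction_own_health = 4.9,
                     aware_hba1c_pct = 42.4, hba1c_in_control_pct = 84),
        behaviors = c(smokers_pct = 7.0, drinkers_pct = 72.0)),
    seg("DS3", "T2D, lifestyle advice and oral medication",
        phases(c("S4", NA)), 9,
        outcomes = c(satisfaction_services = 6.3, own_health = 77.8,
                     satisfaction_own_health = 5.0,
                     aware_hba1c_pct = 56.1, hba1c_in_control_pct = 87),
        behaviors = c(smokers_pct = 11.4, drinkers_pct = 66.8)),
    seg("DS4", "T2D, insulin therapy (with lifestyle/oral medication)",
        phases(c("S5", "1"), c("S6", NA)), 10,
        outcomes = c(satisfaction_services = 6.1, own_health = 69.1,
                     satisfaction_own_health = 4.1,
                     aware_hba1c_pct = 77.1, hba1c_in_control_pct = 78),
        behaviors = c(smokers_pct = 10.9, drinkers_pct = 57.7)),
    seg("DS5", "Complicated T2D, specialist care",
        phases(c("S7", NA)), NA_real_)
  )

  transitions <- list(
    entry = "DS2",
    states = c("DS2", "DS3", "DS4"),
    absorbing = c("DS5", "exit"),
    rows = list(
      DS2 = c(DS3 = 0.313, DS5 = 0.05, exit = 0.012),
      # placeholder rows: totals equal 1/9 and 1/10 (the reciprocals of
      # the declared mean stage durations); the split assigns 0.01 each
      # to specialist referral and exit, the rest to progression
      DS3 = c(DS4 = 1 / 9 - 0.02, DS5 = 0.01, exit = 0.01),
      DS4 = c(DS5 = 0.05, exit = 0.05)
    ),
    assumed = c("DS3", "DS4")
  )

  region <- list(
    population = 443281,
    annual_incidence = 910,
    total_patients = 12218,
    observed_segment_counts = c(DS2 = 2687, DS3 = 8084, DS4 = 1451)
  )

  metadata <- list(
    name = "T2D primary care, NWN&DWO region (ZEL)",
    currency = "EUR", year = 2009L,
    outcome_scales = list(
      satisfaction_services = c(1, 7),
      own_health = c(0, 100),
      satisfaction_own_health = c(1, 7),
      aware_hba1c_pct = c(0, 100),
      hba1c_in_control_pct = c(0, 100)
    )
  )

  care_model(resources, elements, services, segments, transitions, region,
             metadata = metadata)
}
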