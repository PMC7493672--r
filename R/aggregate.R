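# Resource-requirement and outcome aggregation: professional-care hours,
# regional resource loads, incidence/prevalence rates, sojourn-weighted
# journey outcomes, and the per-segment summary table.

.profile_value <- function(profile, name) {
  if (!is.null(profile) && name %in% names(profile)) profile[[name]]
  else NULL
}

# Per-resource expected annual quantities for one service, rounded per the
# costing convention (half-up to whole units at the element level).
.service_resource_quantities <- function(model, service,
                                         round_quantities = TRUE) {
  svc <- model$services[[service]]
  if (is.null(svc)) stop("unknown service: ", service, call. = FALSE)
  acc <- stats::setNames(numeric(length(model$resources)),
                         names(model$resources))
  for (e in svc$usages$element) {
    q <- expected_annual_quantity(model, service, e,
                                  round_quantities = round_quantities)
    acc[names(q)] <- acc[names(q)] + q
  }
  acc
}

.professional_minutes <- function(model, service, include_lab = TRUE,
                                  round_quantities = TRUE) {
  q <- .service_resource_quantities(model, service, round_quantities)
  keep <- vapply(names(q), function(rid) {
    r <- model$resources[[rid]]
    r$cost_basis == "per_minute" &&
      (r$kind == "human" || (include_lab && r$kind == "facility"))
  }, logical(1))
  sum(q[keep])
}

#' Professional-care hours per patient-year in a segment
#'
#' Sums the per-minute resource quantities (whole-minute rounding as in
#' costing) of the services scheduled over the segment's expected tenure,
#' averages per year, and converts to hours. `include_lab` controls
#' whether laboratory (facility) minutes count as professional care, in
#' addition to human resources; items (pills, kits) never count.
#'
#' @param model a [care_model()]
#' @param segment segment id
#' @param include_lab count per-minute facility (laboratory) resources
#'   (default TRUE)
#' @param round_quantities as in [expected_annual_quantity()]
#' @return hours per patient-year, reported to one decimal; the unrounded
#'   value is attached as attribute `"exact"`
#' @examples
#' professional_hours(t2d_model(), "DS2")  # 3.1
#' @export
professional_hours <- function(model, segment, include_lab = TRUE,
                               round_quantities = TRUE) {
  g <- model$segments[[segment]]
  if (is.null(g)) stop("unknown segment: ", segment, call. = FALSE)
  ph <- g$schedule$phases
  tot <- g$schedule$expected_total_duration
  if (is.na(tot))
    stop(sprintf("segment '%s' has no expected_total_duration", segment),
         call. = FALSE)
  closed <- sum(ph$years, na.rm = TRUE)
  years <- ifelse(is.na(ph$years), tot - closed, ph$years)
  mins <- vapply(ph$service, .professional_minutes, numeric(1),
                 model = model, include_lab = include_lab,
                 round_quantities = round_quantities)
  exact <- sum(years * mins) / tot / 60
  structure(round(exact, 1), exact = exact)
}

#' Regional resource load for a given occupancy
#'
#' For each resource, the total expected annual quantity (minutes or
#' items) implied by an occupancy vector: the sum over occupied states of
#' patient count times the per-patient-year quantity under the state's
#' service. Occupancy may be keyed by expanded tenure states
#' (`"DS2:1"`), by segment ids (single-phase segments only), or directly
#' by service ids. The load is linear in occupancy and additive over
#' states.
#'
#' @param model a [care_model()]
#' @param occupancy named non-negative vector of patient counts
#' @param round_quantities as in [expected_annual_quantity()]
#' @return named vector of quantities per resource, with the basis unit of
#'   each resource as attribute `"unit"`
#' @export
resource_load <- function(model, occupancy, round_quantities = TRUE) {
  stopifnot(all(occupancy >= 0))
  chain <- NULL
  load <- stats::setNames(numeric(length(model$resources)),
                          names(model$resources))
  for (key in names(occupancy)) {
    svc <- if (key %in% names(model$services)) {
      key
    } else if (grepl(":", key, fixed = TRUE)) {
      if (is.null(chain)) chain <- expand_tenure(model)
      i <- match(key, chain$map$state)
      if (is.na(i)) stop("unknown state: ", key, call. = FALSE)
      chain$map$service[i]
    } else if (key %in% names(model$segments)) {
      ph <- model$segments[[key]]$schedule$phases
      if (nrow(ph) > 1L)
        stop(sprintf(paste0("segment '%s' has a multi-phase schedule; key ",
                            "occupancy by tenure state ('%s:1', ...)"),
                     key, key), call. = FALSE)
      ph$service[1]
    } else stop("unknown occupancy key: ", key, call. = FALSE)
    q <- .service_resource_quantities(model, svc, round_quantities)
    load <- load + occupancy[[key]] * q
  }
  units <- vapply(model$resources, function(r)
    if (r$cost_basis == "per_minute") "min" else "item", character(1))
  structure(load, unit = units)
}

#' Incidence and prevalence rates for the modelled region
#'
#' @param model a [care_model()] with a region block
#' @param total_patients current patient count; defaults to the region's
#'   declared total, falling back to the sum of observed segment counts
#' @return a `rate_report`: fractions, rendered percents (2 decimals) and
#'   the denominators used
#' @examples
#' demand_rates(t2d_model())  # incidence 0.21%, prevalence 2.76%
#' @export
demand_rates <- function(model, total_patients = NULL) {
  rg <- model$region
  if (is.null(rg)) stop("model has no region block", call. = FALSE)
  if (rg$population <= 0) stop("zero population", call. = FALSE)
  if (is.null(total_patients)) {
    total_patients <- if (!is.na(rg$total_patients)) rg$total_patients
                      else sum(rg$observed_segment_counts)
  }
  inc <- rg$annual_incidence / rg$population
  prev <- total_patients / rg$population
  structure(
    list(incidence_rate = inc, prevalence_rate = prev,
         incidence_pct = sprintf("%.2f", 100 * inc),
         prevalence_pct = sprintf("%.2f", 100 * prev),
         population = rg$population,
         new_patients = rg$annual_incidence,
         total_patients = total_patients),
    class = "rate_report")
}

#' @export
print.rate_report <- function(x, ...) {
  cat(sprintf("incidence:  %s%% (%g new patients / %s population / year)\n",
              x$incidence_pct, x$new_patients,
              format(x$population, big.mark = ",")))
  cat(sprintf("prevalence: %s%% (%g patients / %s population)\n",
              x$prevalence_pct, x$total_patients,
              format(x$population, big.mark = ",")))
  invisible(x)
}

#' Sojourn-weighted outcome over an expected patient journey
#'
#' Weights each visited segment's per-year outcome value by the expected
#' years spent there (absorbing-chain closed form) and reports the total
#' and the per-year mean. A reachable segment without the named outcome is
#' an explicit error, never a silent zero.
#'
#' @param model a [care_model()]
#' @param outcome outcome name, as declared in the segments' profiles
#' @param entry entry segment id
#' @return list with `total` (outcome-years), `per_year_mean`,
#'   `years` (named, per segment) and `journey_years`
#' @export
journey_outcome <- function(model, outcome,
                            entry = model$transitions$entry) {
  v <- expected_visits(model, entry)
  by_seg <- visits_by_segment(v)
  by_seg <- by_seg[by_seg > 1e-12]
  vals <- vapply(names(by_seg), function(s) {
    val <- .profile_value(model$segments[[s]]$outcomes, outcome)
    if (is.null(val))
      stop(sprintf("segment '%s' is reachable but has no outcome '%s'",
                   s, outcome), call. = FALSE)
    val
  }, numeric(1))
  total <- sum(by_seg * vals)
  list(total = total, per_year_mean = total / sum(by_seg),
       years = by_seg, journey_years = sum(by_seg))
}

#' Per-segment summary table
#'
#' One row per demand segment: observed patient count (pass-through),
#' professional-care hours per patient-year, deterministic annual cost per
#' patient with its partial-cost flag, and the declared outcome and
#' behaviour profile columns. Segments without a declared expected total
#' duration report `NA` hours and cost.
#'
#' @param model a [care_model()]
#' @param include_lab as in [professional_hours()]
#' @return a data frame
#' @export
segment_report <- function(model, include_lab = TRUE) {
  segs <- model$segments
  counts <- model$region$observed_segment_counts
  prof_names <- unique(unlist(lapply(segs, function(g)
    c(names(g$outcomes), names(g$behaviors)))))
  rows <- lapply(segs, function(g) {
    has_dur <- !is.na(g$schedule$expected_total_duration)
    cost <- partial <- NA
    hours <- NA_real_
    if (has_dur) {
      bd <- segment_annual_cost(model, g$id, mode = "deterministic")
      cost <- cost_total(bd)
      partial <- bd$partial
      hours <- as.numeric(professional_hours(model, g$id,
                                             include_lab = include_lab))
    }
    row <- data.frame(
      segment = g$id,
      n_patients = if (!is.null(counts) && g$id %in% names(counts))
        counts[[g$id]] else NA_real_,
      hours_per_patient_year = hours,
      cost_per_patient_year = cost,
      partial_cost_flag = partial,
      stringsAsFactors = FALSE)
    for (nm in prof_names) {
      v <- .profile_value(g$outcomes, nm) %||% .profile_value(g$behaviors, nm)
      row[[nm]] <- if (is.null(v)) NA_real_ else v
    }
    row
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out
}
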