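#' @keywords internal
"_PACKAGE"

RESOURCE_KINDS <- c("human", "device", "facility", "consumable")
COST_BASES    <- c("per_minute", "per_item")

#' Round half away from zero to whole units
#'
#' Expected annual quantities (minutes or items) are rounded half-up to a
#' whole unit before pricing. A small epsilon guards against binary
#' representation of quantities such as `1 * 45 * 0.10 = 4.5`.
#' @param x numeric vector
#' @return integer-valued numeric vector
#' @keywords internal
round_half_up <- function(x) floor(x + 0.5 + 1e-9)

cents_to_eur <- function(cents) cents / 100
eur_to_cents <- function(eur) round(eur * 100)

fmt_eur <- function(cents, currency = "EUR") {
  sprintf("%s %.2f", currency, cents / 100)
}

#' Construct an operational care model
#'
#' A `care_model` is the complete declarative description of a care delivery
#' network for one chronic condition: the resources available (with unit
#' costs), the atomic service elements and their per-delivery resource
#' requirements, the services (bundles of element usages with annual
#' frequencies and utilization rates), the demand segments (disease/treatment
#' stages) with their tenure-phased service schedules and optional outcome
#' and behaviour profiles, the annual transition model between segments, and
#' the regional demand (population, incidence).
#'
#' Most users will not call this constructor directly but load a model from
#' a YAML file with [read_care_model()] or build the bundled Type 2 Diabetes
#' model with [t2d_model()].
#'
#' @param resources list of resource records: `id`, `name`, `kind` (one of
#'   human, device, facility, consumable), `cost_basis` (`per_minute` or
#'   `per_item`) and `unit_cost_cents` (integer cents per basis unit, or
#'   `NA` for an uncosted resource).
#' @param elements list of service-element records: `id`, `name` and a
#'   `requirements` data frame with columns `resource`, `quantity`.
#' @param services list of service records: `id`, `name` and a `usages`
#'   data frame with columns `element`, `frequency` (deliveries per
#'   patient-year) and `utilization` (fraction in `[0, 1]` of patients in
#'   the segment actually using the element).
#' @param segments list of demand-segment records: `id`, `name`, `schedule`
#'   (a list with a `phases` data frame -- columns `service`, `years`, where
#'   `NA` years marks the open-ended final phase -- and
#'   `expected_total_duration` in years, possibly `NA`), plus optional named
#'   numeric `outcomes` and `behaviors`.
#' @param transitions list with `entry` (default entry segment), `states`
#'   (transient segment ids), `absorbing` (absorbing state ids, at minimum
#'   `"exit"`), `rows` (per transient state, a named vector of annual
#'   leaving probabilities; the stay probability is implied as one minus
#'   their sum) and `assumed` (states whose row is a documented placeholder
#'   rather than an observed estimate).
#' @param region list with `population`, `annual_incidence` (newly diagnosed
#'   patients per year), optional `total_patients` and optional named
#'   `observed_segment_counts`.
#' @param metadata list with `name`, `currency`, `year` and optionally
#'   `outcome_scales` (per outcome name, a length-2 numeric `c(min, max)`).
#' @param validate logical; check all invariants and fail on any finding.
#' @return an object of class `care_model`
#' @seealso [read_care_model()], [validate_care_model()], [t2d_model()]
#' @export
care_model <- function(resources, elements, services, segments, transitions,
                       region, metadata = list(), validate = TRUE) {
  m <- structure(
    list(
      metadata    = metadata,
      resources   = .index_by_id(resources),
      elements    = .index_by_id(elements),
      services    = .index_by_id(services),
      segments    = .index_by_id(segments),
      transitions = transitions,
      region      = region
    ),
    class = "care_model"
  )
  if (validate) {
    findings <- validate_care_model(m)
    if (nrow(findings) > 0L) {
      stop("invalid care model:\n",
           paste(sprintf("  [%s %s] %s: %s", findings$entity, findings$id,
                         findings$rule, findings$message),
                 collapse = "\n"),
           call. = FALSE)
    }
  }
  m
}

.index_by_id <- function(x) {
  if (is.null(x)) return(list())
  stats::setNames(x, vapply(x, function(r) r$id, character(1)))
}

.finding <- function(entity, id, rule, message) {
  data.frame(entity = entity, id = id, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

.no_findings <- function() {
  data.frame(entity = character(), id = character(), rule = character(),
             message = character(), stringsAsFactors = FALSE)
}

#' Validate a care model
#'
#' Checks every structural invariant of the model -- referential integrity
#' of all id references, sign and range constraints, schedule consistency,
#' outcome values against their declared scales, and the transition-model
#' rules (see [validate_transitions()]). Validation is total: any
#' structurally complete model yields a finite table of findings, never an
#' error.
#'
#' @param model a `care_model` (built with `validate = FALSE` if it may be
#'   broken)
#' @return a data frame of findings with columns `entity`, `id`, `rule`,
#'   `message`; zero rows iff the model is valid
#' @export
validate_care_model <- function(model) {
  f <- list()
  add <- function(x) f[[length(f) + 1L]] <<- x

  res_ids <- names(model$resources)
  if (anyDuplicated(res_ids))
    add(.finding("resource", res_ids[duplicated(res_ids)][1],
                 "unique_id", "duplicated resource id"))
  for (r in model$resources) {
    if (!r$kind %in% RESOURCE_KINDS)
      add(.finding("resource", r$id, "kind",
                   sprintf("unknown kind '%s'", r$kind)))
    if (!r$cost_basis %in% COST_BASES)
      add(.finding("resource", r$id, "cost_basis",
                   sprintf("unknown cost basis '%s'", r$cost_basis)))
    if (!is.na(r$unit_cost_cents) && r$unit_cost_cents < 0)
      add(.finding("resource", r$id, "unit_cost", "unit cost is negative"))
  }

  for (e in model$elements) {
    req <- e$requirements
    if (anyDuplicated(req$resource))
      add(.finding("element", e$id, "unique_resource",
                   "resource listed twice in requirements"))
    for (i in seq_len(nrow(req))) {
      if (!req$resource[i] %in% res_ids)
        add(.finding("element", e$id, "dangling_resource",
                     sprintf("requirement references unknown resource '%s'",
                             req$resource[i])))
      if (!is.finite(req$quantity[i]) || req$quantity[i] <= 0)
        add(.finding("element", e$id, "quantity",
                     sprintf("non-positive quantity for resource '%s'",
                             req$resource[i])))
    }
  }

  el_ids <- names(model$elements)
  for (s in model$services) {
    u <- s$usages
    if (anyDuplicated(u$element))
      add(.finding("service", s$id, "unique_element",
                   "element listed twice in usages"))
    for (i in seq_len(nrow(u))) {
      if (!u$element[i] %in% el_ids)
        add(.finding("service", s$id, "dangling_element",
                     sprintf("usage references unknown element '%s'",
                             u$element[i])))
      if (!is.finite(u$frequency[i]) || u$frequency[i] < 0)
        add(.finding("service", s$id, "frequency",
                     sprintf("negative frequency for element '%s'",
                             u$element[i])))
      if (!is.finite(u$utilization[i]) ||
          u$utilization[i] < 0 || u$utilization[i] > 1)
        add(.finding("service", s$id, "utilization",
                     sprintf("utilization for element '%s' outside [0, 1]",
                             u$element[i])))
    }
  }

  svc_ids <- names(model$services)
  scales <- model$metadata$outcome_scales
  for (g in model$segments) {
    ph <- g$schedule$phases
    for (i in seq_len(nrow(ph))) {
      if (!ph$service[i] %in% svc_ids)
        add(.finding("segment", g$id, "dangling_service",
                     sprintf("schedule references unknown service '%s'",
                             ph$service[i])))
      open <- is.na(ph$years[i])
      if (open && i < nrow(ph))
        add(.finding("segment", g$id, "open_phase",
                     "only the final phase may be open-ended"))
      if (!open && (ph$years[i] < 1 || ph$years[i] != round(ph$years[i])))
        add(.finding("segment", g$id, "phase_years",
                     "phase durations must be whole years >= 1"))
    }
    tot <- g$schedule$expected_total_duration
    closed <- sum(ph$years, na.rm = TRUE)
    if (!is.null(tot) && !is.na(tot) && closed > tot)
      add(.finding("segment", g$id, "schedule_duration",
                   "closed phases exceed expected total duration"))
    for (nm in names(g$outcomes)) {
      sc <- scales[[nm]]
      v <- g$outcomes[[nm]]
      if (!is.null(sc) && (v < sc[1] || v > sc[2]))
        add(.finding("segment", g$id, "outcome_scale",
                     sprintf("outcome '%s' = %g outside scale [%g, %g]",
                             nm, v, sc[1], sc[2])))
    }
  }

  tf <- validate_transitions(model$transitions,
                             segment_ids = names(model$segments))
  if (nrow(tf) > 0L) add(tf)

  rg <- model$region
  if (!is.null(rg)) {
    if (rg$population <= 0)
      add(.finding("region", "region", "population",
                   "population must be positive"))
    if (rg$annual_incidence < 0)
      add(.finding("region", "region", "incidence", "incidence is negative"))
    if (rg$annual_incidence > rg$population)
      add(.finding("region", "region", "incidence",
                   "incidence exceeds population"))
  }

  if (length(f) == 0L) .no_findings() else do.call(rbind, f)
}

#' Validate a transition model
#'
#' Findings are data, not exceptions: a structurally complete transition
#' model always yields a (possibly empty) table. Checked rules: every
#' referenced state is declared; all probabilities lie in `[0, 1]`; each
#' row's leaving probabilities sum to at most 1 (the stay probability is
#' implied as the remainder); and every transient state can reach an
#' absorbing state, so no cohort is immortal.
#'
#' @param transitions a transition-model list (see [care_model()])
#' @param segment_ids optional character vector; when given, transient
#'   states must be drawn from it
#' @return findings data frame as in [validate_care_model()]
#' @export
validate_transitions <- function(transitions, segment_ids = NULL) {
  f <- list()
  add <- function(...) f[[length(f) + 1L]] <<- .finding(...)
  t <- transitions
  states <- t$states
  absorbing <- t$absorbing
  if (length(absorbing) == 0L)
    add("transitions", "model", "absorbing",
        "at least one absorbing state (e.g. 'exit') is required")
  all_states <- c(states, absorbing)

  if (!is.null(segment_ids)) {
    bad <- setdiff(states, segment_ids)
    for (s in bad)
      add("transitions", s, "dangling_state",
          sprintf("transient state '%s' is not a declared segment", s))
  }
  if (!is.null(t$entry) && !t$entry %in% states)
    add("transitions", t$entry, "entry",
        "entry state is not a transient state")

  leave_total <- stats::setNames(numeric(length(states)), states)
  for (s in states) {
    row <- t$rows[[s]]
    if (is.null(row)) {
      add("transitions", s, "missing_row",
          sprintf("no transition row for state '%s'", s))
      next
    }
    bad_dest <- setdiff(names(row), all_states)
    for (d in bad_dest)
      add("transitions", s, "dangling_state",
          sprintf("row targets undeclared state '%s'", d))
    if (s %in% names(row))
      add("transitions", s, "self_target",
          "stay probability is implied and must not be stored")
    if (any(row < 0 | row > 1))
      add("transitions", s, "probability_range",
          "probabilities must lie in [0, 1]")
    tot <- sum(row)
    leave_total[s] <- tot
    if (tot > 1 + 1e-12)
      add("transitions", s, "row_exceeds_1",
          sprintf("leaving probabilities sum to %.4g > 1", tot))
  }

  # reachability of absorption: breadth-first over arcs with positive mass
  can_absorb <- stats::setNames(rep(FALSE, length(states)), states)
  repeat {
    changed <- FALSE
    for (s in states) {
      if (can_absorb[s]) next
      row <- t$rows[[s]]
      if (is.null(row)) next
      dests <- names(row)[row > 0]
      if (any(dests %in% absorbing) || any(can_absorb[intersect(dests, states)])) {
        can_absorb[s] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  for (s in states) {
    if (!is.null(t$rows[[s]]) && !can_absorb[s])
      add("transitions", s, "immortal_state",
          sprintf("state '%s' has no path to an absorbing state", s))
  }

  if (length(f) == 0L) .no_findings() else do.call(rbind, f)
}

#' @export
print.care_model <- function(x, ...) {
  md <- x$metadata
  cat(sprintf("<care_model> %s (%s, %s)\n",
              md$name %||% "unnamed", md$currency %||% "EUR",
              md$year %||% "?"))
  cat(sprintf("  %d resources, %d service elements, %d services, %d segments\n",
              length(x$resources), length(x$elements), length(x$services),
              length(x$segments)))
  cat(sprintf("  transitions: %s -> {%s}; entry %s\n",
              paste(x$transitions$states, collapse = ", "),
              paste(x$transitions$absorbing, collapse = ", "),
              x$transitions$entry %||% "?"))
  if (!is.null(x$region))
    cat(sprintf("  region: population %s, incidence %s/year\n",
                format(x$region$population, big.mark = ","),
                format(x$region$annual_incidence, big.mark = ",")))
  invisible(x)
}

#' @export
summary.care_model <- function(object, ...) {
  uncosted <- vapply(object$resources,
                     function(r) is.na(r$unit_cost_cents), logical(1))
  out <- list(
    model = object,
    findings = validate_care_model(object),
    uncosted_resources = names(object$resources)[uncosted],
    segment_table = segment_report(object)
  )
  class(out) <- "summary.care_model"
  out
}

#' @export
print.summary.care_model <- function(x, ...) {
  print(x$model)
  if (nrow(x$findings) == 0L) cat("  validation: 0 findings\n")
  else cat(sprintf("  validation: %d findings\n", nrow(x$findings)))
  if (length(x$uncosted_resources))
    cat("  uncosted resources:",
        paste(x$uncosted_resources, collapse = ", "), "\n")
  cat("\n")
  print(x$segment_table)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
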