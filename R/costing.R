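# Activity-based costing.
#
# A service element is priced as the sum of its resource usages: for each
# required resource, expected annual quantity = frequency x utilization x
# per-delivery quantity, rounded half-up to a whole unit (minute or item)
# before multiplying by the resource's unit cost. Services sum their
# elements, segment-years time-weight their scheduled services, journeys
# sum segment sojourns. All arithmetic is carried in integer cents at the
# element and service levels; time-weighted levels may carry fractional
# cents but every node's cost is the exact sum of its children's.

new_breakdown <- function(level, id, name, children = list(),
                          expected_quantity = NA_real_,
                          unit = NA_character_,
                          unit_cost_cents = NA_real_,
                          cost_cents = NA_real_, partial = FALSE) {
  if (length(children)) {
    cost_cents <- sum(vapply(children, function(c) c$cost_cents, numeric(1)))
    partial <- any(vapply(children, function(c) c$partial, logical(1)))
  }
  structure(
    list(level = level, id = id, name = name,
         expected_quantity = expected_quantity, unit = unit,
         unit_cost_cents = unit_cost_cents, cost_cents = cost_cents,
         partial = partial, children = children),
    class = "cost_breakdown")
}

#' Total cost of a breakdown, in currency units
#' @param x a `cost_breakdown`
#' @return numeric (e.g. euros)
#' @export
cost_total <- function(x) {
  stopifnot(inherits(x, "cost_breakdown"))
  cents_to_eur(x$cost_cents)
}

#' Expected annual quantity of a resource within a service
#'
#' For one service-element usage and one required resource:
#' `frequency x utilization x per-delivery quantity`, rounded half-up to a
#' whole unit (minutes or items). This whole-unit rounding is applied
#' before pricing throughout the engine; pass
#' `round_quantities = FALSE` for the un-rounded expectation.
#'
#' @param model a [care_model()]
#' @param service service id
#' @param element service-element id (must be used by `service`)
#' @param resource resource id (must be required by `element`); if `NULL`,
#'   quantities for all of the element's resources are returned as a named
#'   vector
#' @param round_quantities round half-up to whole units (default TRUE)
#' @return numeric quantity (or named vector) per patient-year
#' @export
expected_annual_quantity <- function(model, service, element,
                                     resource = NULL,
                                     round_quantities = TRUE) {
  u <- .get_usage(model, service, element)
  el <- model$elements[[element]]
  req <- el$requirements
  if (!is.null(resource)) {
    if (!resource %in% req$resource)
      stop(sprintf("element '%s' does not require resource '%s'",
                   element, resource), call. = FALSE)
    req <- req[req$resource == resource, , drop = FALSE]
  }
  q <- u$frequency * u$utilization * req$quantity
  if (round_quantities) q <- round_half_up(q)
  stats::setNames(q, req$resource)
}

.get_usage <- function(model, service, element) {
  svc <- model$services[[service]]
  if (is.null(svc)) stop("unknown service: ", service, call. = FALSE)
  u <- svc$usages
  i <- match(element, u$element)
  if (is.na(i))
    stop(sprintf("service '%s' has no usage of element '%s'",
                 service, element), call. = FALSE)
  u[i, , drop = FALSE]
}

#' Annual cost of one service element within a service
#'
#' Sums expected annual resource quantities times unit costs over the
#' element's required resources. Resources without a unit cost contribute
#' zero and set the `partial` flag on every enclosing total, so an
#' incomplete tariff is never silently read as a zero cost.
#'
#' @inheritParams expected_annual_quantity
#' @return a `cost_breakdown` at level `"element"` with one child per
#'   resource
#' @export
element_annual_cost <- function(model, service, element,
                                round_quantities = TRUE) {
  el <- model$elements[[element]]
  if (is.null(el)) stop("unknown element: ", element, call. = FALSE)
  q <- expected_annual_quantity(model, service, element,
                                round_quantities = round_quantities)
  children <- lapply(seq_along(q), function(i) {
    rid <- names(q)[i]
    r <- model$resources[[rid]]
    uncosted <- is.na(r$unit_cost_cents)
    new_breakdown("resource", rid, r$name,
                  expected_quantity = q[[i]],
                  unit = if (r$cost_basis == "per_minute") "min" else "item",
                  unit_cost_cents = r$unit_cost_cents,
                  cost_cents = if (uncosted) 0 else q[[i]] * r$unit_cost_cents,
                  partial = uncosted && q[[i]] > 0)
  })
  new_breakdown("element", element, el$name, children)
}

#' Annual per-patient cost of a service
#'
#' @inheritParams expected_annual_quantity
#' @return a `cost_breakdown` at level `"service"` with one child per
#'   element usage
#' @examples
#' m <- t2d_model()
#' cost_total(service_annual_cost(m, "S2"))  # 276.12
#' cost_total(service_annual_cost(m, "S3"))  # 53.10
#' @export
service_annual_cost <- function(model, service, round_quantities = TRUE) {
  svc <- model$services[[service]]
  if (is.null(svc)) stop("unknown service: ", service, call. = FALSE)
  children <- lapply(svc$usages$element, function(e)
    element_annual_cost(model, service, e,
                        round_quantities = round_quantities))
  new_breakdown("service", service, svc$name, children)
}

# Expected years spent in each tenure year-state of one segment,
# conditional on entry, under the implied geometric leaving process.
# Year-states 1..K-1 are the closed schedule years; K is the open tail.
.tenure_visits <- function(model, segment) {
  g <- model$segments[[segment]]
  stay <- 1 - .leave_total(model, segment)
  ph <- g$schedule$phases
  closed <- sum(ph$years, na.rm = TRUE)
  K <- closed + 1L  # one open year-state after the closed years
  visits <- stay^(seq_len(K) - 1)
  if (stay < 1) visits[K] <- visits[K] / (1 - stay)
  else visits[K] <- Inf
  # map year-states to services via phase boundaries
  svc <- character(K)
  yr <- 1L
  for (i in seq_len(nrow(ph))) {
    n <- if (is.na(ph$years[i])) K - yr + 1L else ph$years[i]
    if (n <= 0) next
    svc[yr:(yr + n - 1L)] <- ph$service[i]
    yr <- yr + n
  }
  if (yr <= K) svc[yr:K] <- ph$service[nrow(ph)]
  list(visits = visits, service = svc)
}

.leave_total <- function(model, segment) {
  row <- model$transitions$rows[[segment]]
  if (is.null(row)) 0 else sum(row)
}

#' Annual per-patient cost of a demand segment
#'
#' Averages the costs of the services scheduled over a patient's tenure in
#' the segment. In `"deterministic"` mode each phase is weighted by its
#' share of the declared expected total duration (the accounting used for
#' the worked per-segment figures). In `"markov"` mode the weights are the
#' expected tenure-year occupancies implied by the segment's annual leaving
#' probability (geometric sojourn), so the first-year service is weighted
#' by the probability-weighted share of a random sojourn actually spent in
#' year one.
#'
#' @inheritParams expected_annual_quantity
#' @param segment segment id
#' @param mode `"deterministic"` or `"markov"`
#' @return a `cost_breakdown` at level `"segment_year"`; children are
#'   phase-weighted service costs
#' @examples
#' m <- t2d_model()
#' cost_total(segment_annual_cost(m, "DS2"))  # 127.44
#' @export
segment_annual_cost <- function(model, segment,
                                mode = c("deterministic", "markov"),
                                round_quantities = TRUE) {
  mode <- match.arg(mode)
  g <- model$segments[[segment]]
  if (is.null(g)) stop("unknown segment: ", segment, call. = FALSE)
  ph <- g$schedule$phases

  if (mode == "deterministic") {
    tot <- g$schedule$expected_total_duration
    if (is.na(tot))
      stop(sprintf(paste0("segment '%s' has an open-ended schedule and no ",
                          "expected_total_duration; deterministic mode ",
                          "requires one"), segment), call. = FALSE)
    closed <- sum(ph$years, na.rm = TRUE)
    years <- ifelse(is.na(ph$years), tot - closed, ph$years)
    w <- years / tot
    svc_ids <- ph$service
  } else {
    tv <- .tenure_visits(model, segment)
    if (!is.finite(sum(tv$visits)))
      stop(sprintf("segment '%s' has zero leaving probability (immortal)",
                   segment), call. = FALSE)
    agg <- tapply(tv$visits, tv$service, sum)
    svc_ids <- ph$service[!duplicated(ph$service)]
    w <- as.numeric(agg[svc_ids]) / sum(tv$visits)
    years <- as.numeric(agg[svc_ids])
  }

  children <- lapply(seq_along(svc_ids), function(i) {
    sc <- service_annual_cost(model, svc_ids[i],
                              round_quantities = round_quantities)
    new_breakdown("phase", svc_ids[i],
                  sprintf("%s (weight %.4g)", sc$name, w[i]),
                  expected_quantity = years[i], unit = "years",
                  cost_cents = w[i] * sc$cost_cents,
                  partial = sc$partial)
  })
  bd <- new_breakdown("segment_year", segment, g$name, children)
  attr(bd, "weights") <- stats::setNames(w, svc_ids)
  bd
}

#' Expected cost of a full patient journey
#'
#' Sums, over the segments a patient entering at `entry` passes through,
#' the expected years spent in the segment times its annual per-patient
#' cost. In `"deterministic"` mode the journey follows the main progression
#' pathway (from each segment, the most probable onward segment) and uses
#' each segment's declared expected total duration; in `"markov"` mode the
#' expected years come from the absorbing-chain closed form
#' ([expected_visits()]) and segment costs use markov weighting.
#'
#' @inheritParams segment_annual_cost
#' @param entry entry segment id (defaults to the model's declared entry)
#' @return a `cost_breakdown` at level `"journey"`; children at level
#'   `"segment_total"` carry expected years as `expected_quantity`
#' @export
journey_cost <- function(model, entry = model$transitions$entry,
                         mode = c("deterministic", "markov"),
                         round_quantities = TRUE) {
  mode <- match.arg(mode)
  if (!entry %in% model$transitions$states)
    stop("entry segment not in transition model: ", entry, call. = FALSE)

  if (mode == "deterministic") {
    path <- .main_pathway(model, entry)
    years <- vapply(path, function(s)
      model$segments[[s]]$schedule$expected_total_duration, numeric(1))
    if (anyNA(years))
      stop("deterministic journey requires expected_total_duration for: ",
           paste(path[is.na(years)], collapse = ", "), call. = FALSE)
  } else {
    v <- expected_visits(model, entry)
    by_seg <- visits_by_segment(v)
    path <- names(by_seg)[by_seg > 1e-12]
    years <- as.numeric(by_seg[path])
  }

  children <- lapply(seq_along(path), function(i) {
    sc <- segment_annual_cost(model, path[i], mode = mode,
                              round_quantities = round_quantities)
    new_breakdown("segment_total", path[i], sc$name,
                  expected_quantity = unname(years[i]), unit = "years",
                  cost_cents = unname(years[i]) * sc$cost_cents,
                  partial = sc$partial)
  })
  bd <- new_breakdown("journey", entry,
                      sprintf("journey entering at %s", entry), children)
  attr(bd, "years") <- stats::setNames(years, path)
  bd
}

# Main progression pathway: from each transient segment follow the most
# probable onward transient segment; stops at absorption or a revisit.
.main_pathway <- function(model, entry) {
  t <- model$transitions
  path <- entry
  cur <- entry
  repeat {
    row <- t$rows[[cur]]
    nxt <- row[names(row) %in% t$states & row > 0]
    nxt <- nxt[!names(nxt) %in% path]
    if (length(nxt) == 0L) break
    cur <- names(nxt)[which.max(nxt)]
    path <- c(path, cur)
  }
  path
}

#' Regional annual cost of a service or segment
#'
#' Straight product of a per-patient annual cost and a patient count,
#' cents-exact.
#'
#' @inheritParams segment_annual_cost
#' @param id a service id or segment id
#' @param n_patients non-negative patient count
#' @return numeric cost in currency units, with attributes `cents` and
#'   `partial`
#' @export
region_annual_cost <- function(model, id, n_patients,
                               mode = c("deterministic", "markov"),
                               round_quantities = TRUE) {
  stopifnot(n_patients >= 0)
  bd <- if (id %in% names(model$services))
    service_annual_cost(model, id, round_quantities = round_quantities)
  else if (id %in% names(model$segments))
    segment_annual_cost(model, id, mode = mode,
                        round_quantities = round_quantities)
  else stop("unknown service or segment: ", id, call. = FALSE)
  cents <- n_patients * bd$cost_cents
  structure(cents_to_eur(cents), cents = cents, partial = bd$partial)
}

#' Flatten a cost breakdown to a data frame
#'
#' @param x a `cost_breakdown`
#' @param row.names,optional,... ignored (S3 signature)
#' @return data frame with columns `level`, `id`, `name`,
#'   `expected_quantity`, `unit`, `unit_cost`, `cost`, `partial`
#' @export
as.data.frame.cost_breakdown <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  rows <- list()
  walk <- function(node) {
    rows[[length(rows) + 1L]] <<- data.frame(
      level = node$level, id = node$id, name = node$name,
      expected_quantity = node$expected_quantity, unit = node$unit,
      unit_cost = cents_to_eur(node$unit_cost_cents),
      cost = cents_to_eur(node$cost_cents),
      partial = node$partial, stringsAsFactors = FALSE)
    for (c in node$children) walk(c)
  }
  walk(x)
  do.call(rbind, rows)
}

#' @export
print.cost_breakdown <- function(x, currency = "EUR", indent = 0, ...) {
  pad <- strrep("  ", indent)
  qty <- if (is.na(x$expected_quantity)) ""
         else sprintf(" [%g %s]", x$expected_quantity, x$unit)
  flag <- if (x$partial) " (partial: uncosted resources)" else ""
  cat(sprintf("%s%s %s: %s%s%s\n", pad, x$level, x$id,
              fmt_eur(x$cost_cents, currency), qty, flag))
  for (c in x$children) print(c, currency = currency, indent = indent + 1)
  invisible(x)
}
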