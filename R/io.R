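# YAML serialization of care models.
#
# The on-disk schema mirrors the five framework entities: resources,
# elements (service elements), services, segments, transitions, plus
# region and metadata. Two representation conventions differ between the
# file and the in-memory object:
#   * unit costs are decimal currency in YAML, integer cents internally;
#   * utilization is percent in YAML (matching how uptake rates are
#     reported in practice guidelines), a fraction in [0, 1] internally.
# An absent unit_cost key marks an uncosted resource (internally NA).

#' Read a care model from a YAML file
#'
#' Parses, constructs and validates a model; a parse failure reports the
#' YAML error, a broken reference or constraint reports the offending
#' entity and rule.
#'
#' @param path path to a model definition file (see the packaged
#'   `t2d_nwn_dwo.yaml` for the schema)
#' @param validate fail on validation findings (default TRUE)
#' @return a [care_model()]
#' @examples
#' path <- system.file("extdata", "t2d_nwn_dwo.yaml", package = "carejourney")
#' m <- read_care_model(path)
#' m
#' @export
read_care_model <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  doc <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop("cannot parse model file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  model_from_list(doc, validate = validate)
}

#' Build a care model from a plain list (parsed YAML/JSON)
#' @param doc a list following the model-definition schema
#' @param validate fail on validation findings
#' @return a [care_model()]
#' @keywords internal
#' @export
model_from_list <- function(doc, validate = TRUE) {
  resources <- lapply(doc$resources, function(r) {
    list(id = r$id, name = r$name %||% r$id, kind = r$kind,
         cost_basis = r$cost_basis,
         unit_cost_cents = if (is.null(r$unit_cost)) NA_real_
                           else eur_to_cents(r$unit_cost))
  })
  elements <- lapply(doc$elements, function(e) {
    req <- e$requirements
    list(id = e$id, name = e$name %||% e$id,
         requirements = data.frame(
           resource = vapply(req, function(q) q$resource, character(1)),
           quantity = vapply(req, function(q) as.numeric(q$quantity),
                             numeric(1)),
           stringsAsFactors = FALSE))
  })
  services <- lapply(doc$services, function(s) {
    u <- s$usages
    list(id = s$id, name = s$name %||% s$id,
         usages = data.frame(
           element     = vapply(u, function(q) q$element, character(1)),
           frequency   = vapply(u, function(q) as.numeric(q$frequency),
                                numeric(1)),
           utilization = vapply(u, function(q) as.numeric(q$utilization),
                                numeric(1)) / 100,
           stringsAsFactors = FALSE))
  })
  segments <- lapply(doc$segments, function(g) {
    ph <- g$schedule$phases
    tot <- g$schedule$expected_total_duration
    list(id = g$id, name = g$name %||% g$id,
         schedule = list(
           phases = data.frame(
             service = vapply(ph, function(p) p$service, character(1)),
             years   = vapply(ph, function(p)
                         if (is.null(p$years)) NA_real_
                         else as.numeric(p$years), numeric(1)),
             stringsAsFactors = FALSE),
           expected_total_duration = if (is.null(tot)) NA_real_
                                     else as.numeric(tot)),
         outcomes  = .as_named_numeric(g$outcomes),
         behaviors = .as_named_numeric(g$behaviors))
  })
  tr <- doc$transitions
  transitions <- list(
    entry     = tr$entry,
    states    = as.character(unlist(tr$states)),
    absorbing = as.character(unlist(tr$absorbing)),
    rows      = lapply(tr$rows, function(r) unlist(r)),
    assumed   = as.character(unlist(tr$assumed))
  )
  rg <- doc$region
  region <- if (is.null(rg)) NULL else list(
    population       = as.numeric(rg$population),
    annual_incidence = as.numeric(rg$annual_incidence),
    total_patients   = if (is.null(rg$total_patients)) NA_real_
                       else as.numeric(rg$total_patients),
    observed_segment_counts = .as_named_numeric(rg$observed_segment_counts)
  )
  md <- doc$metadata %||% list()
  if (!is.null(md$outcome_scales))
    md$outcome_scales <- lapply(md$outcome_scales, as.numeric)

  care_model(resources, elements, services, segments, transitions, region,
             metadata = md, validate = validate)
}

.as_named_numeric <- function(x) {
  if (is.null(x) || length(x) == 0L) return(NULL)
  stats::setNames(vapply(x, as.numeric, numeric(1)), names(x))
}

#' Write a care model to a YAML file
#'
#' The inverse of [read_care_model()]: `read_care_model(write_care_model(m))`
#' reproduces `m` field for field, including uncosted-resource flags and
#' optional outcome/behaviour profiles.
#'
#' @param model a [care_model()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_care_model <- function(model, path) {
  doc <- model_to_list(model)
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

.yaml_num <- function(x) {
  if (length(x) == 1L && is.finite(x) && x == round(x) && abs(x) < 2^31)
    as.integer(x) else x
}

#' Convert a care model to its plain-list (YAML schema) form
#' @param model a [care_model()]
#' @return a list following the model-definition schema
#' @keywords internal
#' @export
model_to_list <- function(model) {
  resources <- lapply(unname(model$resources), function(r) {
    out <- list(id = r$id, name = r$name, kind = r$kind,
                cost_basis = r$cost_basis)
    if (!is.na(r$unit_cost_cents))
      out$unit_cost <- cents_to_eur(r$unit_cost_cents)
    out
  })
  elements <- lapply(unname(model$elements), function(e) {
    list(id = e$id, name = e$name,
         requirements = lapply(seq_len(nrow(e$requirements)), function(i)
           list(resource = e$requirements$resource[i],
                quantity = .yaml_num(e$requirements$quantity[i]))))
  })
  services <- lapply(unname(model$services), function(s) {
    list(id = s$id, name = s$name,
         usages = lapply(seq_len(nrow(s$usages)), function(i)
           list(element = s$usages$element[i],
                frequency = .yaml_num(s$usages$frequency[i]),
                utilization = .yaml_num(s$usages$utilization[i] * 100))))
  })
  segments <- lapply(unname(model$segments), function(g) {
    ph <- g$schedule$phases
    out <- list(id = g$id, name = g$name,
                schedule = list(
                  phases = lapply(seq_len(nrow(ph)), function(i) {
                    p <- list(service = ph$service[i])
                    if (!is.na(ph$years[i])) p$years <- .yaml_num(ph$years[i])
                    p
                  })))
    if (!is.na(g$schedule$expected_total_duration))
      out$schedule$expected_total_duration <-
        .yaml_num(g$schedule$expected_total_duration)
    if (!is.null(g$outcomes))  out$outcomes  <- as.list(g$outcomes)
    if (!is.null(g$behaviors)) out$behaviors <- as.list(g$behaviors)
    out
  })
  tr <- model$transitions
  transitions <- list(
    entry = tr$entry,
    states = as.list(tr$states),
    absorbing = as.list(tr$absorbing),
    rows = lapply(tr$rows, as.list)
  )
  if (length(tr$assumed)) transitions$assumed <- as.list(tr$assumed)
  out <- list(metadata = model$metadata, resources = resources,
              elements = elements, services = services, segments = segments,
              transitions = transitions)
  rg <- model$region
  if (!is.null(rg)) {
    region <- list(population = .yaml_num(rg$population),
                   annual_incidence = .yaml_num(rg$annual_incidence))
    if (!is.na(rg$total_patients))
      region$total_patients <- .yaml_num(rg$total_patients)
    if (!is.null(rg$observed_segment_counts))
      region$observed_segment_counts <-
        lapply(as.list(rg$observed_segment_counts), .yaml_num)
    out$region <- region
  }
  out
}
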