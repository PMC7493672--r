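# Microsimulation of individual patient trajectories and service use.
#
# These are the stochastic counterparts of the deterministic engine: each
# patient advances annually by sampling the tenure-expanded transition
# row, and each scheduled service element is delivered (all `frequency`
# deliveries or none) with probability equal to its utilization rate.
# Means over many simulated patients must agree with every closed-form
# result, which is how the engine cross-checks itself.

#' Simulate individual patient trajectories
#'
#' Each of `n` patients enters at `entry` (tenure year 1) and advances
#' annually by sampling the expanded-chain transition row, until
#' absorption or the horizon. One random stream, seeded explicitly, makes
#' runs bit-reproducible.
#'
#' @param model a [care_model()]
#' @param n number of patients
#' @param horizon maximum simulated years per patient
#' @param seed integer seed
#' @param entry entry segment id
#' @return a `care_trajectories` data frame with columns `patient`,
#'   `year`, `state`, `segment`, `tenure_phase`, `service`; attribute
#'   `terminal` is a per-patient data frame (`patient`, `last_year`,
#'   `terminal` -- an absorbing state or `"censored"`), attribute `seed`
#'   records the stream
#' @export
simulate_trajectories <- function(model, n, horizon = 200, seed,
                                  entry = model$transitions$entry) {
  stopifnot(n >= 0, horizon >= 1)
  set.seed(seed)
  chain <- expand_tenure(model)
  cols <- colnames(chain$P)
  start <- match(paste0(entry, ":1"), cols)
  if (is.na(start))
    stop("entry segment not in transition model: ", entry, call. = FALSE)
  n_trans <- length(chain$states)

  terminal <- rep("censored", n)
  last_year <- rep(horizon, n)
  out <- vector("list", horizon)
  if (n > 0) {
    cur <- rep.int(start, n)        # expanded-state index per patient
    alive <- seq_len(n)
    for (t in seq_len(horizon)) {
      if (length(alive) == 0L) break
      out[[t]] <- data.frame(patient = alive, year = t,
                             state_i = cur[alive])
      nxt <- cur
      for (s in unique(cur[alive])) {
        idx <- alive[cur[alive] == s]
        nxt[idx] <- sample.int(length(cols), length(idx), replace = TRUE,
                               prob = chain$P[s, ])
      }
      absorbed <- alive[nxt[alive] > n_trans]
      if (length(absorbed)) {
        terminal[absorbed] <- cols[nxt[absorbed]]
        last_year[absorbed] <- t
        alive <- setdiff(alive, absorbed)
      }
      cur <- nxt
    }
  }
  traj <- if (all(vapply(out, is.null, logical(1))))
    data.frame(patient = integer(), year = integer(), state_i = integer())
  else do.call(rbind, out[!vapply(out, is.null, logical(1))])
  traj <- traj[order(traj$patient, traj$year), , drop = FALSE]
  map <- chain$map
  i <- traj$state_i
  res <- data.frame(patient = traj$patient, year = traj$year,
                    state = map$state[i], segment = map$segment[i],
                    tenure_phase = map$phase_year[i],
                    service = map$service[i], stringsAsFactors = FALSE)
  rownames(res) <- NULL
  structure(res,
            terminal = data.frame(patient = seq_len(n),
                                  last_year = last_year,
                                  terminal = terminal,
                                  stringsAsFactors = FALSE),
            seed = seed, entry = entry, horizon = horizon,
            class = c("care_trajectories", "data.frame"))
}

# Per-delivery cost (cents, costed resources only), professional minutes
# (human + facility per-minute resources) and partial flag per element.
.element_delivery_profile <- function(model) {
  do.call(rbind, lapply(model$elements, function(e) {
    req <- e$requirements
    cost <- 0; mins <- 0; partial <- FALSE
    for (i in seq_len(nrow(req))) {
      r <- model$resources[[req$resource[i]]]
      if (is.na(r$unit_cost_cents)) partial <- TRUE
      else cost <- cost + req$quantity[i] * r$unit_cost_cents
      if (r$cost_basis == "per_minute") mins <- mins + req$quantity[i]
    }
    data.frame(element = e$id, cost_cents_per_delivery = cost,
               minutes_per_delivery = mins, partial = partial,
               stringsAsFactors = FALSE)
  }))
}

#' Simulate realized service use along trajectories
#'
#' For every simulated patient-year, each element of the occupied state's
#' service is delivered with probability equal to its utilization rate,
#' as an annual all-or-nothing block of `frequency` deliveries (the
#' expectation either way equals frequency x utilization;
#' `per_delivery = TRUE` draws each delivery independently instead).
#' Realized costs are priced per delivery without expectation rounding.
#'
#' @param model a [care_model()]
#' @param trajectories a `care_trajectories` from [simulate_trajectories()]
#' @param seed integer seed
#' @param per_delivery draw each delivery as an independent Bernoulli
#' @return a `care_service_use` data frame: `patient`, `year`, `element`,
#'   `count`, `cost_cents`, `minutes`, `partial`
#' @export
simulate_service_use <- function(model, trajectories, seed,
                                 per_delivery = FALSE) {
  set.seed(seed)
  usage <- do.call(rbind, lapply(model$services, function(s) {
    if (nrow(s$usages) == 0L) return(NULL)
    cbind(service = s$id, s$usages, stringsAsFactors = FALSE)
  }))
  prof <- .element_delivery_profile(model)
  df <- merge(as.data.frame(trajectories)[c("patient", "year", "service")],
              usage, by = "service")
  df <- df[order(df$patient, df$year, df$element), , drop = FALSE]
  n <- nrow(df)
  if (n == 0L) {
    out <- data.frame(patient = integer(), year = integer(),
                      element = character(), count = numeric(),
                      cost_cents = numeric(), minutes = numeric(),
                      partial = logical())
    return(structure(out, seed = seed,
                     class = c("care_service_use", "data.frame")))
  }
  count <- if (per_delivery)
    stats::rbinom(n, size = round(df$frequency), prob = df$utilization)
  else
    df$frequency * stats::rbinom(n, size = 1L, prob = df$utilization)
  i <- match(df$element, prof$element)
  out <- data.frame(patient = df$patient, year = df$year,
                    element = df$element, count = count,
                    cost_cents = count * prof$cost_cents_per_delivery[i],
                    minutes = count * prof$minutes_per_delivery[i],
                    partial = prof$partial[i] & count > 0,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, seed = seed, class = c("care_service_use", "data.frame"))
}

#' Maximum-likelihood transition estimates from simulated trajectories
#'
#' Tabulates year-to-year segment transitions (tenure phases are
#' marginalized back to segments: advancing a phase is a stay) and the
#' absorptions recorded on each trajectory, and returns the row-wise
#' empirical frequencies as a transition model with implied stay
#' probabilities.
#'
#' @param trajectories a `care_trajectories`
#' @return a transition-model list (`states`, `absorbing`, `rows`) in the
#'   same form as `model$transitions`
#' @export
estimate_transition_matrix <- function(trajectories) {
  tr <- as.data.frame(trajectories)
  if (nrow(tr) == 0L) stop("no trajectories to estimate from", call. = FALSE)
  term <- attr(trajectories, "terminal")
  # consecutive within-patient segment pairs
  same <- tr$patient[-1] == tr$patient[-nrow(tr)]
  from <- tr$segment[-nrow(tr)][same]
  to <- tr$segment[-1][same]
  # final observed year -> absorbing state (censored rows contribute a
  # row-count only through their observed stays above)
  absorbed <- term[term$terminal != "censored", , drop = FALSE]
  last <- tr[paste(tr$patient, tr$year) %in%
               paste(absorbed$patient, absorbed$last_year), , drop = FALSE]
  from <- c(from, last$segment[order(last$patient)])
  to <- c(to, absorbed$terminal[order(absorbed$patient)])

  states <- sort(unique(tr$segment))
  dests <- sort(unique(to))
  absorbing <- setdiff(dests, states)
  counts <- table(factor(from, levels = states),
                  factor(to, levels = union(states, absorbing)))
  rows <- lapply(states, function(s) {
    n_row <- sum(counts[s, ])
    if (n_row == 0L) return(stats::setNames(numeric(0), character(0)))
    p <- counts[s, ] / n_row
    p <- p[names(p) != s & p > 0]
    stats::setNames(as.numeric(p), names(p))
  })
  list(states = states, absorbing = absorbing,
       rows = stats::setNames(rows, states))
}

#' Generate a random valid care model
#'
#' A small random model for property-style checks: 2-6 demand segments in
#' a forward chain, each with a one- or two-phase schedule of services
#' built from 1-5 random elements (5-60 minutes per delivery, unit costs
#' 0.10-2.00 per minute, frequencies 1-12, utilizations 0.1-1), and
#' annual leaving probabilities in [0.05, 0.95] split between progression
#' and exit. Draws from the current RNG stream; set a seed for
#' reproducibility.
#'
#' @param n_segments number of segments (default random in 2:6)
#' @return a validated [care_model()]
#' @export
random_care_model <- function(n_segments = sample(2:6, 1)) {
  n_res <- sample(2:4, 1)
  resources <- lapply(seq_len(n_res), function(i)
    list(id = paste0("R", i), name = paste0("Staff ", i), kind = "human",
         cost_basis = "per_minute",
         unit_cost_cents = sample(10:200, 1)))
  n_el <- sample(3:8, 1)
  elements <- lapply(seq_len(n_el), function(i)
    list(id = paste0("E", i), name = paste0("Element ", i),
         requirements = data.frame(
           resource = paste0("R", sample(n_res, 1)),
           quantity = sample(5:60, 1), stringsAsFactors = FALSE)))
  seg_ids <- paste0("G", seq_len(n_segments))
  services <- list()
  segments <- list()
  for (k in seq_len(n_segments)) {
    n_phase <- sample(1:2, 1)
    svc_ids <- paste0("S", k, letters[seq_len(n_phase)])
    for (sid in svc_ids) {
      n_use <- sample(1:5, 1)
      els <- sample(n_el, min(n_use, n_el))
      services[[sid]] <- list(
        id = sid, name = paste0("Service ", sid),
        usages = data.frame(element = paste0("E", els),
                            frequency = sample(1:12, length(els),
                                               replace = TRUE),
                            utilization = sample(1:10, length(els),
                                                 replace = TRUE) / 10,
                            stringsAsFactors = FALSE))
    }
    closed <- if (n_phase == 2) sample(1:3, 1) else 0
    phases <- data.frame(
      service = svc_ids,
      years = c(if (n_phase == 2) closed, NA_real_),
      stringsAsFactors = FALSE)
    segments[[seg_ids[k]]] <- list(
      id = seg_ids[k], name = paste0("Segment ", k),
      schedule = list(phases = phases,
                      expected_total_duration = closed + sample(1:5, 1)),
      outcomes = c(wellbeing = stats::runif(1, 0, 100)),
      behaviors = NULL)
  }
  rows <- list()
  for (k in seq_len(n_segments)) {
    leave <- stats::runif(1, 0.05, 0.95)
    if (k < n_segments) {
      w <- stats::runif(1, 0.2, 0.8)
      rows[[seg_ids[k]]] <- stats::setNames(
        c(leave * w, leave * (1 - w)), c(seg_ids[k + 1], "exit"))
    } else {
      rows[[seg_ids[k]]] <- c(exit = leave)
    }
  }
  care_model(
    resources = resources, elements = elements,
    services = unname(services), segments = unname(segments),
    transitions = list(entry = seg_ids[1], states = seg_ids,
                       absorbing = "exit", rows = rows,
                       assumed = character(0)),
    region = list(population = 1e5, annual_incidence = 100,
                  total_patients = NA_real_,
                  observed_segment_counts = NULL),
    metadata = list(name = "random model", currency = "EUR", year = 2026,
                    outcome_scales = list(wellbeing = c(0, 100))))
}
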