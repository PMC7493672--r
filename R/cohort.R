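# Discrete-time Markov cohort engine.
#
# Time step is one year: services are consumed during the year of
# occupancy and transitions are applied at year end. Segments with
# multi-phase schedules are expanded into tenure year-states (year 1,
# year 2, ..., open tail) so that first-year service packages (e.g.
# insulin stabilization) are distinguished from subsequent years; staying
# in a segment advances the tenure phase, and leaving probabilities are
# identical across phases, so marginalizing phases recovers the original
# segment-level matrix.

#' Mean sojourn time in a demand segment
#'
#' Under the annual transition model a patient leaves a segment each year
#' with the summed leaving probability of its row, so the sojourn is
#' geometric and its mean is the reciprocal of that sum.
#'
#' @param model a [care_model()]
#' @param segment transient segment id
#' @return expected years in the segment
#' @examples
#' mean_sojourn(t2d_model(), "DS2")  # 1 / (0.313 + 0.05 + 0.012) = 2.667
#' @export
mean_sojourn <- function(model, segment) {
  if (!segment %in% model$transitions$states)
    stop("not a transient segment: ", segment, call. = FALSE)
  p <- .leave_total(model, segment)
  if (p <= 0)
    stop(sprintf("immortal state: segment '%s' has zero leaving probability",
                 segment), call. = FALSE)
  1 / p
}

#' Expand a model's transition matrix over tenure phases
#'
#' Each transient segment whose schedule has more than one phase is split
#' into year-states `seg:1, seg:2, ...` ending in an open self-loop state.
#' Staying in the segment advances the year-state; leaving probabilities
#' are those of the segment row, from every year-state alike.
#'
#' @param model a [care_model()]
#' @return an `expanded_chain`: `states` (expanded transient names), `map`
#'   (state, segment, phase_year, service, open), `absorbing`, and the full
#'   row-stochastic matrix `P` over `c(states, absorbing)` with absorbing
#'   self-loops
#' @export
expand_tenure <- function(model) {
  t <- model$transitions
  maps <- list()
  for (s in t$states) {
    g <- model$segments[[s]]
    ph <- g$schedule$phases
    closed <- sum(ph$years, na.rm = TRUE)
    K <- as.integer(closed + 1L)
    svc <- character(K)
    yr <- 1L
    for (i in seq_len(nrow(ph))) {
      n <- if (is.na(ph$years[i])) K - yr + 1L else as.integer(ph$years[i])
      if (n <= 0) next
      svc[yr:(yr + n - 1L)] <- ph$service[i]
      yr <- yr + n
    }
    if (yr <= K) svc[yr:K] <- ph$service[nrow(ph)]
    maps[[s]] <- data.frame(
      state = paste0(s, ":", seq_len(K)), segment = s,
      phase_year = seq_len(K), service = svc,
      open = seq_len(K) == K, stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, c(maps, list(make.row.names = FALSE)))
  states <- map$state
  cols <- c(states, t$absorbing)
  P <- matrix(0, nrow = length(states), ncol = length(cols),
              dimnames = list(states, cols))
  for (i in seq_len(nrow(map))) {
    s <- map$segment[i]
    row <- t$rows[[s]]
    stay <- 1 - sum(row)
    nxt <- if (map$open[i]) map$state[i]
           else paste0(s, ":", map$phase_year[i] + 1L)
    P[i, nxt] <- P[i, nxt] + stay
    for (d in names(row)) {
      dest <- if (d %in% t$states) paste0(d, ":1") else d
      P[i, dest] <- P[i, dest] + row[[d]]
    }
  }
  # absorbing self-loops, appended as identity rows
  A <- matrix(0, nrow = length(t$absorbing), ncol = length(cols),
              dimnames = list(t$absorbing, cols))
  for (a in t$absorbing) A[a, a] <- 1
  structure(list(states = states, map = map, absorbing = t$absorbing,
                 P = rbind(P, A)),
            class = "expanded_chain")
}

#' Marginalize an expanded chain back to the segment level
#'
#' Sums each expanded row's probabilities by destination segment. Rows of
#' the same segment are identical by construction; one row per segment is
#' returned, which must equal the original segment-level matrix.
#'
#' @param chain an `expanded_chain`
#' @return matrix: transient segments x (segments + absorbing), including
#'   the implied stay probability on the diagonal
#' @export
segment_matrix <- function(chain) {
  map <- chain$map
  segs <- unique(map$segment)
  cols <- c(segs, chain$absorbing)
  col_seg <- c(map$segment[match(chain$states, map$state)], chain$absorbing)
  M <- matrix(0, nrow = length(segs), ncol = length(cols),
              dimnames = list(segs, cols))
  for (s in segs) {
    i <- match(paste0(s, ":1"), chain$states)
    M[s, ] <- tapply(chain$P[i, ], factor(col_seg, levels = cols), sum)
  }
  M
}

#' @export
print.expanded_chain <- function(x, ...) {
  cat(sprintf("<expanded_chain> %d transient year-states over %d segments; absorbing: %s\n",
              length(x$states), length(unique(x$map$segment)),
              paste(x$absorbing, collapse = ", ")))
  invisible(x)
}

.inflow_vector <- function(chain, incidence, entry) {
  inflow <- stats::setNames(numeric(length(chain$states)), chain$states)
  if (length(incidence) == 1L && is.null(names(incidence))) {
    inflow[paste0(entry, ":1")] <- incidence
  } else {
    for (s in names(incidence)) {
      key <- paste0(s, ":1")
      if (!key %in% chain$states)
        stop("entry segment not in transition model: ", s, call. = FALSE)
      inflow[key] <- incidence[[s]]
    }
  }
  inflow
}

#' Project cohort occupancy year by year
#'
#' New entrants are added at the start of each year; the annual transition
#' matrix is applied at year end. Year `t`'s occupancy is the expected
#' number of patients receiving care in each expanded state during year
#' `t`; absorbing states accumulate cumulative exits. Patients are
#' conserved: at every year, cumulative inflow equals current transient
#' occupancy plus cumulative absorptions.
#'
#' @param model a [care_model()]
#' @param incidence new patients per year: a single number (entering at
#'   `entry`) or a named vector by entry segment
#' @param horizon number of years (>= 1)
#' @param entry entry segment id for scalar `incidence`
#' @return a `care_projection`: `occupancy` (horizon x expanded states),
#'   `exits` (horizon x absorbing, cumulative), plus the chain and inflow
#' @export
cohort_project <- function(model, incidence, horizon,
                           entry = model$transitions$entry) {
  stopifnot(horizon >= 1, all(incidence >= 0))
  chain <- expand_tenure(model)
  inflow <- .inflow_vector(chain, incidence, entry)
  nt <- length(chain$states)
  cols <- colnames(chain$P)
  occ <- matrix(0, nrow = horizon, ncol = length(cols),
                dimnames = list(NULL, cols))
  cur <- c(inflow, stats::setNames(numeric(length(chain$absorbing)),
                                   chain$absorbing))
  occ[1, ] <- cur
  if (horizon > 1) for (t in 2:horizon) {
    cur <- as.numeric(cur %*% chain$P)
    names(cur) <- cols
    cur[chain$states] <- cur[chain$states] + inflow
    occ[t, ] <- cur
  }
  structure(list(occupancy = occ[, chain$states, drop = FALSE],
                 exits = occ[, chain$absorbing, drop = FALSE],
                 chain = chain, inflow = inflow, horizon = horizon),
            class = "care_projection")
}

#' Roll expanded-state occupancy up to segments
#' @param x a named vector over expanded states, or a `care_projection`
#' @return named vector (or matrix, years x segments) by segment
#' @export
occupancy_by_segment <- function(x) {
  if (inherits(x, "care_projection")) {
    seg <- x$chain$map$segment[match(colnames(x$occupancy),
                                     x$chain$map$state)]
    return(t(apply(x$occupancy, 1, function(r)
      tapply(r, factor(seg, levels = unique(seg)), sum))))
  }
  seg <- sub(":[0-9]+$", "", names(x))
  c(tapply(x, factor(seg, levels = unique(seg)), sum))
}

#' @export
print.care_projection <- function(x, ...) {
  cat(sprintf("<care_projection> %d years, %d expanded states\n",
              x$horizon, length(x$chain$states)))
  bys <- occupancy_by_segment(x)
  last <- round(bys[nrow(bys), ], 1)
  cat("  final-year occupancy:",
      paste(sprintf("%s=%g", names(last), last), collapse = ", "), "\n")
  ex <- x$exits[nrow(x$exits), ]
  cat("  cumulative exits:",
      paste(sprintf("%s=%g", names(ex), round(ex, 1)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.care_projection <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  map <- x$chain$map
  long <- expand.grid(year = seq_len(x$horizon), state = x$chain$states,
                      stringsAsFactors = FALSE)
  i <- match(long$state, map$state)
  long$segment <- map$segment[i]
  long$tenure_phase <- map$phase_year[i]
  long$service <- map$service[i]
  long$count <- as.numeric(x$occupancy[cbind(long$year,
                                             match(long$state,
                                                   colnames(x$occupancy)))])
  ex <- as.data.frame.table(x$exits, stringsAsFactors = FALSE)
  names(ex) <- c("year", "state", "cumulative_exits")
  attr(long, "exits") <- ex
  long
}

#' Occupancy trajectories plotted by segment
#' @param x a `care_projection`
#' @param ... passed to [graphics::matplot()]
#' @export
plot.care_projection <- function(x, ...) {
  bys <- occupancy_by_segment(x)
  graphics::matplot(seq_len(nrow(bys)), bys, type = "l", lty = 1,
                    xlab = "year", ylab = "expected patients", ...)
  graphics::legend("bottomright", legend = colnames(bys),
                   col = seq_len(ncol(bys)), lty = 1, bty = "n")
  invisible(x)
}

#' Steady-state occupancy under constant incidence
#'
#' Solves the linear balance equations (inflow = outflow per expanded
#' state), the limit of [cohort_project()] as the horizon grows.
#'
#' @inheritParams cohort_project
#' @return named vector of expected patient counts per expanded state,
#'   with the per-segment rollup as attribute `by_segment`
#' @examples
#' # one segment, leave 0.375, incidence 910 -> 910 / 0.375 = 2427 patients
#' @export
steady_state_occupancy <- function(model, incidence,
                                   entry = model$transitions$entry) {
  chain <- expand_tenure(model)
  inflow <- .inflow_vector(chain, incidence, entry)
  Q <- chain$P[chain$states, chain$states, drop = FALSE]
  x <- tryCatch(
    solve(diag(length(chain$states)) - t(Q), inflow),
    error = function(e) stop("immortal state: balance equations are singular",
                             call. = FALSE))
  x <- stats::setNames(as.numeric(x), chain$states)
  attr(x, "by_segment") <- occupancy_by_segment(x)
  x
}

#' Expected years spent in each state over a full journey
#'
#' For a single entrant, the expected total years in each expanded state
#' before absorption, from the fundamental matrix of the absorbing chain
#' (a linear solve, not a simulation).
#'
#' @param model a [care_model()]
#' @param entry entry segment id
#' @return named vector over expanded states; rollup via
#'   [visits_by_segment()]
#' @export
expected_visits <- function(model, entry = model$transitions$entry) {
  chain <- expand_tenure(model)
  key <- paste0(entry, ":1")
  if (!key %in% chain$states)
    stop("entry segment not in transition model: ", entry, call. = FALSE)
  Q <- chain$P[chain$states, chain$states, drop = FALSE]
  e <- stats::setNames(numeric(length(chain$states)), chain$states)
  e[key] <- 1
  v <- tryCatch(
    solve(diag(length(chain$states)) - t(Q), e),
    error = function(e) stop("immortal state: fundamental matrix is singular",
                             call. = FALSE))
  stats::setNames(as.numeric(v), chain$states)
}

#' Roll expected visits up to segments
#' @param v named vector over expanded states (from [expected_visits()])
#' @return named vector of expected years per segment
#' @export
visits_by_segment <- function(v) occupancy_by_segment(v)
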