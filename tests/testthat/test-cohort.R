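m <- t2d_model()

test_that("mean sojourn is the reciprocal of the summed leaving probabilities", {
  # published row: 0.313 + 0.05 + 0.012 = 0.375 -> 2.667 years, under 3
  expect_equal(mean_sojourn(m, "DS2"), 1 / 0.375)
  expect_lt(mean_sojourn(m, "DS2"), 3)
  # certain annual exit -> exactly one year
  expect_identical(mean_sojourn(toy_single_segment(leave = 1), "G1"), 1)
  # immortal segment is an error
  imm <- toy_single_segment(leave = 0.5)
  imm$transitions$rows$G1 <- c(exit = 0)
  expect_error(mean_sojourn(imm, "G1"), "immortal")

  # Monte-Carlo oracle: geometric sojourns at an arbitrary leave probability
  set.seed(7)
  p <- 0.23
  draws <- 1 + stats::rgeom(1e6, p)
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mean_sojourn(toy_single_segment(leave = p),
                                           "G1")),
            3 * se)
})

test_that("tenure expansion splits phased segments and marginalizes back", {
  chain <- expand_tenure(m)
  # DS2 and DS4 have a first-year service: two year-states each
  expect_setequal(chain$map$state[chain$map$segment == "DS2"],
                  c("DS2:1", "DS2:2"))
  expect_identical(chain$map$service[chain$map$state == "DS4:1"], "S5")
  expect_identical(chain$map$service[chain$map$state == "DS4:2"], "S6")
  # single-phase DS3 stays one state
  expect_identical(sum(chain$map$segment == "DS3"), 1L)
  # rows are stochastic
  expect_equal(unname(rowSums(chain$P)), rep(1, nrow(chain$P)))
  # marginalizing phases recovers the original rows
  M <- segment_matrix(chain)
  expect_equal(M["DS2", c("DS3", "DS5", "exit")],
               c(DS3 = 0.313, DS5 = 0.05, exit = 0.012))
  expect_equal(unname(M["DS2", "DS2"]), 0.625)
  for (s in m$transitions$states)
    expect_equal(unname(M[s, s]), 1 - sum(m$transitions$rows[[s]]))
})

test_that("expanded and collapsed chains project identical segment occupancy", {
  set.seed(11)
  for (rep in 1:3) {
    rm <- random_care_model()
    pr <- cohort_project(rm, 100, horizon = 50)
    got <- occupancy_by_segment(pr)
    # oracle: iterate the segment-level matrix directly
    chain <- expand_tenure(rm)
    M <- segment_matrix(chain)
    segs <- rm$transitions$states
    Mt <- M[segs, segs, drop = FALSE]
    inflow <- stats::setNames(numeric(length(segs)), segs)
    inflow[rm$transitions$entry] <- 100
    x <- inflow
    for (t in 1:50) {
      expect_equal(unname(got[t, segs]), unname(x), tolerance = 1e-10)
      x <- as.numeric(x %*% Mt) + inflow
      names(x) <- segs
    }
  }
})

test_that("projection conserves patients and handles the no-exit edge case", {
  # no exits: occupancy grows linearly with cumulative inflow
  imm <- toy_single_segment(leave = 0.5)
  imm$transitions$rows$G1 <- c(exit = 0)
  pr <- cohort_project(imm, 100, horizon = 10)
  expect_equal(unname(pr$occupancy[, "G1:1"]), 100 * (1:10))

  # conservation on the bundled model: inflow = occupancy + absorptions
  pr2 <- cohort_project(m, 910, horizon = 80)
  for (t in c(1, 10, 40, 80))
    expect_equal(sum(pr2$occupancy[t, ]) + sum(pr2$exits[t, ]),
                 910 * t, tolerance = 1e-9)
})

test_that("short-horizon projection matches exhaustive path enumeration", {
  p_ab <- 0.3; p_ax <- 0.1; p_b <- 0.25
  toy2 <- toy_two_segment(p_ab, p_ax, p_b)
  H <- 5
  pr <- cohort_project(toy2, 50, horizon = H)
  # enumerate every state path for each entry cohort
  P <- matrix(0, 3, 3, dimnames = list(c("A", "B", "exit"),
                                       c("A", "B", "exit")))
  P["A", ] <- c(1 - p_ab - p_ax, p_ab, p_ax)
  P["B", ] <- c(0, 1 - p_b, p_b)
  P["exit", "exit"] <- 1
  occ <- matrix(0, H, 3, dimnames = list(NULL, colnames(P)))
  paths <- function(state, prob, t) {
    if (t > H) return()
    occ[t, state] <<- occ[t, state] + prob
    for (nxt in colnames(P))
      if (P[state, nxt] > 0) paths(nxt, prob * P[state, nxt], t + 1)
  }
  # one 50-patient cohort enters at the start of every year
  for (entry_year in 1:H) paths("A", 50, entry_year)
  expect_equal(unname(pr$occupancy[, "A:1"]), unname(occ[, "A"]),
               tolerance = 1e-12)
  expect_equal(unname(pr$occupancy[, "B:1"]), unname(occ[, "B"]),
               tolerance = 1e-12)
})

test_that("projection converges to incidence times mean sojourn", {
  pr <- cohort_project(m, 910, horizon = 60)
  ds2 <- occupancy_by_segment(pr)[60, "DS2"]
  expect_equal(unname(ds2), 910 / 0.375, tolerance = 1e-6)
})

test_that("steady state solves the balance equations and matches the long run", {
  # single state: 910 / 0.375 = 2426.67
  toy <- toy_single_segment(leave = 0.375)
  ss <- steady_state_occupancy(toy, 910)
  expect_equal(unname(ss["G1:1"]), 910 / 0.375)

  # equals the horizon-500 projection on random models
  set.seed(23)
  for (rep in 1:3) {
    rm <- random_care_model(5)
    ss <- steady_state_occupancy(rm, 100)
    pr <- cohort_project(rm, 100, horizon = 500)
    expect_equal(as.numeric(ss), unname(pr$occupancy[500, names(ss)]),
                 tolerance = 1e-6)
  }

  # zero incidence -> empty system
  expect_equal(as.numeric(steady_state_occupancy(m, 0)),
               rep(0, length(expand_tenure(m)$states)))
})

test_that("expected visits follow the absorbing-chain closed form", {
  # one state with leave p: 1/p years
  expect_equal(unname(expected_visits(toy_single_segment(leave = 0.2))),
               5)
  # bundled model: 2.667 years in DS2 across its tenure states
  v <- expected_visits(m)
  expect_equal(unname(visits_by_segment(v)["DS2"]), 1 / 0.375)

  # Little's law: steady state = incidence x expected visits
  set.seed(31)
  for (rep in 1:3) {
    rm <- random_care_model()
    ss <- steady_state_occupancy(rm, 100)
    v <- expected_visits(rm)
    expect_equal(as.numeric(ss), 100 * unname(v), tolerance = 1e-9)
  }

  # Monte-Carlo oracle on a random 4-segment chain
  set.seed(37)
  rm <- random_care_model(4)
  v <- visits_by_segment(expected_visits(rm))
  tr <- simulate_trajectories(rm, n = 2e4, horizon = 200, seed = 99)
  yrs <- table(factor(tr$segment, levels = names(v))) / 2e4
  for (s in names(v)) {
    per_patient <- tabulate(
      factor(tr$patient[tr$segment == s], levels = 1:2e4), nbins = 2e4)
    se <- stats::sd(per_patient) / sqrt(2e4)
    expect_lt(abs(mean(per_patient) - v[[s]]), 3 * se + 1e-9)
  }
})
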