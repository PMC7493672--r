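m <- t2d_model()

test_that("trajectory simulation respects the chain and the seed", {
  # no patients -> empty trajectory set
  tr0 <- simulate_trajectories(m, n = 0, horizon = 10, seed = 1)
  expect_identical(nrow(as.data.frame(tr0)), 0L)

  # certain annual exit -> every trajectory is exactly one year long
  det <- toy_single_segment(leave = 1)
  tr1 <- simulate_trajectories(det, n = 500, horizon = 10, seed = 2)
  expect_identical(nrow(as.data.frame(tr1)), 500L)
  expect_true(all(tr1$year == 1))
  expect_true(all(attr(tr1, "terminal")$terminal == "exit"))

  # the same seed reproduces the run bit for bit
  a <- simulate_trajectories(m, n = 2000, horizon = 100, seed = 33)
  b <- simulate_trajectories(m, n = 2000, horizon = 100, seed = 33)
  expect_identical(as.data.frame(a), as.data.frame(b))

  # transitions only along arcs with positive probability
  chain <- expand_tenure(m)
  idx <- cbind(match(a$state[-nrow(a)], rownames(chain$P)),
               match(a$state[-1], colnames(chain$P)))
  same_patient <- a$patient[-1] == a$patient[-nrow(a)]
  expect_true(all(chain$P[idx[same_patient, , drop = FALSE]] > 0))

  # mean DS2 sojourn agrees with the geometric closed form within 3 SE
  tr <- simulate_trajectories(m, n = 2e4, horizon = 150, seed = 8)
  ds2_years <- tabulate(factor(tr$patient[tr$segment == "DS2"],
                               levels = 1:2e4), nbins = 2e4)
  se <- stats::sd(ds2_years) / sqrt(2e4)
  expect_lt(abs(mean(ds2_years) - mean_sojourn(m, "DS2")), 3 * se)
})

test_that("realized service use matches its closed-form expectation", {
  # fabricated patient-years receiving the lifestyle-care service
  n <- 1e5
  fake <- structure(
    data.frame(patient = seq_len(n), year = 1, state = "DS2:2",
               segment = "DS2", tenure_phase = 2, service = "S3",
               stringsAsFactors = FALSE),
    class = c("care_trajectories", "data.frame"))
  use <- simulate_service_use(m, fake, seed = 12)

  # delivered counts are 0 or the full annual frequency
  s3 <- m$services$S3$usages
  for (i in seq_len(nrow(s3))) {
    cnt <- use$count[use$element == s3$element[i]]
    expect_true(all(cnt %in% c(0, s3$frequency[i])))
    # uptake frequency within 3 binomial SE of the utilization rate
    p_hat <- mean(cnt > 0)
    se <- sqrt(s3$utilization[i] * (1 - s3$utilization[i]) / n)
    expect_lt(abs(p_hat - s3$utilization[i]), 3 * se + 1e-12)
  }

  # mean realized cost within 3 SE of the un-rounded expectation (52.69)
  per_year <- tapply(use$cost_cents, use$patient, sum)
  closed <- service_annual_cost(m, "S3", round_quantities = FALSE)$cost_cents
  expect_equal(closed, 5269)
  se <- stats::sd(per_year) / sqrt(n)
  expect_lt(abs(mean(per_year) - closed), 3 * se)

  # with 100% utilization the realized cost is exactly the closed form
  full <- t2d_model()
  full$services$S3$usages$utilization <- rep(1, nrow(s3))
  use_full <- simulate_service_use(full, fake[1:100, ], seed = 3)
  per_year_full <- tapply(use_full$cost_cents, use_full$patient, sum)
  expect_true(all(per_year_full ==
                    service_annual_cost(full, "S3",
                                        round_quantities = FALSE)$cost_cents))

  # fixed seed -> bit-identical realized counts
  expect_identical(as.data.frame(simulate_service_use(m, fake[1:500, ],
                                                      seed = 4)),
                   as.data.frame(simulate_service_use(m, fake[1:500, ],
                                                      seed = 4)))
})

test_that("transition estimation recovers the generating matrix", {
  tr <- simulate_trajectories(m, n = 2e4, horizon = 150, seed = 21)
  est <- estimate_transition_matrix(tr)
  n_ds2 <- sum(tr$segment == "DS2")
  for (dest in c("DS3", "DS5", "exit")) {
    truth <- m$transitions$rows$DS2[[dest]]
    se <- sqrt(truth * (1 - truth) / n_ds2)
    expect_lt(abs(est$rows$DS2[[dest]] - truth), 3 * se)
  }
  # estimated rows are valid probability rows with implied stay
  for (s in est$states) {
    expect_true(all(est$rows[[s]] >= 0 & est$rows[[s]] <= 1))
    expect_lte(sum(est$rows[[s]]), 1)
  }

  # a deterministic chain is recovered exactly
  det <- toy_two_segment(p_ab = 1, p_a_exit = 0, p_b = 1)
  trd <- simulate_trajectories(det, n = 200, horizon = 10, seed = 5)
  estd <- estimate_transition_matrix(trd)
  expect_identical(estd$rows$A, c(B = 1))
  expect_identical(estd$rows$B, c(exit = 1))

  expect_error(estimate_transition_matrix(
    simulate_trajectories(m, 0, 10, seed = 1)), "no trajectories")
})

test_that("the random model generator emits valid, simulable models", {
  set.seed(77)
  for (rep in 1:5) {
    rm <- random_care_model()
    expect_identical(nrow(validate_care_model(rm)), 0L)
    expect_gt(cost_total(journey_cost(rm, mode = "markov")), 0)
  }
})

test_that("the bundled model's assumed rows match the declared mean durations", {
  expect_setequal(m$transitions$assumed, c("DS3", "DS4"))
  expect_equal(sum(m$transitions$rows$DS3), 1 / 9)
  expect_equal(sum(m$transitions$rows$DS4), 1 / 10)
  expect_equal(mean_sojourn(m, "DS3"), 9)
  expect_equal(mean_sojourn(m, "DS4"), 10)
})
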