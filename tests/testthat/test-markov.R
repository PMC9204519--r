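test_that("follow-up bands map months correctly and reject the rest", {
  expect_identical(band_for_month(2), "band_2_12")
  expect_identical(band_for_month(12), "band_2_12")
  expect_identical(band_for_month(13), "band_13_24")
  expect_identical(band_for_month(24), "band_13_24")
  expect_identical(band_for_month(25), "band_25_60")
  expect_identical(band_for_month(60), "band_25_60")
  expect_error(band_for_month(1), "2\\.\\.60")
  expect_error(band_for_month(61), "2\\.\\.60")
  expect_error(band_for_month(12.5), "integer")
})

test_that("transition matrices carry the published rates and are row-stochastic", {
  p <- default_params()
  P <- build_transition_matrix(p, "tavr", 6)
  expect_equal(unname(P["no_event", ]),
               c(0.9904, 0.001, 0.0017, 0.0007, 0.0036 + 0.0026))
  # post-AF mortality: AF-specific rate plus the arm's banded CV mortality
  expect_equal(unname(P["post_af", "death"]), 0.0024 + 0.0036)
  expect_equal(unname(P["post_disabling_stroke", "death"]), 0.0036 + 0.0026)
  expect_equal(unname(P["death", ]), c(0, 0, 0, 0, 1))
  # no backward edges
  expect_identical(unname(P["post_disabling_stroke", "post_af"]), 0)
  expect_identical(unname(P["post_non_disabling_stroke", "no_event"]), 0)

  for (arm in c("tavr", "savr")) for (m in c(2, 12, 13, 24, 25, 60)) {
    M <- build_transition_matrix(p, arm, m)
    expect_equal(unname(rowSums(M)), rep(1, 5), tolerance = 1e-12)
    expect_true(all(M >= 0))
  }

  bad <- p
  bad$transitions$tavr$af["band_2_12"] <- 0.7
  bad$transitions$tavr$disabling_stroke["band_2_12"] <- 0.7
  expect_error(build_transition_matrix(bad, "tavr", 5),
               "infeasible probabilities.*no_event.*month 5")
})

test_that("a two-cycle hand computation matches run_cohort", {
  p <- default_params()
  s0 <- c(0.815, 0.091, 0.032, 0.023, 0.039)
  # months 2-12 matrix written out from the published cells
  P <- rbind(
    c(0.9904, 0.0010, 0.0017, 0.0007, 0.0062),
    c(0,      0.9924, 0.0011, 0.0005, 0.0024 + 0.0036),
    c(0,      0,      0.9938, 0,      0.0062),
    c(0,      0,      0,      0.9938, 0.0062),
    c(0,      0,      0,      0,      1))
  m2 <- as.numeric(s0 %*% P)
  m3 <- as.numeric(m2 %*% P)
  trace <- run_cohort(s0, p, "tavr")
  expect_equal(unname(trace$occupancy[2, ]), m2, tolerance = 1e-12)
  expect_equal(unname(trace$occupancy[3, ]), m3, tolerance = 1e-12)
  # flows recorded for the event-bearing edges in cycle 2
  expect_equal(unname(trace$flows[1, "into_af"]), s0[1] * 0.0010)
  expect_equal(unname(trace$flows[1, "into_disabling"]),
               s0[1] * 0.0017 + s0[2] * 0.0011)
  expect_equal(unname(trace$flows[1, "stroke_to_death"]),
               (s0[3] + s0[4]) * 0.0062)
})

test_that("degenerate cohorts behave exactly", {
  p <- default_params()
  dead <- c(0, 0, 0, 0, 1)
  trace <- run_cohort(dead, p, "tavr")
  expect_true(all(trace$occupancy[, "death"] == 1))
  acc <- accumulate_trace(trace, p, "tavr")
  expect_identical(acc$cost, 0)
  expect_identical(acc$qaly, 0)

  frozen <- immortal_params()
  tr2 <- run_cohort(c(0.6, 0.2, 0.1, 0.05, 0.05), frozen, "savr")
  for (m in 1:60)
    expect_equal(unname(tr2$occupancy[m, ]), c(0.6, 0.2, 0.1, 0.05, 0.05))
})

test_that("probability is conserved and death is absorbing on random sets", {
  for (s in 1:100) {
    p <- random_valid_params(s)
    arm <- if (s %% 2) "tavr" else "savr"
    trace <- run_cohort(initial_state_vector(p$incidences[[arm]]), p, arm)
    expect_equal(unname(rowSums(trace$occupancy)), rep(1, 60),
                 tolerance = 1e-9)
    expect_true(all(trace$occupancy >= -1e-15))
    expect_true(all(diff(trace$occupancy[, "death"]) >= -1e-15))
  }
})

test_that("an individual-level walker simulation reproduces the cohort", {
  p <- default_params()
  s0 <- initial_state_vector(p$incidences$tavr)
  trace <- run_cohort(s0, p, "tavr")

  set.seed(2024)
  n <- 1e5
  state <- sample.int(5, n, replace = TRUE, prob = s0)
  cumP <- lapply(c(2, 13, 25), function(m)
    t(apply(build_transition_matrix(p, "tavr", m), 1, cumsum)))
  occ_at <- list()
  for (m in 2:60) {
    cp <- cumP[[if (m <= 12) 1 else if (m <= 24) 2 else 3]]
    u <- runif(n)
    state <- 1L + rowSums(u > cp[state, , drop = FALSE])
    if (m %in% c(12, 24, 60)) occ_at[[as.character(m)]] <- tabulate(state, 5) / n
  }
  for (m in c(12, 24, 60)) {
    emp <- occ_at[[as.character(m)]]
    thry <- unname(trace$occupancy[m, ])
    se <- sqrt(pmax(thry * (1 - thry), 1e-12) / n)
    expect_true(all(abs(emp - thry) <= 3 * se + 1e-12),
                info = paste("month", m))
  }
})

test_that("zero-risk cohort QALY equals the discounted geometric series", {
  u <- 0.74
  p <- immortal_params(u = u)
  p$options$qaly_discount <- TRUE
  res <- run_strategy(p, "tavr")
  d <- 1 / (1 + annual_to_monthly_discount(0.037))
  closed <- u / 12 * (1 + sum(d^(1:59)))
  expect_equal(res$total_qaly, closed, tolerance = 1e-12)
  # undiscounted counterpart: a flat 60 months
  p$options$qaly_discount <- FALSE
  expect_equal(run_strategy(p, "tavr")$total_qaly, 60 * u / 12,
               tolerance = 1e-12)
})

test_that("discounting never increases totals; equality only at rate zero", {
  p <- default_params()
  p$options$qaly_discount <- TRUE
  disc <- run_base_case(p)
  p0 <- p
  p0$annual_discount_rate <- 0
  undisc <- run_base_case(p0)
  for (arm in c("tavr", "savr")) {
    expect_lt(disc[[arm]]$total_cost, undisc[[arm]]$total_cost)
    expect_lt(disc[[arm]]$total_qaly, undisc[[arm]]$total_qaly)
  }
  again <- run_base_case(p0)
  expect_equal(again$tavr$total_cost, undisc$tavr$total_cost)
})

test_that("trace export has one row per month with accruals and discounts", {
  res <- run_strategy(default_params(), "savr")
  tt <- trace_table(res)
  expect_equal(nrow(tt), 60)
  expect_equal(tt$discount[1], 1)
  expect_equal(sum(tt$cycle_cost), res$total_cost)
  expect_equal(sum(tt$cycle_qaly), res$total_qaly)
  expect_true(all(diff(tt$discount[-1]) < 0))
})
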