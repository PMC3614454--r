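test_that("design validation enforces the look schedule and thresholds", {
  expect_error(design_spec(look_fractions = c(0.75, 0.5, 1)),
               "look_fractions")
  expect_error(design_spec(look_fractions = c(0.5, 0.75)),
               "look_fractions")
  expect_error(design_spec(mean_threshold = 1.2), "mean_threshold")
  d <- design_spec()
  expect_equal(d$look_n, c(25, 38, 50))
})

test_that("posterior summaries follow the Beta closed forms", {
  flat <- posterior_ppa(0, 0)
  expect_equal(flat$mean, 0.5)
  expect_equal(c(flat$lower, flat$upper), c(0.025, 0.975),
               tolerance = 1e-12)

  p <- posterior_ppa(31, 38)
  expect_equal(p$mean, 32 / 40)
  expect_equal(p$lower, qbeta(0.025, 32, 8), tolerance = 1e-12)
  expect_true(p$lower <= p$mean && p$mean <= p$upper)

  means <- vapply(0:38, function(x) posterior_ppa(x, 38)$mean, 0)
  expect_true(all(diff(means) > 0))
  expect_error(posterior_ppa(40, 38), "x")
})

test_that("the second look accepts on 31/38 and 32/38 agreements", {
  d <- design_spec()
  dec <- evaluate_look(c(HNSCC = 31, LUNG_SCC = 32), c(38, 38), 2, d)
  expect_equal(dec$decision, "accept")
  expect_equal(dec$posteriors[[1]]$mean, 0.800)
  expect_equal(dec$posteriors[[2]]$mean, 0.825)
  expect_gte(dec$posteriors[[1]]$lower, 0.65)
  expect_gte(dec$posteriors[[2]]$lower, 0.65)
})

test_that("look decisions cover accept, futility, continue, and final fail", {
  d <- design_spec()
  expect_equal(evaluate_look(c(50, 50), c(50, 50), 3, d)$decision,
               "accept")
  expect_equal(evaluate_look(c(10, 10), c(38, 38), 2, d)$decision,
               "stop_futility")
  cont <- evaluate_look(c(20, 20), c(25, 25), 1, d)
  expect_equal(cont$decision, "continue")
  expect_gte(cont$pps, d$futility_threshold)
  # no continue at the final look
  expect_equal(evaluate_look(c(30, 30), c(50, 50), 3, d)$decision,
               "fail")
  expect_error(evaluate_look(c(1, 1), c(25, 25), 4, d), "schedule")
  expect_error(evaluate_look(c(10, 10), c(30, 30), 1, d), "look-1")
})

test_that("predictive probability of success behaves at its boundaries", {
  d <- design_spec()
  # 0/25 toward 50: final acceptance needs 41 successes, 25 remain
  expect_lt(predictive_probability_of_success(c(0, 0), 25, d), 1e-6)
  # already past the final acceptance boundary in both classes
  easy <- design_spec(mean_threshold = 0.1, lower_threshold = 0.01)
  expect_equal(predictive_probability_of_success(c(25, 25), 38, easy), 1)
  expect_error(predictive_probability_of_success(c(40, 40), 50, d),
               "smaller than")
  # monotone non-decreasing in x at fixed n
  pps <- vapply(0:38, function(x)
    predictive_probability_of_success(c(x, 38), 38, d), 0)
  expect_true(all(diff(pps) >= -1e-12))
})

test_that("Monte Carlo predictive probabilities agree with exact enumeration", {
  d <- design_spec(pps_draws = 20000, seed = 9)
  set.seed(9)
  for (i in 1:20) {
    x <- sample(0:38, 2, replace = TRUE)
    exact <- predictive_probability_of_success(x, 38, d, method = "exact")
    mc <- predictive_probability_of_success(x, 38, d, method = "mc")
    se <- sqrt(max(exact * (1 - exact), 1e-12) / d$pps_draws)
    expect_lte(abs(mc - exact), 3 * se + 1e-9)
  }
})

test_that("certain truth is always accepted and simulations are deterministic", {
  d <- design_spec()
  oc <- simulate_operating_characteristics(d, 1.0, 500, seed = 2)
  expect_equal(oc$acceptance_rate, 1.0)
  expect_equal(oc$expected_n_per_class, 25)  # all accept at look 1
  oc2 <- simulate_operating_characteristics(d, 0.8, 500, seed = 2)
  oc3 <- simulate_operating_characteristics(d, 0.8, 500, seed = 2)
  expect_identical(oc2, oc3)
})

test_that("a single-look design matches the closed-form binomial product", {
  d1 <- design_spec(n_max = 40, look_fractions = 1, seed = 2)
  smin <- 0
  while (!all(squamdx:::meets_acceptance(smin, 40, d1))) smin <- smin + 1
  closed <- pbinom(smin - 1, 40, 0.9, lower.tail = FALSE)^2
  oc <- simulate_operating_characteristics(d1, 0.9, 20000, seed = 2)
  se <- sqrt(closed * (1 - closed) / 20000)
  expect_lte(abs(oc$acceptance_rate - closed), 4 * se)
})

test_that("acceptance rate rises with true PPA and early looks only add paths", {
  d <- design_spec()
  rates <- vapply(c(0.65, 0.75, 0.85, 0.95), function(p)
    simulate_operating_characteristics(d, p, 3000, seed = 5)$acceptance_rate,
    0)
  expect_true(all(diff(rates) > -0.02))  # monotone within Monte-Carlo error

  # with futility effectively disabled, a multi-look design accepts at
  # least as often as its single-final-look counterpart
  dm <- design_spec(futility_threshold = 1e-9, seed = 7)
  ds <- design_spec(look_fractions = 1, futility_threshold = 1e-9,
                    seed = 7)
  am <- simulate_operating_characteristics(dm, 0.82, 5000,
                                           seed = 7)$acceptance_rate
  as_ <- simulate_operating_characteristics(ds, 0.82, 5000,
                                            seed = 7)$acceptance_rate
  expect_gte(am, as_ - 0.02)
})
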