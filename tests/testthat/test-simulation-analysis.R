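test_that("closed-form steady state agrees with the iterated recursion", {
  p <- median_ti()
  ss <- steady_state_performance("TI", p, 250, 250)
  # explicit closed form at the reported median parameter values
  expect_equal(ss, 250 + 0.0074 * (1 - 0.0021 * 250) *
                 (250 / (1 - exp(-0.292))) / 0.0305, tolerance = 1e-12)
  expect_equal(ss, 363.8, tolerance = 1e-4)
  expect_equal(iterated_steady_state("TI", p, 250, 250), ss,
               tolerance = 1e-6 / ss)

  # dose 0 is exactly baseline; Model T increases without turning over
  expect_identical(steady_state_performance("TI", p, 0, 250), 250)
  pT <- model_params("T", k_off = 0.0305, k_s1 = 0.292, k_s2 = 0.0074)
  doses <- seq(0, 600, by = 50)
  ssT <- steady_state_performance("T", pT, doses, 250)
  expect_true(all(diff(ssT) > 0))

  expect_error(
    steady_state_performance("TI", replace(p, "k_off", 0), 100, 250))
})

test_that("closed vs iterated steady state agree across a parameter sweep", {
  set.seed(19)
  b <- default_bounds()
  for (i in 1:20) {
    p <- model_params(
      "TI",
      k_off = exp(stats::runif(1, log(b$k_off[1]), log(b$k_off[2]))),
      k_s1 = exp(stats::runif(1, log(b$k_s1[1]), log(b$k_s1[2]))),
      k_s2 = exp(stats::runif(1, log(b$k_s2[1]), log(b$k_s2[2]))),
      k_i = exp(stats::runif(1, log(b$k_i[1]), log(b$k_i[2]))))
    dose <- stats::runif(1, 0, 500)
    expect_equal(iterated_steady_state("TI", p, dose, 250),
                 steady_state_performance("TI", p, dose, 250),
                 tolerance = 1e-8)
  }
})

test_that("steady-state gain is quadratic in dose with the analytic coefficients", {
  p <- median_ti()
  doses <- c(100, 200, 300)
  gains <- steady_state_performance("TI", p, doses, 250) - 250
  # two points pin the two coefficients; the third confirms the form
  coefs <- solve(cbind(doses[1:2], doses[1:2]^2), gains[1:2])
  A <- 0.0074 / ((1 - exp(-0.292)) * 0.0305)
  expect_equal(unname(coefs[1]), A, tolerance = 1e-9)
  expect_equal(unname(coefs[2]), -0.0021 * A, tolerance = 1e-9)
  # third point confirms there is no higher-order term
  expect_equal(coefs[1] * 300 + coefs[2] * 300^2, gains[3],
               tolerance = 1e-9)
})

test_that("optimal dose: analytic 1/(2 k_i), numeric search, scaling law", {
  p <- median_ti()
  expect_equal(optimal_dose(p, "analytic"), 1 / (2 * 0.0021))
  expect_equal(optimal_dose(p, "analytic"), 238.1, tolerance = 1e-3)
  expect_lt(abs(optimal_dose(p, "numeric") - optimal_dose(p, "analytic")),
            0.5)
  doubled <- replace(p, "k_i", 0.0042)
  expect_equal(optimal_dose(doubled, "analytic"),
               optimal_dose(p, "analytic") / 2)
  expect_error(optimal_dose(model_params("T", k_off = 0.03, k_s1 = 0.3,
                                         k_s2 = 0.007)), "k_i > 0")
})

test_that("dose-response curve records the inverted-U optimum", {
  p <- median_ti()
  curve <- dose_response_curve("TI", p, 0:600, 250)
  expect_equal(curve$perf_w[1], 250)
  expect_lt(abs(attr(curve, "optimum_dose") - 238), 1 + 1e-9)
  # the curve returns to baseline exactly at dose 1/k_i
  expect_equal(steady_state_performance("TI", p, 1 / 0.0021, 250), 250,
               tolerance = 1e-9)
  # interior maximum strictly above both endpoints
  expect_gt(attr(curve, "optimum_performance"), curve$perf_w[1])
  expect_gt(attr(curve, "optimum_performance"),
            curve$perf_w[nrow(curve)])

  pT <- model_params("T", k_off = 0.0305, k_s1 = 0.292, k_s2 = 0.0074)
  curveT <- dose_response_curve("T", pT, 0:600, 250)
  expect_equal(attr(curveT, "optimum_dose"), 600)  # no interior maximum

  expect_error(dose_response_curve("TI", p, numeric(0), 250), "empty")
  expect_error(dose_response_curve("TI", p, c(5, 3), 250), "increasing")
})

test_that("session responses superpose under T and interfere under TI", {
  pT <- model_params("T", k_off = 0.0305, k_s1 = 0.292, k_s2 = 0.0074)
  resT <- session_interaction("T", pT, 300, horizon = 100)
  single <- resT$delta_perf_w[resT$scenario == "single"]
  plus1 <- resT$delta_perf_w[resT$scenario == "plus1"]
  # exact linearity: the day-after series is the single response plus a
  # one-day-shifted copy
  expect_equal(plus1, single + c(0, single[-length(single)]),
               tolerance = 1e-10)

  pTI <- median_ti()
  resTI <- session_interaction("TI", pTI, 300, horizon = 150)
  summ <- attr(resTI, "summary")
  peak1 <- summ$peak_gain_w[summ$scenario == "single"]
  peak2 <- summ$peak_gain_w[summ$scenario == "plus1"]
  expect_lt(peak2, 2 * peak1)  # inhibition of the residual signal
  expect_equal(summ$per_session_gain_w[summ$scenario == "plus1"],
               peak2 / 2)

  # single 200-tu session: delayed peak, near-complete washout
  res200 <- session_interaction("TI", pTI, 200, scenarios = "single",
                                horizon = 300)
  d <- res200$delta_perf_w
  expect_equal(d[1], 0)
  expect_true(all(is.finite(d)))
  expect_gt(res200$day[which.max(d)], 2)
  expect_lt(d[length(d)], 0.01 * max(d))

  expect_error(session_interaction("TI", pTI, 300, scenarios = "weekly"),
               "unknown scenario")
  expect_error(session_interaction("TI", pTI, -5), "dose")
})
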