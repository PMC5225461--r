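test_that("parameter sets are kind-specific and validated", {
  expect_equal(model_n_params("T"), 3L)
  expect_equal(model_n_params("TI"), 4L)
  expect_equal(model_n_params("TF"), 5L)
  expect_equal(model_n_params("TIF"), 6L)
  expect_error(model_params("T", k_off = 0.03, k_s1 = 0.3, k_s2 = 0.007,
                            k_i = 0.002), "do not belong")
  expect_error(model_params("TI", k_off = 0.03, k_s1 = 0.3, k_s2 = 0.007),
               "requires parameter")
  expect_error(model_params("T", k_off = -0.03, k_s1 = 0.3, k_s2 = 0.007),
               "> 0")
  expect_error(model_params("T", k_off = NaN, k_s1 = 0.3, k_s2 = 0.007),
               "non-finite")
  # fatigue gain may be negative (reported for five of six subjects)
  expect_silent(model_params("TF", k_off = 0.03, k_s1 = 0.3, k_s2 = 0.007,
                             k_f1 = -0.2, k_f2 = 0.1))
})

test_that("training series enforce day structure and measurement count", {
  expect_error(training_series(load = c(100, 0), performance = c(250, 251)),
               "day 0")
  expect_error(training_series(load = c(0, 0), performance = c(250, NA)),
               "at least 2")
  expect_error(training_series(load = c(0, -1, 0),
                               performance = c(250, NA, 251)),
               "negative load")
  s <- toy_series()
  expect_equal(perf0(s), 301)
  expect_equal(n_measurements(s), 5L)
  expect_equal(measurement_days(s), c(0, 7, 14, 21, 28))
})

test_that("zero training leaves performance exactly at baseline for all kinds", {
  params <- list(
    T = model_params("T", k_off = 0.0305, k_s1 = 0.292, k_s2 = 0.0074),
    TI = median_ti(),
    TF = model_params("TF", k_off = 0.0305, k_s1 = 0.292, k_s2 = 0.0074,
                      k_f1 = 0.1, k_f2 = 0.1),
    TIF = model_params("TIF", k_off = 0.0305, k_s1 = 0.292, k_s2 = 0.0074,
                       k_i = 0.0021, k_f1 = 0.1, k_f2 = 0.1))
  for (kind in MODEL_KINDS) {
    for (decay in c("euler", "exp")) {
      tr <- simulate_trajectory(kind, params[[kind]], rep(0, 100), 250,
                                perf_decay = decay)
      expect_identical(tr$perf_w, rep(250, 100))
      expect_identical(tr$netperf_w, rep(250, 100))
    }
  }
})

test_that("nested reductions reproduce the smaller model's trajectory exactly", {
  set.seed(11)
  loads <- c(0, sample(c(0, 100, 340, 440), 59, replace = TRUE))
  base <- model_params("T", k_off = 0.0305, k_s1 = 0.292, k_s2 = 0.0074)
  tr_T <- simulate_trajectory("T", base, loads, 250)
  tr_TI0 <- simulate_trajectory("TI", c(base, k_i = 0), loads, 250)
  tr_TF0 <- simulate_trajectory("TF", c(base, k_f1 = 0, k_f2 = 0.3),
                                loads, 250)
  expect_equal(tr_TI0$netperf_w, tr_T$netperf_w, tolerance = 0)
  expect_equal(tr_TF0$netperf_w, tr_T$netperf_w, tolerance = 0)

  tif <- model_params("TIF", k_off = 0.0305, k_s1 = 0.292, k_s2 = 0.0074,
                      k_i = 0.0021, k_f1 = 0.15, k_f2 = 0.3)
  tr_TIF_ki0 <- simulate_trajectory(
    "TIF", replace(tif, "k_i", 0), loads, 250)
  tr_TF <- simulate_trajectory("TF", tif[c("k_off", "k_s1", "k_s2",
                                           "k_f1", "k_f2")], loads, 250)
  expect_equal(tr_TIF_ki0$netperf_w, tr_TF$netperf_w, tolerance = 0)
  tr_TIF_kf0 <- simulate_trajectory(
    "TIF", replace(tif, "k_f1", 0), loads, 250)
  tr_TI <- simulate_trajectory("TI", tif[c("k_off", "k_s1", "k_s2", "k_i")],
                               loads, 250)
  expect_equal(tr_TIF_kf0$netperf_w, tr_TI$netperf_w, tolerance = 0)
})

test_that("Model T recursion matches the explicit convolution-sum oracle", {
  # single 200-tu dose on day 1: the double sum is hand-checkable
  p <- model_params("T", k_off = 0.0305, k_s1 = 0.292, k_s2 = 0.0074)
  loads <- c(0, 200, rep(0, 38))
  tr <- simulate_trajectory("T", p, loads, 250)
  oracle <- conv_oracle_T(0.0305, 0.292, 0.0074, loads, 250)
  expect_equal(tr$perf_w, oracle, tolerance = 1e-9)

  # random load series of length <= 50
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(10:50, 1)
    loads <- c(0, round(stats::runif(n - 1, 0, 500)))
    loads[sample(2:n, floor(n / 3))] <- 0
    k <- c(k_off = stats::runif(1, 0.01, 0.1),
           k_s1 = stats::runif(1, 0.1, 1),
           k_s2 = stats::runif(1, 0.001, 0.02))
    tr <- simulate_trajectory("T", k, loads, 300)
    oracle <- conv_oracle_T(k[["k_off"]], k[["k_s1"]], k[["k_s2"]],
                            loads, 300)
    expect_equal(tr$perf_w, oracle, tolerance = 1e-9)
  }
})

test_that("Model T deviations superpose and k_s2 = 0 freezes performance", {
  p <- model_params("T", k_off = 0.04, k_s1 = 0.35, k_s2 = 0.009)
  set.seed(7)
  w1 <- c(0, round(stats::runif(40, 0, 300)))
  w2 <- c(0, round(stats::runif(40, 0, 300)))
  d1 <- simulate_trajectory("T", p, w1, 250)$perf_w - 250
  d2 <- simulate_trajectory("T", p, w2, 250)$perf_w - 250
  d12 <- simulate_trajectory("T", p, w1 + w2, 250)$perf_w - 250
  expect_equal(d12, d1 + d2, tolerance = 1e-12)

  frozen <- simulate_trajectory("T", replace(p, "k_s2", 0), w1, 250)
  expect_identical(frozen$perf_w, rep(250, 41))
})

test_that("trajectory state invariants hold", {
  p <- model_params("TIF", k_off = 0.0305, k_s1 = 0.292, k_s2 = 0.0074,
                    k_i = 0.0021, k_f1 = 0.1, k_f2 = 0.2)
  loads <- c(0, 300, 0, 0, 0, 440, 0, 0, 0, 0)
  tr <- simulate_trajectory("TIF", p, loads, 250)
  expect_true(all(tr$signal_tu >= 0))
  # geometric decay of signal on zero-load stretches
  expect_equal(tr$signal_tu[4], tr$signal_tu[3] * exp(-0.292))
  expect_equal(tr$inhib[loads == 0], rep(0, sum(loads == 0)))
  expect_equal(tr$fatigue_w[1], 0)
  expect_equal(tr$netperf_w, tr$perf_w - tr$fatigue_w)
  # day-i performance is unaffected by day-i load
  tr2 <- simulate_trajectory("TIF", p, replace(loads, 10, 999), 250)
  expect_equal(tr2$perf_w[10], tr$perf_w[10])
})

test_that("simulate_trajectory rejects invalid input", {
  p <- median_ti()
  expect_error(simulate_trajectory("TI", p, c(100, 0), 250), "day 0")
  expect_error(simulate_trajectory("TI", p, c(0, -5), 250), "negative")
  expect_error(simulate_trajectory("TI", p, c(0, NA), 250), "non-finite")
  expect_error(simulate_trajectory("TI", p, c(0, 100), -10), "perf0")
  # inhibition above 1 is legitimate, not an error
  big <- simulate_trajectory("TI", p, c(0, 600, rep(0, 10)), 250)
  expect_gt(max(big$inhib), 1)
  expect_true(all(is.finite(big$perf_w)))
})

test_that("predictions sit on measurement days and respect the observable", {
  # zero-load series: constant predictions at the first measurement
  s <- training_series(load = rep(0, 15),
                       performance = c(300, rep(NA, 6), 299, rep(NA, 6),
                                       301))
  pr <- predict_performance("TI", median_ti(), s)
  expect_equal(pr$day, c(0, 7, 14))
  expect_equal(pr$predicted_w, rep(300, 3))

  # TF with k_f1 = 0 predicts exactly like T
  s2 <- toy_series()
  pT <- model_params("T", k_off = 0.03, k_s1 = 0.3, k_s2 = 0.007)
  prT <- predict_performance("T", pT, s2)
  prTF <- predict_performance("TF", c(pT, k_f1 = 0, k_f2 = 0.2), s2)
  expect_equal(prTF$predicted_w, prT$predicted_w, tolerance = 0)

  # one-step hand computation: net prediction subtracts decayed fatigue
  s3 <- training_series(load = c(0, 300, 0),
                        performance = c(250, NA, 255))
  ptif <- model_params("TIF", k_off = 0.0305, k_s1 = 0.292,
                       k_s2 = 0.0074, k_i = 0.0021, k_f1 = 0.1, k_f2 = 0.1)
  pr3 <- predict_performance("TIF", ptif, s3)
  tr3 <- simulate_trajectory("TIF", ptif, s3$load_tu, 250)
  expect_equal(pr3$predicted_w[2],
               tr3$perf_w[3] - 0.1 * 300 * exp(-0.1))
})
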