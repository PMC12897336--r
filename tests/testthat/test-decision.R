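p_cal <- (0.85 - 0.745) / (0.85 - 0.63)  # calibrated prevalence, 0.477273

test_that("predicted-positive rate follows the mixture formula", {
  s2 <- list(sensitivity = 0.733, specificity = 0.745)
  # hand-computed: 0.4772727*0.733 + 0.5227273*0.255 = 0.4831364
  expect_equal(predicted_positive_rate(p_cal, s2), 0.4831364,
               tolerance = 1e-6)
  # degenerate no-prediction classifier labels nobody low
  s_np <- list(sensitivity = 0, specificity = 1)
  for (p in c(0.1, 0.477, 0.9)) {
    expect_equal(predicted_positive_rate(p, s_np), 0)
  }
  # a perfect classifier labels exactly the prevalent fraction
  s_perf <- list(sensitivity = 1, specificity = 1)
  expect_equal(predicted_positive_rate(0.3, s_perf), 0.3)
})

test_that("posterior beliefs follow Bayes' rule", {
  s2 <- list(sensitivity = 0.733, specificity = 0.745)
  # 0.3498409 / 0.4831364
  expect_equal(posterior_low(p_cal, s2, TRUE), 0.7241, tolerance = 1e-3)

  s_perf <- list(sensitivity = 1, specificity = 1)
  for (p in c(0.05, 0.477, 0.95)) {
    expect_equal(posterior_low(p, s_perf, TRUE), 1)
  }
  # uninformative classifier: posterior equals prior
  s_unif <- list(sensitivity = 0.6, specificity = 0.4)
  for (p in c(0.2, 0.477, 0.8)) {
    expect_equal(posterior_low(p, s_unif, TRUE), p, tolerance = 1e-12)
    expect_equal(posterior_low(p, s_unif, FALSE), p, tolerance = 1e-12)
  }
  expect_error(posterior_low(0.5, list(sensitivity = 0, specificity = 1),
                             TRUE), "zero")
})

test_that("posteriors satisfy the law of total probability", {
  set.seed(31)
  for (i in 1:50) {
    p <- runif(1, 0.05, 0.95)
    s <- list(sensitivity = runif(1, 0.05, 0.95),
              specificity = runif(1, 0.05, 0.95))
    ppr <- predicted_positive_rate(p, s)
    recomposed <- posterior_low(p, s, TRUE) * ppr +
      posterior_low(p, s, FALSE) * (1 - ppr)
    expect_equal(recomposed, p, tolerance = 1e-12)
  }
})

test_that("expected QALYs reproduce the published strategy values", {
  p <- default_parameters()
  expect_equal(round(expected_qaly(p, "no_prediction"), 3), 0.745)
  expect_equal(round(expected_qaly(p, "clinician_plus_predictor"), 3), 0.759)
  expect_equal(round(expected_qaly(p, "clinician"), 3), 0.758)
  expect_equal(round(expected_qaly(p, "predictor_only"), 3), 0.756)

  # value-of-perfect-information ceiling: sens = 1
  perf <- list(id = "perfect", sensitivity = 1, specificity = 1,
               prediction_cost = 0, offers_support = TRUE)
  expect_equal(expected_qaly(p, perf), 0.745 + p_cal * 0.04,
               tolerance = 1e-12)
})

test_that("expected costs decompose as prediction + IPS + utilization", {
  p <- default_parameters()
  # untreated cohort: 16.909 expected visits at EUR 367 each, nothing else
  e_visits <- p_cal * 19 + (1 - p_cal) * 15
  expect_equal(expected_cost(p, "no_prediction"), e_visits * 367,
               tolerance = 1e-9)

  # all unit costs zero: zero cost for any strategy
  p0 <- p
  p0$costs[c("ips_cost_provider", "ips_cost_patient", "visit_cost_provider",
             "visit_cost_patient", "sick_day_cost")] <- 0
  p0$strategies$prediction_cost <- rep(0, 4)
  for (id in p0$strategies$id) {
    expect_equal(expected_cost(p0, id), 0)
  }

  # the modeled incremental cost of the combined strategy is within 10% of
  # the published EUR 310 (the exact fee-inclusion convention is unprinted)
  inc <- expected_cost(p, "clinician_plus_predictor") -
    expected_cost(p, "no_prediction")
  expect_lt(abs(inc - 310) / 310, 0.10)
})

test_that("societal perspective adds sick-leave productivity costs", {
  pay <- default_parameters("payer")
  soc <- default_parameters("societal")
  e_sick <- p_cal * 130 + (1 - p_cal) * 86
  expect_equal(expected_cost(soc, "no_prediction") -
                 expected_cost(pay, "no_prediction"),
               e_sick * 378, tolerance = 1e-9)
  # QALYs are perspective-independent
  expect_equal(expected_qaly(soc, "clinician"), expected_qaly(pay, "clinician"))
  # prediction strategies save sick-leave costs relative to no prediction
  res <- evaluate_all(soc)
  np_sick <- res$cost_sickleave[res$strategy_id == "no_prediction"]
  expect_true(all(res$cost_sickleave[res$strategy_id != "no_prediction"] <
                    np_sick))
})

test_that("evaluate_all ranking and limiting cases", {
  p <- default_parameters()
  res <- evaluate_all(p)
  ord <- res$strategy_id[order(-res$expected_qaly)]
  expect_equal(ord, c("clinician_plus_predictor", "clinician",
                      "predictor_only", "no_prediction"))
  expect_equal(res$nmb, p$wtp * res$expected_qaly - res$expected_cost)
  # no-prediction is the cost minimum under default parameters
  expect_equal(res$strategy_id[which.min(res$expected_cost)], "no_prediction")

  p0 <- default_parameters(wtp = 0)
  res0 <- evaluate_all(p0)
  expect_equal(res0$nmb, -res0$expected_cost)

  # no-benefit limit: delta_u -> 0 equalizes QALYs, prediction costs remain
  peps <- default_parameters()
  peps$outcomes$delta_u <- 1e-12
  reseps <- evaluate_all(peps)
  expect_equal(max(reseps$expected_qaly) - min(reseps$expected_qaly), 0,
               tolerance = 1e-12)
  np_cost <- reseps$expected_cost[reseps$strategy_id == "no_prediction"]
  expect_true(all(reseps$expected_cost[reseps$strategy_id != "no_prediction"] >
                    np_cost))
})

test_that("expected QALYs and costs are monotone in the drivers", {
  base <- default_parameters()
  grid <- seq(0.1, 1, by = 0.1)
  q_sens <- vapply(grid, function(sv) {
    s <- list(sensitivity = sv, specificity = 0.745, prediction_cost = 15,
              offers_support = TRUE)
    expected_qaly(base, s)
  }, numeric(1))
  expect_true(all(diff(q_sens) >= 0))

  q_delta <- vapply(seq(0.01, 0.15, by = 0.01), function(d) {
    p <- base
    p$outcomes$delta_u <- d
    expected_qaly(p, "clinician")
  }, numeric(1))
  expect_true(all(diff(q_delta) >= 0))

  c_spec <- vapply(grid, function(sp) {
    s <- list(sensitivity = 0.733, specificity = sp, prediction_cost = 15,
              offers_support = TRUE)
    expected_cost(base, s)
  }, numeric(1))
  expect_true(all(diff(c_spec) <= 0))
})

test_that("negative expected utilization is clamped with a warning", {
  p <- default_parameters()
  p$outcomes$visit_coeff <- 15  # 120 visits avoided per treated true positive
  expect_warning(expected_cost(p, "clinician_plus_predictor"), "clamped")
})

test_that("microsimulation agrees with the analytic expectations", {
  p <- default_parameters()
  cp <- cohort_parameters_from_model(p, n_patients = 60000, seed = 21)
  coh <- generate_cohort(cp)
  for (id in c("no_prediction", "clinician_plus_predictor")) {
    ms <- microsim_strategy(p, id, coh, seed = 99)
    expect_lt(abs(ms$expected_qaly - expected_qaly(p, id)), 3 * ms$se_qaly)
    expect_lt(abs(ms$expected_cost - expected_cost(p, id)), 3 * ms$se_cost)
  }
})

test_that("microsimulation is exact for a perfect classifier on a noiseless cohort", {
  p <- default_parameters()
  perf <- list(id = "perfect", sensitivity = 1, specificity = 1,
               prediction_cost = 0, offers_support = TRUE)
  cp <- cohort_parameters_from_model(p, n_patients = 4000, seed = 8,
                                     u_within_sd = 0, count_noise = 0)
  coh <- generate_cohort(cp)
  ms <- microsim_strategy(p, perf, coh, seed = 1)
  # with a perfect classifier every label is deterministic; the only
  # deviation from the analytic value is the realized prevalence
  p_real <- mean(coh$true_state == "low")
  p2 <- p
  p2$prevalence <- p_real
  expect_equal(ms$expected_qaly, expected_qaly(p2, perf), tolerance = 1e-12)
  expect_equal(ms$expected_cost, expected_cost(p2, perf), tolerance = 1e-9)
})

test_that("single-patient microsimulation is reproducible", {
  p <- default_parameters()
  coh <- generate_cohort(cohort_parameters(n_patients = 1, seed = 4))
  a <- microsim_strategy(p, "clinician", coh, seed = 123)
  b <- microsim_strategy(p, "clinician", coh, seed = 123)
  expect_identical(a, b)
})
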