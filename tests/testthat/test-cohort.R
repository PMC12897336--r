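test_that("same seed gives byte-identical cohorts", {
  cp <- cohort_parameters(n_patients = 500, seed = 42)
  expect_identical(generate_cohort(cp), generate_cohort(cp))
  cp2 <- cohort_parameters(n_patients = 500, seed = 43)
  expect_false(identical(generate_cohort(cp), generate_cohort(cp2)))
})

test_that("degenerate noise gives exact group values", {
  cp <- cohort_parameters(n_patients = 300, u_within_sd = 0, count_noise = 0,
                          seed = 7)
  coh <- generate_cohort(cp)
  low <- coh[coh$true_state == "low", ]
  high <- coh[coh$true_state == "high", ]
  expect_true(all(low$u_12m == 0.63))
  expect_true(all(high$u_12m == 0.85))
  expect_true(all(low$visits ==
                    round(cp$visits_intercept + cp$visits_slope * 0.63)))
  expect_true(all(high$sick_days ==
                    round(cp$sickdays_intercept + cp$sickdays_slope * 0.85)))
  # parameterized to the base case, those are the printed group levels
  expect_true(all(low$visits == 19))
  expect_true(all(high$visits == 15))
  expect_true(all(low$sick_days == 130))
  expect_true(all(high$sick_days == 86))
})

test_that("cohort records respect the threshold/state consistency", {
  coh <- generate_cohort(cohort_parameters(n_patients = 5000, seed = 11))
  expect_true(all((coh$u_12m <= 0.75) == (coh$true_state == "low")))
  expect_true(all(coh$visits >= 0))
  expect_true(all(coh$sick_days >= 0))
  expect_true(all(coh$u_12m > 0 & coh$u_12m <= 1))
})

test_that("mixture mean of generated utilities matches the calibrated cohort", {
  cp <- cohort_parameters(n_patients = 10000, prevalence_true = 0.477,
                          seed = 5)
  coh <- generate_cohort(cp)
  target <- 0.477 * 0.63 + 0.523 * 0.85  # ~0.745
  se <- sd(coh$u_12m) / sqrt(nrow(coh))
  expect_lt(abs(mean(coh$u_12m) - target), 3 * se + 1e-12)
})

test_that("prevalence estimation counts the threshold correctly", {
  toy <- tibble::tibble(u_12m = c(0.6, 0.7, 0.8, 0.9))
  expect_equal(estimate_prevalence(toy, 0.75), 0.5)
  expect_equal(estimate_prevalence(tibble::tibble(u_12m = rep(0.9, 5)),
                                   0.75), 0)
  expect_error(estimate_prevalence(tibble::tibble(u_12m = numeric(0))),
               "empty")
})

test_that("OLS slope fit is exact on an exact line and matches lm otherwise", {
  # records constructed exactly on a line: closed-form fit must be exact
  u <- seq(0.3, 0.95, length.out = 40)
  line <- tibble::tibble(u_12m = u, visits = 30.4545 - 18.2 * u,
                         sick_days = 256 - 200 * u)
  fit <- fit_utilization_slope(line, "visits")
  expect_equal(fit$slope, -18.2, tolerance = 1e-10)
  expect_equal(fit$intercept, 30.4545, tolerance = 1e-10)
  expect_equal(fit$slope_per_001, -0.182, tolerance = 1e-10)

  # flat outcome: slope 0, intercept at the level
  flat <- tibble::tibble(u_12m = u, visits = rep(5, 40))
  fit0 <- fit_utilization_slope(flat, "visits")
  expect_equal(fit0$slope, 0)
  expect_equal(fit0$intercept, 5)

  # cross-check of the normal-equation fit against lm on noisy data
  coh <- generate_cohort(cohort_parameters(n_patients = 2000, seed = 3))
  fit1 <- fit_utilization_slope(coh, "sick_days")
  ref <- stats::lm(sick_days ~ u_12m, data = coh)
  expect_equal(fit1$slope, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(fit1$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
  expect_equal(fit1$slope_se, summary(ref)$coefficients[2, 2],
               tolerance = 1e-8)

  expect_error(fit_utilization_slope(
    tibble::tibble(u_12m = rep(0.5, 10), visits = rnorm(10)), "visits"),
    "degenerate")
  expect_error(fit_utilization_slope(line[1:2, ], "visits"), "at least 3")
})

test_that("slope recovery: fitted slope covers the truth across replicates", {
  hits <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    coh <- generate_cohort(cohort_parameters(n_patients = 660, seed = 1000 + r))
    fit <- fit_utilization_slope(coh, "visits")
    truth <- (15 - 19) / (0.85 - 0.63)
    if (abs(fit$slope - truth) <= 2 * fit$slope_se) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("cohort summary reports group means and handles absent groups", {
  cp <- cohort_parameters(n_patients = 300, u_within_sd = 0, count_noise = 0,
                          seed = 2)
  summ <- summarize_cohort(generate_cohort(cp))
  expect_equal(summ$mean_visits[summ$true_state == "low"], 19)
  expect_equal(summ$mean_u_12m[summ$true_state == "high"], 0.85)

  # tiny cohort with near-zero prevalence: the low group is simply absent
  cp2 <- cohort_parameters(n_patients = 5, prevalence_true = 1e-6, seed = 1)
  summ2 <- summarize_cohort(generate_cohort(cp2))
  expect_equal(summ2$true_state, "high")
  expect_false(anyNA(summ2))
})

test_that("parameter recovery at large n", {
  cp <- cohort_parameters(n_patients = 100000, seed = 77)
  coh <- generate_cohort(cp)

  p_hat <- estimate_prevalence(coh, cp$low_threshold)
  se_p <- sqrt(cp$prevalence_true * (1 - cp$prevalence_true) / nrow(coh))
  expect_lt(abs(p_hat - cp$prevalence_true), 3 * se_p)

  summ <- summarize_cohort(coh)
  for (g in c("low", "high")) {
    sub <- coh[coh$true_state == g, ]
    target <- if (g == "low") cp$u_low_mean else cp$u_high_mean
    se_u <- sd(sub$u_12m) / sqrt(nrow(sub))
    expect_lt(abs(mean(sub$u_12m) - target), 3 * se_u)
  }

  for (oc in c("visits", "sick_days")) {
    fit <- fit_utilization_slope(coh, oc)
    truth <- if (oc == "visits") cp$visits_slope else cp$sickdays_slope
    expect_lt(abs(fit$slope - truth), 3 * fit$slope_se)
  }
})

test_that("cohort CSV round trip is lossless", {
  coh <- generate_cohort(cohort_parameters(n_patients = 200, seed = 13))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(coh, f)
  back <- read_cohort(f)
  for (col in names(coh)) {
    expect_identical(as.vector(back[[col]]), as.vector(coh[[col]]))
  }
})

test_that("generator rejects inconsistent configurations", {
  expect_error(cohort_parameters(n_patients = 0), "n_patients")
  expect_error(cohort_parameters(u_low_mean = 0.8), "truncation")
  expect_error(cohort_parameters(u_high_mean = 0.7), "truncation")
  expect_error(cohort_parameters(visits_slope = 2), "slopes")
  expect_error(cohort_parameters(prevalence_true = 1), "prevalence_true")
})
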