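# Decision-tree engine: expected per-patient cost and QALYs for each strategy.
#
# The tree partitions patients by true one-year QoL state (low with
# probability p, high otherwise) and by the strategy's predicted label.
# True state is held constant through the decision; only beliefs update.
# Support is given to predicted-low patients; only treated TRUE positives
# accrue the utility gain and the utilization reductions.

# Resolve a strategy argument: id string, one-row data frame, or list.
resolve_strategy <- function(params, s) {
  if (is.character(s) && length(s) == 1) {
    row <- params$strategies[params$strategies$id == s, ]
    if (nrow(row) != 1) stop("unknown strategy id: ", s, call. = FALSE)
    return(as.list(row))
  }
  if (is.data.frame(s)) {
    stopifnot(nrow(s) == 1)
    return(as.list(s))
  }
  as.list(s)
}

#' Probability that a strategy predicts low QoL
#'
#' The marginal rate at which a strategy labels patients low (and hence
#' treats them): `p * sensitivity + (1 - p) * (1 - specificity)`.
#'
#' @param p Prevalence of true low QoL.
#' @param s A strategy: id string (with `params`-style lookup not needed here),
#'   one-row data frame, or list with `sensitivity` and `specificity`.
#' @return The predicted-positive rate.
#' @export
#' @examples
#' predicted_positive_rate(0.4773, list(sensitivity = 0.733, specificity = 0.745))
predicted_positive_rate <- function(p, s) {
  s <- if (is.data.frame(s)) as.list(s) else s
  p * s$sensitivity + (1 - p) * (1 - s$specificity)
}

#' Posterior probability of true low QoL given a prediction
#'
#' Bayesian update of the prior prevalence with the strategy's operating
#' characteristics:
#' `P(low | predicted low) = p*sens / (p*sens + (1-p)*(1-spec))` and
#' `P(low | predicted high) = p*(1-sens) / (p*(1-sens) + (1-p)*spec)`.
#'
#' @param p Prior prevalence of low QoL.
#' @param s Strategy (list or one-row data frame with `sensitivity`,
#'   `specificity`).
#' @param predicted_low Logical: condition on a low (TRUE) or high (FALSE)
#'   prediction.
#' @return Posterior probability of true low QoL.
#' @export
posterior_low <- function(p, s, predicted_low) {
  s <- if (is.data.frame(s)) as.list(s) else s
  if (predicted_low) {
    denom <- p * s$sensitivity + (1 - p) * (1 - s$specificity)
    num <- p * s$sensitivity
  } else {
    denom <- p * (1 - s$sensitivity) + (1 - p) * s$specificity
    num <- p * (1 - s$sensitivity)
  }
  if (denom <= 0) {
    stop("undefined posterior: the conditioning branch has probability zero",
         call. = FALSE)
  }
  num / denom
}

# Effective unit costs under the fee-inclusion convention.
unit_costs <- function(costs) {
  fee <- as.numeric(costs$include_patient_fees)
  list(ips = costs$ips_cost_provider + fee * costs$ips_cost_patient,
       visit = costs$visit_cost_provider + fee * costs$visit_cost_patient,
       sick_day = costs$sick_day_cost)
}

# Vectorized core shared by evaluate_all() and run_psa(): every argument may
# be a vector (draws); strategy characteristics are scalars per call.
eval_core <- function(p, sens, spec, offers, pred_cost,
                      u_low, u_high, gain_per_tp,
                      visits_low, visits_high, sickdays_low, sickdays_high,
                      visit_coeff, sickday_coeff, delta_u,
                      c_ips, c_visit, c_sick_day, societal) {
  offers <- as.numeric(offers)
  ppr <- p * sens + (1 - p) * (1 - spec)
  treated_tp <- offers * p * sens

  qaly_base <- p * u_low + (1 - p) * u_high
  qaly_gain <- treated_tp * gain_per_tp

  # utilization reductions accrue only to treated true positives; the
  # coefficients are per +0.01 QoL, the gain is delta_u on the unit scale
  e_visits <- p * visits_low + (1 - p) * visits_high -
    treated_tp * visit_coeff * 100 * delta_u
  e_sickdays <- p * sickdays_low + (1 - p) * sickdays_high -
    treated_tp * sickday_coeff * 100 * delta_u
  if (any(e_visits < 0) || any(e_sickdays < 0)) {
    warning("expected utilization fell below zero after treatment reduction; clamped to 0",
            call. = FALSE)
    e_visits <- pmax(e_visits, 0)
    e_sickdays <- pmax(e_sickdays, 0)
  }

  cost_prediction <- pred_cost + numeric(length(ppr))
  cost_ips <- offers * ppr * c_ips
  cost_visits <- e_visits * c_visit
  cost_sickleave <- as.numeric(societal) * e_sickdays * c_sick_day

  list(
    ppr = ppr,
    expected_qaly = qaly_base + qaly_gain,
    qaly_base = qaly_base,
    qaly_gain = qaly_gain,
    expected_cost = cost_prediction + cost_ips + cost_visits + cost_sickleave,
    cost_prediction = cost_prediction,
    cost_ips = cost_ips,
    cost_visits = cost_visits,
    cost_sickleave = cost_sickleave
  )
}

core_args <- function(params, strat) {
  uc <- unit_costs(params$costs)
  o <- params$outcomes
  list(
    p = params$prevalence,
    sens = strat$sensitivity, spec = strat$specificity,
    offers = strat$offers_support, pred_cost = strat$prediction_cost,
    u_low = o$u_low, u_high = o$u_high,
    gain_per_tp = o$delta_u * o$benefit_duration_fraction,
    visits_low = o$visits_low, visits_high = o$visits_high,
    sickdays_low = o$sickdays_low, sickdays_high = o$sickdays_high,
    visit_coeff = o$visit_coeff, sickday_coeff = o$sickday_coeff,
    delta_u = o$delta_u,
    c_ips = uc$ips, c_visit = uc$visit, c_sick_day = uc$sick_day,
    societal = params$perspective == "societal"
  )
}

#' Expected QALYs of a strategy
#'
#' Over the one-year horizon with no discounting:
#' `p*u_low + (1-p)*u_high + [offers_support] * p * sensitivity * gain`,
#' where `gain = delta_u * benefit_duration_fraction`. False positives
#' receive support but no QALY change (only truly low-QoL patients benefit).
#'
#' @param params A `qol_params` object.
#' @param s Strategy id string, one-row data frame, or list.
#' @return Expected QALYs per patient.
#' @export
#' @examples
#' expected_qaly(default_parameters(), "no_prediction")  # 0.745
expected_qaly <- function(params, s) {
  strat <- resolve_strategy(params, s)
  do.call(eval_core, core_args(params, strat))$expected_qaly
}

#' Expected per-patient cost of a strategy
#'
#' Sum of the prediction cost, IPS course costs for all predicted-low
#' patients, expected healthcare-visit costs (reduced for treated true
#' positives by `visit_coeff` visits per +0.01 QoL gained), and — under the
#' societal perspective — sick-leave productivity losses costed by the
#' human-capital method. Unit costs include patient co-payments when
#' `costs$include_patient_fees` is `TRUE`.
#'
#' @inheritParams expected_qaly
#' @return Expected cost in EUR per patient.
#' @export
expected_cost <- function(params, s) {
  strat <- resolve_strategy(params, s)
  do.call(eval_core, core_args(params, strat))$expected_cost
}

#' Evaluate all strategies
#'
#' Runs the decision tree for every strategy in `params$strategies` and
#' returns expected cost, expected QALYs, net monetary benefit at
#' `params$wtp`, and the component breakdown. Deterministic.
#'
#' @param params A `qol_params` object.
#' @return A tibble of class `qol_results`, one row per strategy, with
#'   columns `strategy_id`, `label`, `perspective`, `expected_cost`,
#'   `expected_qaly`, `nmb`, and cost/QALY components.
#' @export
#' @examples
#' evaluate_all(default_parameters())
evaluate_all <- function(params) {
  validate_parameters(params)
  s <- params$strategies
  rows <- lapply(seq_len(nrow(s)), function(i) {
    comp <- do.call(eval_core, core_args(params, as.list(s[i, ])))
    tibble::tibble(
      strategy_id = s$id[i],
      label = s$label[i],
      perspective = params$perspective,
      expected_cost = comp$expected_cost,
      expected_qaly = comp$expected_qaly,
      nmb = params$wtp * comp$expected_qaly - comp$expected_cost,
      cost_prediction = comp$cost_prediction,
      cost_ips = comp$cost_ips,
      cost_visits = comp$cost_visits,
      cost_sickleave = comp$cost_sickleave,
      qaly_base = comp$qaly_base,
      qaly_gain = comp$qaly_gain
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "wtp") <- params$wtp
  attr(out, "prevalence") <- params$prevalence
  class(out) <- c("qol_results", class(out))
  out
}

#' Microsimulation oracle for one strategy
#'
#' Brute-force check of the analytic expectations: for each patient in a
#' synthetic cohort, draws the strategy's predicted label (Bernoulli with
#' the sensitivity for truly low patients, 1 - specificity for high ones),
#' treats predicted-low patients, applies the utility gain and utilization
#' reductions to treated true positives, and averages per-patient cost and
#' QALYs. Identical seed gives identical results.
#'
#' @param params A `qol_params` object.
#' @param s Strategy id string, one-row data frame, or list.
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param seed Integer seed for the prediction-label draws.
#' @return One-row tibble with `strategy_id`, `perspective`, `expected_cost`,
#'   `expected_qaly`, `nmb`, Monte Carlo standard errors `se_cost`, `se_qaly`,
#'   and `n`.
#' @export
microsim_strategy <- function(params, s, cohort, seed = 1) {
  validate_parameters(params)
  strat <- resolve_strategy(params, s)
  stopifnot(nrow(cohort) > 0)
  n <- nrow(cohort)
  o <- params$outcomes
  uc <- unit_costs(params$costs)
  low <- cohort$true_state == "low"
  societal <- params$perspective == "societal"

  pred_low <- with_seed(seed, {
    pr <- ifelse(low, strat$sensitivity, 1 - strat$specificity)
    runif(n) < pr
  })
  treated <- pred_low & strat$offers_support
  benefit <- treated & low

  gain <- o$delta_u * o$benefit_duration_fraction
  qaly_i <- cohort$u_12m + ifelse(benefit, gain, 0)

  visits_i <- pmax(cohort$visits -
                     ifelse(benefit, o$visit_coeff * 100 * o$delta_u, 0), 0)
  sick_i <- pmax(cohort$sick_days -
                   ifelse(benefit, o$sickday_coeff * 100 * o$delta_u, 0), 0)
  cost_i <- strat$prediction_cost + as.numeric(treated) * uc$ips +
    visits_i * uc$visit + as.numeric(societal) * sick_i * uc$sick_day

  tibble::tibble(
    strategy_id = strat$id %||% NA_character_,
    perspective = params$perspective,
    expected_cost = mean(cost_i),
    expected_qaly = mean(qaly_i),
    nmb = params$wtp * mean(qaly_i) - mean(cost_i),
    se_cost = stats::sd(cost_i) / sqrt(n),
    se_qaly = stats::sd(qaly_i) / sqrt(n),
    n = n
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
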