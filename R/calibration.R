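#' Calibrate the prevalence of low QoL from a QALY anchor
#'
#' The published analysis does not print the prior probability of low QoL one
#' year after diagnosis (it was estimated from unpublished cohort data), but
#' it does print the expected QALYs of the no-prediction strategy, which under
#' the two-state model equal the mixture mean `p * u_low + (1 - p) * u_high`.
#' Inverting that relation recovers the prevalence:
#' `p = (u_high - qaly_anchor) / (u_high - u_low)`.
#'
#' With the base-case utilities 0.63/0.85 and the printed anchor 0.745 this
#' gives p = 0.4773.
#'
#' @param u_low,u_high One-year state utilities of true low- and high-QoL
#'   patients, `u_low < u_high`, both in \[0, 1\].
#' @param qaly_anchor Expected QALYs of the untreated cohort (the
#'   no-prediction strategy); must lie in `(u_low, u_high]`.
#' @return The prevalence p in \[0, 1).
#' @export
#' @examples
#' calibrate_prevalence(0.63, 0.85, 0.745)  # 0.4773
calibrate_prevalence <- function(u_low, u_high, qaly_anchor) {
  stopifnot(is.numeric(u_low), is.numeric(u_high), is.numeric(qaly_anchor))
  if (u_low >= u_high) {
    stop("infeasible calibration: u_low must be strictly below u_high",
         call. = FALSE)
  }
  if (qaly_anchor <= u_low || qaly_anchor > u_high) {
    stop(sprintf(
      "infeasible calibration: anchor %.4f outside (u_low = %.4f, u_high = %.4f]",
      qaly_anchor, u_low, u_high), call. = FALSE)
  }
  (u_high - qaly_anchor) / (u_high - u_low)
}

#' Effective QALY gain per treated true-positive patient
#'
#' The IPS intervention raises utility by `delta_u` for truly low-QoL patients,
#' but the course runs over roughly half the one-year horizon, so by default
#' only that fraction of the gain accrues as QALYs:
#' `gain = delta_u * benefit_duration_fraction`.
#'
#' @param delta_u Utility gain from IPS (base case +0.08).
#' @param benefit_duration_fraction Fraction of the 1-year horizon over which
#'   the gain accrues, in (0, 1] (base case 0.5).
#' @return QALYs gained per treated true positive.
#' @export
#' @examples
#' effective_qaly_gain(0.08, 0.5)  # 0.04
effective_qaly_gain <- function(delta_u, benefit_duration_fraction) {
  stopifnot(delta_u >= 0, benefit_duration_fraction > 0,
            benefit_duration_fraction <= 1)
  delta_u * benefit_duration_fraction
}

#' Verify the calibrated model against published base-case anchors
#'
#' Evaluates all four strategies with the decision model under the payer
#' perspective and compares expected QALYs, incremental QALYs versus the
#' no-prediction reference, costs and NMBs against the published base-case
#' values. Incremental QALYs deviating by more than `tol_incr` (default
#' 0.0005, i.e. failing the printed three-decimal rounding) are flagged.
#'
#' @param params Model parameters; default [default_parameters()].
#' @param reference Reference table as returned by [basecase_reference()].
#' @param tol_incr Flag threshold for incremental-QALY residuals.
#' @param json_path Optional path; if given, the comparison table plus summary
#'   is written as a JSON report.
#' @return An object of class `qol_calibration_check`: list with elements
#'   `table` (per-strategy comparison tibble), `prevalence`, `n_flagged`,
#'   `max_cost_rel_err`, `max_nmb_rel_err`.
#' @export
verify_calibration <- function(params = default_parameters(),
                               reference = basecase_reference(),
                               tol_incr = 5e-4,
                               json_path = NULL) {
  params$perspective <- "payer"
  res <- evaluate_all(params)
  m <- match(reference$strategy_id, res$strategy_id)
  if (anyNA(m)) {
    stop("reference contains strategies absent from the parameter set",
         call. = FALSE)
  }
  mod <- res[m, ]
  ref_q0 <- reference$qaly[reference$strategy_id == "no_prediction"]
  mod_q0 <- mod$expected_qaly[mod$strategy_id == "no_prediction"]
  tab <- tibble::tibble(
    strategy_id = reference$strategy_id,
    modeled_qaly = mod$expected_qaly,
    reference_qaly = reference$qaly,
    qaly_residual = mod$expected_qaly - reference$qaly,
    modeled_incr_qaly = mod$expected_qaly - mod_q0,
    reference_incr_qaly = reference$qaly - ref_q0,
    incr_qaly_residual = (mod$expected_qaly - mod_q0) -
      (reference$qaly - ref_q0),
    incr_flag = abs((mod$expected_qaly - mod_q0) -
                      (reference$qaly - ref_q0)) > tol_incr,
    modeled_cost = mod$expected_cost,
    reference_cost = reference$cost,
    cost_rel_err = mod$expected_cost / reference$cost - 1,
    modeled_nmb = mod$nmb,
    reference_nmb = reference$nmb,
    nmb_rel_err = mod$nmb / reference$nmb - 1
  )
  out <- structure(
    list(
      table = tab,
      prevalence = params$prevalence,
      n_flagged = sum(tab$incr_flag),
      max_cost_rel_err = max(abs(tab$cost_rel_err)),
      max_nmb_rel_err = max(abs(tab$nmb_rel_err))
    ),
    class = "qol_calibration_check"
  )
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(prevalence = out$prevalence,
           n_flagged = out$n_flagged,
           max_cost_rel_err = out$max_cost_rel_err,
           max_nmb_rel_err = out$max_nmb_rel_err,
           comparison = tab),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  out
}

#' @export
print.qol_calibration_check <- function(x, ...) {
  cat("<qol_calibration_check>\n")
  cat(sprintf("  prevalence used: %.4f\n", x$prevalence))
  cat(sprintf("  incremental-QALY flags raised: %d\n", x$n_flagged))
  cat(sprintf("  max |cost error| vs reference: %.2f%%\n",
              100 * x$max_cost_rel_err))
  cat(sprintf("  max |NMB error| vs reference:  %.2f%%\n",
              100 * x$max_nmb_rel_err))
  print(x$table[, c("strategy_id", "modeled_qaly", "reference_qaly",
                    "incr_qaly_residual", "incr_flag")])
  invisible(x)
}
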