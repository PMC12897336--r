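#' Published base-case reference results
#'
#' Per-patient net monetary benefit, cost and QALYs of the four strategies in
#' the published base-case analysis (payer perspective, willingness to pay
#' EUR 30,000 per QALY), as printed in the source evaluation's incremental
#' cost-effectiveness table. These values serve as calibration anchors (the
#' no-prediction QALY of 0.745 pins down the prevalence of low QoL) and as the
#' reference surface for [verify_calibration()] and the reproduction tests.
#'
#' Rows are ordered by increasing cost, matching the published table.
#'
#' @return A tibble with columns `strategy_id`, `label`, `nmb` (EUR),
#'   `cost` (EUR) and `qaly` (QALYs per patient).
#' @seealso [verify_calibration()], [build_frontier()]
#' @export
#' @examples
#' basecase_reference()
basecase_reference <- function() {
  tibble::tibble(
    strategy_id = c("no_prediction", "predictor_only",
                    "clinician_plus_predictor", "clinician"),
    label = c("No prediction, no psychosocial support",
              "QoL predictor alone",
              "Clinician prediction with QoL predictor",
              "Clinician prediction alone"),
    nmb  = c(16252, 16327, 16348, 16327),
    cost = c(6104, 6354, 6414, 6420),
    qaly = c(0.745, 0.756, 0.759, 0.758)
  )
}
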