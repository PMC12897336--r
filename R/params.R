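#' Default strategy definitions
#'
#' The four decision-making strategies compared by the model. Sensitivity and
#' specificity of the three prediction strategies come from the published
#' clinician/algorithm user experiment; the no-prediction strategy is encoded
#' as a degenerate classifier (sensitivity 0, specificity 1, zero cost) so all
#' four strategies flow through the same decision-tree engine.
#'
#' @return A tibble with one row per strategy and columns `id`, `label`,
#'   `sensitivity`, `specificity`, `prediction_cost` (EUR per patient) and
#'   `offers_support` (logical; whether psychosocial support is ever given).
#' @export
default_strategies <- function() {
  tibble::tibble(
    id = c("clinician", "clinician_plus_predictor", "predictor_only",
           "no_prediction"),
    label = c("Clinician prediction alone",
              "Clinician prediction with QoL predictor",
              "QoL predictor alone",
              "No prediction, no psychosocial support"),
    sensitivity     = c(0.705, 0.733, 0.585, 0),
    specificity     = c(0.733, 0.745, 0.776, 1),
    prediction_cost = c(30, 15, 10, 0),
    offers_support  = c(TRUE, TRUE, TRUE, FALSE)
  )
}

#' Base-case model parameters
#'
#' Returns the full parameter set of the base-case analysis: strategy
#' operating characteristics, one-year utility states, the IPS utility gain
#' and its accrual fraction, healthcare utilization and sick-leave levels and
#' regression coefficients, unit costs (2024 EUR), the willingness-to-pay
#' threshold and the analytic perspective.
#'
#' The prevalence of true low QoL at 12 months is not printed in the source
#' analysis; by default it is calibrated so the no-prediction strategy's
#' expected QALYs hit the published 0.745 anchor (see
#' [calibrate_prevalence()]), giving p = 0.4773.
#'
#' @param perspective `"payer"` (healthcare payer; default) or `"societal"`
#'   (additionally counts sick-leave productivity losses, human-capital
#'   method).
#' @param prevalence Probability of true low QoL one year after diagnosis.
#'   `NULL` (default) calibrates it from the published no-prediction QALY.
#' @param include_patient_fees Whether patient co-payments are counted in the
#'   payer perspective's unit costs (default `TRUE`, giving EUR 1011 per IPS
#'   course and EUR 367 per visit).
#' @param wtp Willingness to pay, EUR per QALY gained. Default 30000.
#' @return An object of class `qol_params`: a list with elements `prevalence`,
#'   `strategies` (tibble, see [default_strategies()]), `outcomes`, `costs`,
#'   `wtp`, `perspective`, `horizon_years` (fixed at 1; no discounting).
#' @export
#' @examples
#' p <- default_parameters()
#' p$prevalence      # 0.4773 (calibrated)
#' p$outcomes$delta_u
default_parameters <- function(perspective = c("payer", "societal"),
                               prevalence = NULL,
                               include_patient_fees = TRUE,
                               wtp = 30000) {
  perspective <- match.arg(perspective)
  outcomes <- list(
    u_low = 0.63, u_high = 0.85, u_baseline = 0.74,
    delta_u = 0.08, benefit_duration_fraction = 0.5,
    visits_low = 19, visits_high = 15,
    sickdays_low = 130, sickdays_high = 86,
    visit_coeff = 0.2, sickday_coeff = 1.2
  )
  costs <- list(
    ips_cost_provider = 947, ips_cost_patient = 64,
    visit_cost_provider = 344, visit_cost_patient = 23,
    sick_day_cost = 378,
    include_patient_fees = include_patient_fees
  )
  if (is.null(prevalence)) {
    anchor <- basecase_reference()
    prevalence <- calibrate_prevalence(
      outcomes$u_low, outcomes$u_high,
      anchor$qaly[anchor$strategy_id == "no_prediction"]
    )
  }
  params <- structure(
    list(
      prevalence = prevalence,
      strategies = default_strategies(),
      outcomes = outcomes,
      costs = costs,
      wtp = wtp,
      perspective = perspective,
      horizon_years = 1
    ),
    class = "qol_params"
  )
  validate_parameters(params)
}

#' Validate a model parameter set
#'
#' Checks every structural invariant of a `qol_params` object and stops with
#' an error naming the offending field on the first violation.
#'
#' @param params A `qol_params` object (see [default_parameters()]).
#' @return `params`, invisibly unchanged, if valid.
#' @export
validate_parameters <- function(params) {
  fail <- function(field, msg) {
    stop(sprintf("invalid parameter `%s`: %s", field, msg), call. = FALSE)
  }
  chk_prob <- function(x, field, open = FALSE) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
      fail(field, "must be a single number")
    }
    if (open && (x <= 0 || x >= 1)) fail(field, "must lie strictly in (0, 1)")
    if (!open && (x < 0 || x > 1)) fail(field, "must lie in [0, 1]")
  }
  chk_nonneg <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0) {
      fail(field, "must be a single non-negative number")
    }
  }

  chk_prob(params$prevalence, "prevalence", open = TRUE)
  chk_nonneg(params$wtp, "wtp")
  if (!identical(params$horizon_years, 1) && params$horizon_years != 1) {
    fail("horizon_years", "the model horizon is fixed at 1 year")
  }
  if (!params$perspective %in% c("payer", "societal")) {
    fail("perspective", "must be 'payer' or 'societal'")
  }

  s <- params$strategies
  need <- c("id", "label", "sensitivity", "specificity", "prediction_cost",
            "offers_support")
  if (!all(need %in% names(s))) fail("strategies", "missing columns")
  for (i in seq_len(nrow(s))) {
    chk_prob(s$sensitivity[i], paste0("strategies.", s$id[i], ".sensitivity"))
    chk_prob(s$specificity[i], paste0("strategies.", s$id[i], ".specificity"))
    chk_nonneg(s$prediction_cost[i],
               paste0("strategies.", s$id[i], ".prediction_cost"))
  }
  if (sum(s$id == "no_prediction") != 1) {
    fail("strategies", "exactly one strategy must have id 'no_prediction'")
  }
  np <- s[s$id == "no_prediction", ]
  if (np$offers_support || np$prediction_cost != 0 ||
      np$sensitivity != 0 || np$specificity != 1) {
    fail("strategies.no_prediction",
         "must have offers_support = FALSE, prediction_cost = 0, sensitivity = 0, specificity = 1")
  }

  o <- params$outcomes
  chk_prob(o$u_low, "outcomes.u_low")
  chk_prob(o$u_high, "outcomes.u_high")
  chk_prob(o$u_baseline, "outcomes.u_baseline")
  if (o$u_low >= o$u_high) fail("outcomes.u_low", "must be < u_high")
  if (o$delta_u <= 0) fail("outcomes.delta_u", "must be > 0")
  if (o$u_low + o$delta_u > 1) {
    fail("outcomes.delta_u", "u_low + delta_u must not exceed 1")
  }
  if (o$benefit_duration_fraction <= 0 || o$benefit_duration_fraction > 1) {
    fail("outcomes.benefit_duration_fraction", "must lie in (0, 1]")
  }
  if (o$visits_high < 0 || o$visits_low < o$visits_high) {
    fail("outcomes.visits_low", "need visits_low >= visits_high >= 0")
  }
  if (o$sickdays_high < 0 || o$sickdays_low < o$sickdays_high) {
    fail("outcomes.sickdays_low", "need sickdays_low >= sickdays_high >= 0")
  }
  chk_nonneg(o$visit_coeff, "outcomes.visit_coeff")
  chk_nonneg(o$sickday_coeff, "outcomes.sickday_coeff")

  cc <- params$costs
  for (f in c("ips_cost_provider", "ips_cost_patient", "visit_cost_provider",
              "visit_cost_patient", "sick_day_cost")) {
    chk_nonneg(cc[[f]], paste0("costs.", f))
  }
  if (!is.logical(cc$include_patient_fees) ||
      length(cc$include_patient_fees) != 1 || is.na(cc$include_patient_fees)) {
    fail("costs.include_patient_fees", "must be TRUE or FALSE")
  }
  invisible(params)
}

#' @export
print.qol_params <- function(x, ...) {
  cat("<qol_params> decision-model parameter set\n")
  cat(sprintf("  perspective: %s | WTP: EUR %s/QALY | horizon: %d year\n",
              x$perspective, format(x$wtp, big.mark = ","), x$horizon_years))
  cat(sprintf("  prevalence of low QoL: %.4f\n", x$prevalence))
  cat(sprintf("  utilities: low %.2f / high %.2f; IPS gain +%.2f over %.0f%% of the year\n",
              x$outcomes$u_low, x$outcomes$u_high, x$outcomes$delta_u,
              100 * x$outcomes$benefit_duration_fraction))
  cat("  strategies:\n")
  s <- x$strategies
  for (i in seq_len(nrow(s))) {
    cat(sprintf("    %-26s sens %.3f spec %.3f, EUR %g/prediction\n",
                s$id[i], s$sensitivity[i], s$specificity[i],
                s$prediction_cost[i]))
  }
  invisible(x)
}

# ---- configuration files ----------------------------------------------------

# Flatten a qol_params object into plain nested lists for YAML/JSON.
as_params_list <- function(params) {
  s <- params$strategies
  strat <- lapply(seq_len(nrow(s)), function(i) {
    list(label = s$label[i],
         sensitivity = s$sensitivity[i],
         specificity = s$specificity[i],
         prediction_cost = s$prediction_cost[i],
         offers_support = s$offers_support[i])
  })
  names(strat) <- s$id
  list(
    prevalence = params$prevalence,
    wtp = params$wtp,
    perspective = params$perspective,
    horizon_years = params$horizon_years,
    strategies = strat,
    outcomes = params$outcomes,
    costs = params$costs
  )
}

params_from_list <- function(lst) {
  strat <- lst$strategies
  ids <- names(strat)
  strategies <- tibble::tibble(
    id = ids,
    label = unname(vapply(strat, function(x) as.character(x$label),
                          character(1))),
    sensitivity = unname(vapply(strat, function(x) as.numeric(x$sensitivity),
                                numeric(1))),
    specificity = unname(vapply(strat, function(x) as.numeric(x$specificity),
                                numeric(1))),
    prediction_cost = unname(vapply(strat,
                                    function(x) as.numeric(x$prediction_cost),
                                    numeric(1))),
    offers_support = unname(vapply(strat, function(x) isTRUE(x$offers_support),
                                   logical(1)))
  )
  structure(
    list(
      prevalence = as.numeric(lst$prevalence),
      strategies = strategies,
      outcomes = lapply(lst$outcomes, function(x) as.numeric(x)),
      costs = c(lapply(lst$costs[setdiff(names(lst$costs),
                                         "include_patient_fees")], as.numeric),
                list(include_patient_fees =
                       isTRUE(lst$costs$include_patient_fees))),
      wtp = as.numeric(lst$wtp),
      perspective = as.character(lst$perspective),
      horizon_years = as.numeric(lst$horizon_years)
    ),
    class = "qol_params"
  )
}

# Set a `a.b.c`-dotted key in a nested list.
set_nested <- function(lst, key, value) {
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  if (length(parts) == 1) {
    lst[[parts]] <- value
    return(lst)
  }
  head <- parts[1]
  rest <- paste(parts[-1], collapse = ".")
  if (is.null(lst[[head]])) lst[[head]] <- list()
  lst[[head]] <- set_nested(lst[[head]], rest, value)
  lst
}

#' Load model parameters from a configuration file
#'
#' Reads a YAML or JSON configuration whose keys mirror the fields of
#' [default_parameters()] (any subset; omitted keys keep their defaults),
#' applies optional key-value overrides with dotted paths (e.g.
#' `"outcomes.delta_u"`), and re-validates all invariants.
#'
#' An empty file yields exactly the default parameter set.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file.
#' @param overrides Named list of overrides; names are dotted key paths.
#' @return A validated `qol_params` object.
#' @export
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("wtp: 50000", f)
#' load_config(f)$wtp
load_config <- function(path, overrides = list()) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()
  base <- as_params_list(default_parameters())
  merged <- utils::modifyList(base, cfg)
  for (key in names(overrides)) {
    merged <- set_nested(merged, key, overrides[[key]])
  }
  params <- params_from_list(merged)
  # a config may change utilities without restating prevalence: keep explicit
  validate_parameters(params)
}

#' Write model parameters to a configuration file
#'
#' Serializes a `qol_params` object to YAML or JSON. Reloading the file with
#' [load_config()] reproduces an equal parameter set (round-trip property).
#'
#' @param params A `qol_params` object.
#' @param path Output path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path) {
  validate_parameters(params)
  lst <- as_params_list(params)
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(lst, path, precision = 15)
  }
  invisible(path)
}
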