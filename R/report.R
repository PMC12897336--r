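# Reporting pipeline: deterministic base-case, PSA and synthetic-cohort
# reports with a run manifest. These functions back the thin command-line
# wrapper shipped in inst/cli/qolcea.R.

resolve_params <- function(config, overrides = list()) {
  if (is.null(config)) {
    params <- default_parameters()
    if (length(overrides)) {
      lst <- as_params_list(params)
      for (key in names(overrides)) {
        lst <- set_nested(lst, key, overrides[[key]])
      }
      params <- validate_parameters(params_from_list(lst))
    }
    params
  } else {
    load_config(config, overrides)
  }
}

# Hash the canonical JSON rendering of the configuration (timestamps and
# output paths are never part of the hashed content).
config_hash <- function(params) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(as_params_list(params), tmp, auto_unbox = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}

write_manifest <- function(outdir, params, seed, outputs) {
  manifest <- list(
    package = "qolcea",
    version = as.character(utils::packageVersion("qolcea")),
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config_md5 = config_hash(params),
    outputs = basename(outputs)
  )
  path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

# Table-style view: costs to whole euros, QALYs to three decimals, matching
# the rounding conventions of the published tables.
format_incremental <- function(inc) {
  tibble::tibble(
    strategy_id = inc$strategy_id,
    cost = round(inc$cost),
    delta_cost = round(inc$delta_cost),
    qaly = round(inc$qaly, 3),
    delta_qaly = round(inc$delta_qaly, 3),
    icer = round(inc$icer),
    status = inc$status
  )
}

#' Base-case report
#'
#' Evaluates all strategies under the configured (or default) parameters and
#' writes the strategy results (full precision), the incremental table in the
#' published rounding convention, the frontier as JSON, the calibration
#' check, and a run manifest. All outputs are deterministic.
#'
#' @param config Optional path to a YAML/JSON configuration; `NULL` uses the
#'   base-case defaults.
#' @param outdir Output directory (created if needed).
#' @param overrides Named list of dotted-key parameter overrides.
#' @return Invisibly, a character vector of the files written.
#' @export
cmd_basecase <- function(config = NULL, outdir, overrides = list()) {
  params <- resolve_params(config, overrides)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  results <- evaluate_all(params)
  inc <- build_frontier(results)
  calib <- verify_calibration(params)

  f_results <- file.path(outdir, "strategy_results.csv")
  data.table::fwrite(as.data.frame(results), f_results)
  f_inc <- file.path(outdir, "incremental_table.csv")
  data.table::fwrite(format_incremental(inc), f_inc)
  f_frontier <- file.path(outdir, "frontier.json")
  jsonlite::write_json(inc, f_frontier, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  f_calib <- file.path(outdir, "calibration_check.json")
  verify_calibration(params, json_path = f_calib)

  files <- c(f_results, f_inc, f_frontier, f_calib)
  manifest <- write_manifest(outdir, params, seed = NA, outputs = files)
  invisible(c(files, manifest))
}

#' PSA report
#'
#' Runs the probabilistic sensitivity analysis and writes the per-draw table,
#' the acceptability curves (wide CSV: one WTP column plus one probability
#' column per strategy) and a manifest recording the seed. Outputs are
#' byte-reproducible for a fixed seed.
#'
#' @inheritParams cmd_basecase
#' @param n_sims Number of Monte Carlo draws.
#' @param seed Integer seed.
#' @param wtp_grid Willingness-to-pay grid.
#' @return Invisibly, the files written.
#' @export
cmd_psa <- function(config = NULL, n_sims = 10000, seed = 1, outdir,
                    wtp_grid = default_wtp_grid(), overrides = list()) {
  params <- resolve_params(config, overrides)
  stopifnot(n_sims >= 1)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  psa <- run_psa(params, n_sims = n_sims, wtp_grid = wtp_grid, seed = seed)
  cc <- ceac(psa)

  f_draws <- file.path(outdir, "psa_draws.csv")
  data.table::fwrite(as.data.frame(psa$draws), f_draws)
  # wide CEAC: wtp, then one column per strategy
  ids <- unique(cc$strategy_id)
  wide <- data.frame(wtp = unique(cc$wtp))
  for (id in ids) {
    wide[[id]] <- cc$probability[cc$strategy_id == id]
  }
  f_ceac <- file.path(outdir, "ceac.csv")
  data.table::fwrite(wide, f_ceac)

  files <- c(f_draws, f_ceac)
  manifest <- write_manifest(outdir, params, seed = seed, outputs = files)
  invisible(c(files, manifest))
}

#' Synthetic-cohort report
#'
#' Generates a synthetic cohort, writes it as CSV, and writes a JSON summary
#' with the group means, the estimated prevalence and the fitted utilization
#' slopes.
#'
#' @param cp A `qol_cohort_params` object; defaults to the base-case
#'   generator settings at the given size and seed.
#' @param n_patients,seed Convenience arguments used when `cp` is `NULL`.
#' @param outdir Output directory.
#' @return Invisibly, the files written.
#' @export
cmd_synth <- function(cp = NULL, n_patients = 660, seed = 1, outdir) {
  if (is.null(cp)) {
    cp <- cohort_parameters(n_patients = n_patients, seed = seed)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  coh <- generate_cohort(cp)
  f_cohort <- file.path(outdir, "cohort.csv")
  write_cohort(coh, f_cohort)

  summ <- summarize_cohort(coh)
  fit_v <- fit_utilization_slope(coh, "visits")
  fit_s <- fit_utilization_slope(coh, "sick_days")
  report <- list(
    n_patients = nrow(coh),
    estimated_prevalence = estimate_prevalence(coh, cp$low_threshold),
    u_baseline_mean = attr(summ, "u_baseline_mean"),
    group_means = summ,
    visits_fit = fit_v[c("intercept", "slope", "slope_se", "slope_per_001")],
    sick_days_fit = fit_s[c("intercept", "slope", "slope_se",
                            "slope_per_001")]
  )
  f_summary <- file.path(outdir, "cohort_summary.json")
  jsonlite::write_json(report, f_summary, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  files <- c(f_cohort, f_summary)
  manifest <- write_manifest(outdir, default_parameters(), seed = cp$seed,
                             outputs = files)
  invisible(c(files, manifest))
}
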