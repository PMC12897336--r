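# Probabilistic sensitivity analysis: parameter distributions, Monte Carlo
# propagation through the decision tree, and acceptability curves.

#' Default uncertainty specification
#'
#' One row per model parameter with its sampling distribution for the PSA:
#' gamma for costs (method-of-moments, spread = coefficient of variation),
#' beta for the utility-scale IPS gain (spread = standard deviation), normal
#' for the regression coefficients (spread = standard deviation), `fixed` for
#' parameters the base-case table does not vary (the state utilities, the
#' group utilization levels and the sick-day unit cost).
#'
#' The spread magnitudes are not published; the defaults — CV 0.2 for gamma
#' costs, sd 0.02 for the beta-distributed +0.08 utility gain, sd equal to
#' half the mean for the normal coefficients — are this package's own choice
#' of wide parameter uncertainty and are fully configurable.
#'
#' @param params A `qol_params` object supplying the central values.
#' @param cost_cv Coefficient of variation of the gamma cost distributions.
#' @param delta_u_sd Standard deviation of the beta-distributed utility gain.
#' @param coeff_sd_frac Normal coefficient sd as a fraction of the mean.
#' @return A tibble of class `qol_uncertainty` with columns `parameter`,
#'   `dist` (`gamma`/`beta`/`normal`/`fixed`), `mean`, `spread`.
#' @export
default_uncertainty <- function(params = default_parameters(),
                                cost_cv = 0.2,
                                delta_u_sd = 0.02,
                                coeff_sd_frac = 0.5) {
  o <- params$outcomes
  cc <- params$costs
  s <- params$strategies
  pred <- s[s$id != "no_prediction", ]
  spec <- tibble::tibble(
    parameter = c(
      "ips_cost_provider", "ips_cost_patient",
      "visit_cost_provider", "visit_cost_patient",
      paste0("prediction_cost.", pred$id),
      "delta_u", "visit_coeff", "sickday_coeff",
      "u_low", "u_high", "visits_low", "visits_high",
      "sickdays_low", "sickdays_high", "sick_day_cost"
    ),
    dist = c(rep("gamma", 4 + nrow(pred)),
             "beta", "normal", "normal",
             rep("fixed", 7)),
    mean = c(cc$ips_cost_provider, cc$ips_cost_patient,
             cc$visit_cost_provider, cc$visit_cost_patient,
             pred$prediction_cost,
             o$delta_u, o$visit_coeff, o$sickday_coeff,
             o$u_low, o$u_high, o$visits_low, o$visits_high,
             o$sickdays_low, o$sickdays_high, cc$sick_day_cost),
    spread = c(rep(cost_cv, 4 + nrow(pred)),
               delta_u_sd, coeff_sd_frac * o$visit_coeff,
               coeff_sd_frac * o$sickday_coeff,
               rep(NA_real_, 7))
  )
  validate_uncertainty(spec)
  class(spec) <- c("qol_uncertainty", class(spec))
  spec
}

#' Uncertainty specification with every parameter held fixed
#'
#' Degenerate specification used to check that the PSA machinery collapses to
#' the deterministic base case.
#'
#' @inheritParams default_uncertainty
#' @return A `qol_uncertainty` tibble with all distributions `fixed`.
#' @export
degenerate_uncertainty <- function(params = default_parameters()) {
  spec <- default_uncertainty(params)
  spec$dist <- "fixed"
  spec$spread <- NA_real_
  spec
}

validate_uncertainty <- function(spec) {
  stopifnot(all(c("parameter", "dist", "mean", "spread") %in% names(spec)))
  bad <- !spec$dist %in% c("gamma", "beta", "normal", "fixed")
  if (any(bad)) {
    stop("unknown distribution: ", paste(spec$dist[bad], collapse = ", "),
         call. = FALSE)
  }
  varied <- spec$dist != "fixed"
  if (any(is.na(spec$spread[varied]) | spec$spread[varied] <= 0)) {
    stop("non-fixed parameters need a positive spread", call. = FALSE)
  }
  is_beta <- spec$dist == "beta"
  if (any(is_beta)) {
    m <- spec$mean[is_beta]
    v <- spec$spread[is_beta]^2
    if (any(m <= 0 | m >= 1 | v >= m * (1 - m))) {
      stop("infeasible beta moments: need 0 < mean < 1 and sd^2 < mean*(1-mean)",
           call. = FALSE)
    }
  }
  invisible(spec)
}

# Draw n values from one spec row. Gamma by method of moments
# (shape = 1/cv^2, scale = mean*cv^2); beta by method of moments; normal by
# (mean, sd); fixed passed through.
sample_one <- function(dist, mean, spread, n) {
  switch(dist,
    fixed = rep(mean, n),
    gamma = {
      shape <- 1 / spread^2
      rgamma(n, shape = shape, rate = shape / mean)
    },
    beta = {
      v <- spread^2
      a <- mean * (mean * (1 - mean) / v - 1)
      b <- (1 - mean) * (mean * (1 - mean) / v - 1)
      rbeta(n, a, b)
    },
    normal = rnorm(n, mean, spread)
  )
}

# All parameter draws as an n x k tibble; column order fixed by the spec.
sample_draws <- function(spec, n) {
  validate_uncertainty(spec)
  cols <- lapply(seq_len(nrow(spec)), function(i) {
    sample_one(spec$dist[i], spec$mean[i], spec$spread[i], n)
  })
  names(cols) <- spec$parameter
  tibble::as_tibble(cols)
}

#' Draw one parameter set from the uncertainty specification
#'
#' Samples every parameter once from its assigned distribution and injects
#' the draw into a copy of `params`. Costs are non-negative by construction
#' (gamma), the utility gain lies in \[0, 1\] by construction (beta); normal
#' regression coefficients may go negative, reflecting genuine sign
#' uncertainty.
#'
#' @param params A `qol_params` object (central values and fixed fields).
#' @param spec A `qol_uncertainty` tibble (see [default_uncertainty()]).
#' @return A `qol_params` object with sampled values.
#' @export
sample_parameters <- function(params, spec = default_uncertainty(params)) {
  d <- sample_draws(spec, 1)
  inject_draw(params, d, 1)
}

inject_draw <- function(params, draws, i) {
  get <- function(name, default) {
    if (name %in% names(draws)) draws[[name]][i] else default
  }
  p <- params
  for (f in c("ips_cost_provider", "ips_cost_patient", "visit_cost_provider",
              "visit_cost_patient", "sick_day_cost")) {
    p$costs[[f]] <- get(f, p$costs[[f]])
  }
  for (f in c("delta_u", "visit_coeff", "sickday_coeff", "u_low", "u_high",
              "visits_low", "visits_high", "sickdays_low", "sickdays_high")) {
    p$outcomes[[f]] <- get(f, p$outcomes[[f]])
  }
  for (j in seq_len(nrow(p$strategies))) {
    nm <- paste0("prediction_cost.", p$strategies$id[j])
    p$strategies$prediction_cost[j] <- get(nm, p$strategies$prediction_cost[j])
  }
  p
}

#' Run the probabilistic sensitivity analysis
#'
#' Samples `n_sims` parameter sets from `spec`, evaluates every strategy's
#' expected cost and QALYs for each draw (costs and QALYs do not depend on
#' the willingness to pay, so one draw serves every grid point), and returns
#' the per-draw results. Identical seeds give identical tables.
#'
#' @param params A `qol_params` object (base case and fixed fields).
#' @param spec A `qol_uncertainty` tibble.
#' @param n_sims Number of Monte Carlo draws (>= 1); the published analysis
#'   used 10,000.
#' @param wtp_grid Willingness-to-pay grid, EUR/QALY; default EUR 1 then
#'   1,000-EUR steps to 140,000.
#' @param seed Integer seed.
#' @return A list of class `qol_psa` with elements `draws` (tibble: `draw`,
#'   `strategy_id`, `cost`, `qaly`), `wtp_grid`, `n_sims`, `seed`,
#'   `perspective`.
#' @export
#' @examples
#' psa <- run_psa(default_parameters(), n_sims = 100, seed = 7)
#' head(psa$draws)
run_psa <- function(params,
                    spec = default_uncertainty(params),
                    n_sims = 10000,
                    wtp_grid = default_wtp_grid(),
                    seed = 1) {
  validate_parameters(params)
  stopifnot(n_sims >= 1, length(wtp_grid) >= 1)
  d <- with_seed(seed, sample_draws(spec, n_sims))
  pick <- function(name, default) {
    if (name %in% names(d)) d[[name]] else rep(default, n_sims)
  }
  o <- params$outcomes
  cc <- params$costs
  fee <- as.numeric(cc$include_patient_fees)
  c_ips <- pick("ips_cost_provider", cc$ips_cost_provider) +
    fee * pick("ips_cost_patient", cc$ips_cost_patient)
  c_visit <- pick("visit_cost_provider", cc$visit_cost_provider) +
    fee * pick("visit_cost_patient", cc$visit_cost_patient)
  c_sick <- pick("sick_day_cost", cc$sick_day_cost)
  delta_u <- pick("delta_u", o$delta_u)

  s <- params$strategies
  pieces <- lapply(seq_len(nrow(s)), function(j) {
    comp <- eval_core(
      p = params$prevalence,
      sens = s$sensitivity[j], spec = s$specificity[j],
      offers = s$offers_support[j],
      pred_cost = pick(paste0("prediction_cost.", s$id[j]),
                       s$prediction_cost[j]),
      u_low = pick("u_low", o$u_low), u_high = pick("u_high", o$u_high),
      gain_per_tp = delta_u * o$benefit_duration_fraction,
      visits_low = pick("visits_low", o$visits_low),
      visits_high = pick("visits_high", o$visits_high),
      sickdays_low = pick("sickdays_low", o$sickdays_low),
      sickdays_high = pick("sickdays_high", o$sickdays_high),
      visit_coeff = pick("visit_coeff", o$visit_coeff),
      sickday_coeff = pick("sickday_coeff", o$sickday_coeff),
      delta_u = delta_u,
      c_ips = c_ips, c_visit = c_visit, c_sick_day = c_sick,
      societal = params$perspective == "societal"
    )
    tibble::tibble(draw = seq_len(n_sims), strategy_id = s$id[j],
                   cost = comp$expected_cost, qaly = comp$expected_qaly)
  })
  structure(
    list(draws = do.call(rbind, pieces), wtp_grid = wtp_grid,
         n_sims = n_sims, seed = seed, perspective = params$perspective),
    class = "qol_psa"
  )
}

#' Default willingness-to-pay grid
#'
#' EUR 1, then 1,000-EUR steps up to EUR 140,000 per QALY (the published
#' analysis states the range; the step is this package's choice).
#'
#' @return Numeric vector of WTP thresholds.
#' @export
default_wtp_grid <- function() {
  c(1, seq(1000, 140000, by = 1000))
}

#' Cost-effectiveness acceptability curves
#'
#' For each willingness-to-pay threshold, the probability that each strategy
#' attains the highest net monetary benefit across the PSA draws. Exact NMB
#' ties within a draw are split equally among the tied strategies, so the
#' probabilities sum to one at every grid point.
#'
#' @param psa A `qol_psa` object from [run_psa()], or its `draws` tibble.
#' @param wtp_grid WTP thresholds; defaults to the grid stored in `psa`.
#' @return A tibble with columns `wtp`, `strategy_id`, `probability`.
#' @export
ceac <- function(psa, wtp_grid = NULL) {
  draws <- if (inherits(psa, "qol_psa")) psa$draws else psa
  if (is.null(wtp_grid)) {
    wtp_grid <- if (inherits(psa, "qol_psa")) psa$wtp_grid else
      default_wtp_grid()
  }
  if (is.null(draws) || nrow(draws) == 0) {
    stop("empty draws table", call. = FALSE)
  }
  ids <- unique(draws$strategy_id)
  n_draw <- length(unique(draws$draw))
  cost <- matrix(draws$cost, nrow = n_draw,
                 dimnames = list(NULL, NULL))[, seq_along(ids), drop = FALSE]
  qaly <- matrix(draws$qaly, nrow = n_draw)[, seq_along(ids), drop = FALSE]
  rows <- lapply(wtp_grid, function(w) {
    nmb_m <- w * qaly - cost
    best <- nmb_m == apply(nmb_m, 1, max)
    wts <- best / rowSums(best)
    tibble::tibble(wtp = w, strategy_id = ids, probability = colMeans(wts))
  })
  do.call(rbind, rows)
}
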