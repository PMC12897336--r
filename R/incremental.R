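# Incremental cost-effectiveness analysis: ICERs, dominance, frontier.

#' Net monetary benefit
#'
#' `nmb = wtp * qaly - cost`.
#'
#' @param qaly QALYs per patient.
#' @param cost Cost in EUR per patient.
#' @param wtp Willingness to pay, EUR per QALY.
#' @return NMB in EUR per patient. Vectorized.
#' @export
#' @examples
#' nmb(0.745, 6104, 30000)
nmb <- function(qaly, cost, wtp) {
  wtp * qaly - cost
}

#' Incremental cost-effectiveness ratio
#'
#' `icer = delta_cost / delta_qaly`; undefined (NA) when `delta_qaly` is 0.
#'
#' @param delta_cost Incremental cost, EUR.
#' @param delta_qaly Incremental QALYs.
#' @return EUR per QALY gained, or `NA` where `delta_qaly == 0`. Vectorized.
#' @export
#' @examples
#' icer(250, 0.011)
icer <- function(delta_cost, delta_qaly) {
  ifelse(delta_qaly == 0, NA_real_, delta_cost / delta_qaly)
}

# Accept a qol_results tibble or any data frame with recognizable columns.
normalize_results <- function(results) {
  df <- as.data.frame(results)
  id <- df[["strategy_id"]] %||% df[["id"]]
  cost <- df[["expected_cost"]] %||% df[["cost"]]
  qaly <- df[["expected_qaly"]] %||% df[["qaly"]]
  if (is.null(id) || is.null(cost) || is.null(qaly)) {
    stop("results must contain strategy id, cost and QALY columns",
         call. = FALSE)
  }
  data.frame(strategy_id = as.character(id), cost = as.numeric(cost),
             qaly = as.numeric(qaly), stringsAsFactors = FALSE)
}

#' Build the cost-effectiveness frontier
#'
#' Implements the standard sequential incremental analysis: strategies are
#' ordered by increasing cost (ties broken by higher QALYs), strictly
#' dominated strategies (another strategy with cost <= and QALYs >=, at least
#' one strict) are marked, then extendedly dominated strategies — whose ICER
#' versus the previous frontier member strictly exceeds the ICER of the next,
#' more effective member — are removed iteratively until the ICERs along the
#' frontier increase. Equal ICERs (collinear strategies) are kept.
#'
#' Incremental columns (`delta_cost`, `delta_qaly`, `icer`) are reported
#' versus the previous row of the cost-ordered table, mirroring the published
#' presentation; `icer_vs_reference` compares each strategy with the cheapest
#' (reference) strategy.
#'
#' @param results A `qol_results` tibble from [evaluate_all()], or any data
#'   frame with strategy id, cost and QALY columns (e.g.
#'   [basecase_reference()]). At least two strategies.
#' @return A tibble of `IncrementalRow`s ordered by cost: `strategy_id`,
#'   `cost`, `qaly`, `delta_cost`, `delta_qaly`, `icer`, `icer_vs_reference`,
#'   `status` (one of `reference`, `on_frontier`, `dominated`,
#'   `extendedly_dominated`).
#' @export
#' @examples
#' build_frontier(basecase_reference())
build_frontier <- function(results) {
  df <- normalize_results(results)
  if (nrow(df) < 2) {
    stop("at least two strategies are required for incremental analysis",
         call. = FALSE)
  }
  df <- df[order(df$cost, -df$qaly), ]
  rownames(df) <- NULL
  n <- nrow(df)

  # strict dominance
  dominated <- vapply(seq_len(n), function(i) {
    any(df$cost <= df$cost[i] & df$qaly >= df$qaly[i] &
          (df$cost < df$cost[i] | df$qaly > df$qaly[i]))
  }, logical(1))

  # extended dominance on the survivors, iterated
  ext <- rep(FALSE, n)
  repeat {
    cand <- which(!dominated & !ext)
    if (length(cand) < 3) break
    cc <- df$cost[cand]
    qq <- df$qaly[cand]
    icers <- (cc[-1] - cc[-length(cc)]) / (qq[-1] - qq[-length(qq)])
    removed <- FALSE
    for (k in seq_len(length(icers) - 1)) {
      if (!is.na(icers[k]) && !is.na(icers[k + 1]) &&
          icers[k] > icers[k + 1]) {
        ext[cand[k + 1]] <- TRUE
        removed <- TRUE
        break
      }
    }
    if (!removed) break
  }

  status <- rep("on_frontier", n)
  status[dominated] <- "dominated"
  status[ext] <- "extendedly_dominated"
  status[1] <- "reference"

  delta_cost <- c(NA_real_, diff(df$cost))
  delta_qaly <- c(NA_real_, diff(df$qaly))
  tibble::tibble(
    strategy_id = df$strategy_id,
    cost = df$cost,
    qaly = df$qaly,
    delta_cost = delta_cost,
    delta_qaly = delta_qaly,
    icer = icer(delta_cost, delta_qaly),
    icer_vs_reference = icer(df$cost - df$cost[1], df$qaly - df$qaly[1]),
    status = status
  )
}

#' Rank strategies by net monetary benefit
#'
#' Orders strategies by decreasing NMB at a given willingness to pay; ties
#' are broken by lower cost, then alphabetically by strategy id, so the
#' ordering is deterministic.
#'
#' @param results As in [build_frontier()].
#' @param wtp Willingness to pay, EUR per QALY.
#' @return A tibble ordered by decreasing NMB with columns `rank`,
#'   `strategy_id`, `cost`, `qaly`, `nmb`.
#' @export
#' @examples
#' rank_by_nmb(basecase_reference(), wtp = 30000)
rank_by_nmb <- function(results, wtp) {
  df <- normalize_results(results)
  df$nmb <- nmb(df$qaly, df$cost, wtp)
  ord <- order(-df$nmb, df$cost, df$strategy_id)
  df <- df[ord, ]
  tibble::tibble(
    rank = seq_len(nrow(df)),
    strategy_id = df$strategy_id,
    cost = df$cost,
    qaly = df$qaly,
    nmb = df$nmb
  )
}
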