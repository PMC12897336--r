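# Independent oracles used by the property tests. These deliberately avoid
# the package's own algorithms.

# Frontier membership by exhaustive enumeration: a strategy is on the
# cost-effectiveness frontier iff it is not strictly dominated and attains
# the maximum net monetary benefit for some willingness to pay >= 0. The
# candidate thresholds are the kink points (all non-negative pairwise ICERs),
# zero, and one value beyond the largest kink.
frontier_oracle <- function(df) {
  n <- nrow(df)
  nd <- which(!vapply(seq_len(n), function(i) {
    any(df$cost <= df$cost[i] & df$qaly >= df$qaly[i] &
          (df$cost < df$cost[i] | df$qaly > df$qaly[i]))
  }, logical(1)))
  cost <- df$cost[nd]
  qaly <- df$qaly[nd]
  lams <- c()
  for (i in seq_along(nd)) {
    for (j in seq_along(nd)) {
      dq <- qaly[i] - qaly[j]
      if (dq != 0) {
        l <- (cost[i] - cost[j]) / dq
        if (is.finite(l) && l >= 0) lams <- c(lams, l)
      }
    }
  }
  lams <- c(0, lams, max(c(lams, 0)) + 1)
  on <- vapply(seq_along(nd), function(i) {
    any(vapply(lams, function(l) {
      benefit <- l * qaly - cost
      benefit[i] >= max(benefit) - 1e-9
    }, logical(1)))
  }, logical(1))
  sort(df$strategy_id[nd][on])
}

# Random strategy sets for the frontier property tests.
random_strategy_set <- function(k) {
  data.frame(
    strategy_id = paste0("s", seq_len(k)),
    cost = round(runif(k, 0, 10000), 2),
    qaly = round(runif(k, 0, 1), 4),
    stringsAsFactors = FALSE
  )
}

# Mixture-model prevalence calibration by brute-force grid search.
calibrate_prevalence_grid <- function(u_low, u_high, anchor,
                                      grid = seq(0, 1, by = 0.001)) {
  mix <- grid * u_low + (1 - grid) * u_high
  grid[which.min(abs(mix - anchor))]
}
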