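# Plots: cost-effectiveness plane with the frontier, and acceptability curves.

#' Plot the cost-effectiveness plane and frontier
#'
#' QALYs on the x-axis, costs on the y-axis; all strategies are shown as
#' points and the non-dominated strategies (reference plus frontier members)
#' are connected by the frontier line.
#'
#' @param frontier A tibble from [build_frontier()], or a results table that
#'   will be run through it.
#' @return A ggplot object.
#' @export
plot_frontier <- function(frontier) {
  if (!"status" %in% names(frontier)) {
    frontier <- build_frontier(frontier)
  }
  on_front <- frontier[frontier$status %in% c("reference", "on_frontier"), ]
  ggplot2::ggplot(frontier, ggplot2::aes(x = .data$qaly, y = .data$cost)) +
    ggplot2::geom_line(data = on_front, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status), size = 3) +
    ggplot2::geom_text(ggplot2::aes(label = .data$strategy_id),
                       vjust = -1, size = 3) +
    ggplot2::labs(x = "QALYs per patient", y = "Cost per patient (EUR)",
                  colour = NULL, title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Plot cost-effectiveness acceptability curves
#'
#' One curve per strategy: the probability of attaining the highest net
#' monetary benefit as a function of the willingness-to-pay threshold.
#'
#' @param ceac_tbl A tibble from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_tbl) {
  ggplot2::ggplot(ceac_tbl,
                  ggplot2::aes(x = .data$wtp, y = .data$probability,
                               colour = .data$strategy_id)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (EUR/QALY)",
                  y = "P(highest NMB)", colour = "Strategy",
                  title = "Cost-effectiveness acceptability curves") +
    ggplot2::theme_minimal()
}
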