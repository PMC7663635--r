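#' Cost-effectiveness plane
#'
#' Scatter of incremental QALYs (x) against incremental cost (y) across the
#' PSA draws, with the willingness-to-pay threshold line; draws below the
#' line are cost-effective at that threshold.
#'
#' @param result a `psa_result` from [run_psa()].
#' @param wtp threshold (USD/QALY) drawn through the origin.
#' @return a ggplot object.
#' @export
plot_ce_plane <- function(result, wtp = 100000) {
  df <- result$draws
  ggplot2::ggplot(df, ggplot2::aes(x = .data$delta_qaly,
                                   y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.6, colour = "steelblue") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = "Incremental effectiveness (QALY)",
      y = "Incremental cost (USD)",
      title = "Cost-effectiveness plane",
      subtitle = sprintf("WTP threshold $%s/QALY",
                         format(wtp, big.mark = ","))
    ) +
    ggplot2::theme_minimal()
}

#' Tornado diagram
#'
#' @param tor a `tornado_result` from [tornado()].
#' @return a ggplot object; bars span the low/high ICERs per variable,
#'   ordered by leverage, with the base-case ICER as a vertical line.
#' @export
plot_tornado <- function(tor) {
  base <- attr(tor, "base_icer")
  df <- as.data.frame(tor)
  df$lo <- pmin(df$icer_low, df$icer_high)
  df$hi <- pmax(df$icer_low, df$icer_high)
  df$span <- df$hi - df$lo
  df$variable <- stats::reorder(df$variable, df$span)
  ggplot2::ggplot(df, ggplot2::aes(y = .data$variable)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$lo, xend = .data$hi,
                                       yend = .data$variable),
                          linewidth = 5, colour = "grey55") +
    ggplot2::geom_vline(xintercept = base, linetype = 2) +
    ggplot2::labs(x = "ICER (USD/QALY)", y = NULL,
                  title = "One-way sensitivity (+/-25%)") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curve
#'
#' @param result a `psa_result`.
#' @return a ggplot object: probability of positive net monetary benefit
#'   against the willingness-to-pay threshold.
#' @export
plot_ceac <- function(result) {
  ggplot2::ggplot(result$ceac,
                  ggplot2::aes(x = .data$wtp,
                               y = .data$prob_cost_effective)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "P(cost-effective)",
                  title = "Cost-effectiveness acceptability") +
    ggplot2::theme_minimal()
}
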