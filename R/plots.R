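# Optional figure renderers. All analyses emit data tables; these helpers
# draw the conventional figures when ggplot2 is available.

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for rendering; install it or use the data tables")
}

#' Tornado diagram
#' @param tornado result of [one_way_sensitivity()].
#' @param top number of widest bars to show.
#' @return A ggplot object.
#' @export
plot_tornado <- function(tornado, top = 15) {
  need_ggplot()
  d <- utils::head(as.data.frame(tornado), top)
  d$parameter_id <- factor(d$parameter_id, levels = rev(d$parameter_id))
  ggplot2::ggplot(d, ggplot2::aes(y = .data$parameter_id)) +
    ggplot2::geom_linerange(ggplot2::aes(xmin = pmin(.data$icer_low, .data$icer_high),
                                         xmax = pmax(.data$icer_low, .data$icer_high)),
                            linewidth = 4, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = attr(tornado, "base_icer"),
                        linetype = "dashed") +
    ggplot2::labs(x = "ICER (USD/QALY)", y = NULL,
                  title = "One-way sensitivity of the ICER")
}

#' Cost-effectiveness acceptability curve
#' @param ceac_table result of [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(ceac_table) {
  need_ggplot()
  ggplot2::ggplot(ceac_table, ggplot2::aes(.data$wtp, .data$probability)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Willingness to pay (USD/QALY)",
                  y = "Probability TAVR cost-effective",
                  title = "Cost-effectiveness acceptability curve")
}

#' Cost-effectiveness plane scatter
#' @param psa a `psa_result`.
#' @param wtp willingness-to-pay line to draw.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, wtp = 37500) {
  need_ggplot()
  ggplot2::ggplot(psa$draws, ggplot2::aes(.data$delta_qaly, .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.5, colour = "steelblue") +
    ggplot2::geom_abline(slope = wtp, intercept = 0, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0) + ggplot2::geom_vline(xintercept = 0) +
    ggplot2::labs(x = "Incremental QALY", y = "Incremental cost (USD)",
                  title = "Cost-effectiveness plane")
}
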