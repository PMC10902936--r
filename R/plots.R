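# ggplot2 figures: tornado diagram, cost-effectiveness plane with a 95%
# ellipse, and cost-effectiveness acceptability curves.

#' Tornado diagram
#'
#' Horizontal bars spanning the ICER at the low and high end of each
#' parameter's range, widest spread on top, with a vertical line at the
#' base-case ICER.
#'
#' @param entries A `tornado` data frame from [tornado()].
#' @return A ggplot object.
#' @export
plot_tornado <- function(entries) {
  if (!inherits(entries, "tornado")) stop("'entries' must come from tornado()")
  base_icer <- attr(entries, "base_icer")
  df <- as.data.frame(entries)
  df$parameter <- factor(df$parameter, levels = rev(df$parameter))
  lo <- pmin(df$icer_at_low, df$icer_at_high)
  hi <- pmax(df$icer_at_low, df$icer_at_high)
  df$ymin <- lo
  df$ymax <- hi
  ggplot2::ggplot(df, ggplot2::aes(y = .data$parameter)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$ymin, xend = .data$ymax,
                                       yend = .data$parameter),
                          linewidth = 5, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = base_icer, linetype = 2) +
    ggplot2::labs(x = "ICER (USD per tooth-life-year)", y = NULL,
                  title = "One-way sensitivity analysis") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness plane
#'
#' Scatter of the per-iteration incremental effect and incremental cost
#' (root canal treatment minus pulpotomy) with quadrant axes and a 95%
#' normal-theory ellipse.
#'
#' @param psa A `psa_result` from [run_psa()].
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa) {
  if (!inherits(psa, "psa_result")) stop("'psa' must come from run_psa()")
  df <- psa$incremental
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d_effect, y = .data$d_cost)) +
    ggplot2::geom_point(alpha = 0.2, size = 0.6, colour = "firebrick") +
    ggplot2::stat_ellipse(level = 0.95, colour = "black") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::geom_vline(xintercept = 0) +
    ggplot2::labs(x = "Incremental effect (tooth-life-years)",
                  y = "Incremental cost (USD)",
                  title = "Cost-effectiveness plane") +
    ggplot2::theme_minimal()
}

#' Cost-effectiveness acceptability curves
#'
#' @param curve A `ceac_curve` from [ceac()].
#' @return A ggplot object.
#' @export
plot_ceac <- function(curve) {
  if (!inherits(curve, "ceac_curve")) stop("'curve' must come from ceac()")
  ggplot2::ggplot(as.data.frame(curve),
                  ggplot2::aes(x = .data$wtp, y = .data$probability,
                               colour = .data$strategy)) +
    ggplot2::geom_line(linewidth = 1) +
    ggplot2::labs(x = "Willingness-to-pay (USD per tooth-life-year)",
                  y = "Probability cost-effective", colour = NULL,
                  title = "Cost-effectiveness acceptability curves") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
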