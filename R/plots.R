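#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot methods for PSA uncertainty curves
#'
#' `autoplot()` methods render each result type the way it is conventionally
#' drawn: CEAC and relaxed CEAC as probability-vs-WTP lines with the frontier
#' dashed on top; ELC as expected-loss-vs-WTP lines with the EVPI envelope
#' dashed; the expected benefit plot with its 95% band; densities, dominance
#' and incremental-benefit curves and rankograms as their curve families; the
#' return-risk space as labelled points; and the heat map as curves colored
#' by the joined quantity with frontier-ICER ticks and region labels on the
#' x axis.
#'
#' @param object A result tibble from one of the method functions.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-psacurves
NULL

frontier_layer <- function(object) {
  front <- object[object$on_frontier, , drop = FALSE]
  ggplot2::geom_line(
    data = front,
    ggplot2::aes(x = .data$wtp, y = .data$value, group = 1),
    inherit.aes = FALSE, linetype = "dashed", color = "black",
    linewidth = 0.9
  )
}

wtp_curve_plot <- function(object, ylab) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$wtp, y = .data$value,
                               color = .data$strategy)) +
    ggplot2::geom_line() +
    frontier_layer(object) +
    ggplot2::labs(x = "Willingness to pay", y = ylab, color = "Strategy") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-psacurves
#' @export
autoplot.ceac_curves <- function(object, ...) {
  wtp_curve_plot(object, "Probability of cost-effectiveness") +
    ggplot2::coord_cartesian(ylim = c(0, 1))
}

#' @rdname autoplot-psacurves
#' @export
autoplot.relaxed_ceac_curves <- function(object, ...) {
  relax <- attr(object, "relaxation")
  sub <- paste0("relaxation: ", relax$scheme, " = ", relax$parameter)
  wtp_curve_plot(object, "Probability of cost-effectiveness (relaxed)") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(subtitle = sub)
}

#' @rdname autoplot-psacurves
#' @export
autoplot.elc_curves <- function(object, ...) {
  wtp_curve_plot(object, "Expected loss")
}

#' @rdname autoplot-psacurves
#' @export
autoplot.ebp_curves <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$wtp, y = .data$value,
                               color = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(ggplot2::aes(y = .data$lower), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$upper), linetype = "dashed") +
    ggplot2::labs(x = "Willingness to pay", y = "Expected benefit",
                  color = "Strategy") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-psacurves
#' @export
autoplot.density_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       color = .data$strategy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = attr(object, "measure"), y = "Density",
                  color = "Strategy") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-psacurves
#' @export
autoplot.dominance_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       color = .data$strategy)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = attr(object, "measure"), y = "P(benefit ≥ x)",
                  color = "Strategy") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-psacurves
#' @export
autoplot.ibc_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       color = .data$strategy)) +
    ggplot2::geom_step() +
    ggplot2::geom_vline(xintercept = attr(object, "reference_x"),
                        color = "black") +
    ggplot2::labs(x = "Incremental benefit", y = "P(INB ≤ x)",
                  color = "Strategy") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-psacurves
#' @export
autoplot.return_risk_points <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mean, y = .data$sd,
                                       color = .data$strategy)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Mean benefit (return)", y = "SD of benefit (risk)",
                  color = "Strategy") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-psacurves
#' @export
autoplot.rankogram_curves <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$cum_prob,
                                       color = .data$strategy)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "Rank (1 = best)", y = "P(rank ≤ x)",
                  color = "Strategy") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-psacurves
#' @export
autoplot.psa_heatmap <- function(object, ...) {
  base <- attr(object, "base")
  color_kind <- attr(object, "color_kind")
  segs <- attr(object, "segments")
  ylab <- if (base == "elc") "Expected loss" else
    "Probability of cost-effectiveness"
  collab <- if (color_kind == "probability") "P(cost-effective)" else
    "Expected loss"
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$wtp, y = .data$y_value,
                                    group = .data$strategy,
                                    color = .data$color_value)) +
    ggplot2::geom_line() +
    ggplot2::scale_color_gradient(low = "blue", high = "red") +
    ggplot2::labs(x = "Willingness to pay", y = ylab, color = collab) +
    ggplot2::theme_minimal()
  ticks <- segs$boundary_icer[!is.na(segs$boundary_icer)]
  if (length(ticks) > 0) {
    ymin <- min(object$y_value)
    yrange <- diff(range(object$y_value))
    p <- p + ggplot2::annotate("segment", x = ticks, xend = ticks,
                               y = ymin, yend = ymin + 0.03 * yrange,
                               linewidth = 0.8)
  }
  mid <- (segs$wtp_low + segs$wtp_high) / 2
  p + ggplot2::annotate("text", x = mid, y = min(object$y_value),
                        label = as.character(segs$strategy), vjust = 1.5,
                        size = 3)
}

#' @importFrom rlang .data
NULL
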