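# ggplot2 views of the main result types.

#' Plot an SSD curve
#'
#' Posterior median fraction affected versus concentration (log10 axis)
#' with the 95% credible band.
#'
#' @param object A [ssd_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hssd_ssd_curve
#' @export
autoplot.hssd_ssd_curve <- function(object, ...) {
  sc <- attr(object, "scenario")
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$conc_ug_l)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = expression("Concentration (" * mu * "g/L)"),
      y = "Fraction of species affected",
      title = sprintf("SSD, %g µm, %s", sc$size_um, sc$medium)
    ) +
    ggplot2::theme_minimal()
}

#' Plot an HC5 posterior
#'
#' Histogram of the posterior HC5 draws (log10 axis) with the median and
#' 95% credible limits marked.
#'
#' @param object A [hc5()] result.
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hssd_hc5
#' @export
autoplot.hssd_hc5 <- function(object, bins = 50, ...) {
  ggplot2::ggplot(tibble::tibble(hc5 = object$draws),
                  ggplot2::aes(x = .data$hc5)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey60", colour = "white") +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$median,
                                       object$ci_high),
                        linetype = c("dashed", "solid", "dashed")) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = expression("HC5 (" * mu * "g/L)"), y = "Posterior draws",
      title = sprintf("HC%d posterior, %g µm, %s",
                      round(100 * object$hcp), object$scenario$size_um,
                      object$scenario$medium)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a model-ranking table
#'
#' Delta-WAIC of each candidate model, best model at the top.
#'
#' @param object A [rank_models()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hssd_rank_table
#' @export
autoplot.hssd_rank_table <- function(object, ...) {
  tab <- tibble::as_tibble(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$delta_waic,
                                    y = stats::reorder(.data$model,
                                                       -.data$delta_waic))) +
    ggplot2::geom_col(fill = "grey60") +
    ggplot2::labs(x = expression(Delta * "WAIC"), y = NULL,
                  title = "Candidate SSD models") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
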