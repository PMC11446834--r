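# ggplot2 displays for the main result types.

#' Plot an MEFV envelope
#' @param object An `mefv_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mefv_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$volume_above_RV,
                               y = .data$max_flow)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "Lung volume above RV (L)",
                  y = "Maximal expiratory flow (L/s)",
                  title = "MEFV envelope") +
    ggplot2::theme_minimal()
}

#' Plot a placed tidal curve inside its MEFV envelope
#'
#' The classic overlay used to judge expiratory flow limitation: the
#' composite tidal expiratory limb at its measured operating lung
#' volumes, with the envelope flow at the same volumes.
#'
#' @param object A `placed_tidal`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.placed_tidal <- function(object, ...) {
  df <- tibble::as_tibble(object)
  long <- tidyr::pivot_longer(df, c("exp_flow", "envelope_flow"),
                              names_to = "curve", values_to = "flow")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$abs_volume,
                                     y = .data$flow,
                                     linetype = .data$curve)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::scale_x_reverse() +
    ggplot2::scale_linetype_manual(
      values = c(envelope_flow = "dashed", exp_flow = "solid"),
      labels = c(envelope_flow = "MEFV envelope",
                 exp_flow = "tidal expiratory limb")) +
    ggplot2::labs(x = "Lung volume above RV (L)", y = "Flow (L/s)",
                  linetype = NULL,
                  title = "Tidal loop placement") +
    ggplot2::theme_minimal()
}

#' Plot a repeatability report
#'
#' ICC point estimates with 95% CIs per parameter, against the Koo-Li
#' band boundaries.
#'
#' @param object A `repeat_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.repeat_report <- function(object, ...) {
  df <- object$continuous
  ggplot2::ggplot(df, ggplot2::aes(x = .data$icc,
                                   y = stats::reorder(.data$parameter,
                                                      .data$icc))) +
    ggplot2::geom_vline(xintercept = c(0.5, 0.75, 0.9),
                        linetype = "dotted", colour = "grey50") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$icc_ci_lo,
                                         xmax = .data$icc_ci_hi),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "ICC (95% CI)", y = NULL,
                  title = "Between-day repeatability") +
    ggplot2::theme_minimal()
}
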