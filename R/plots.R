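#' Plot a mutation spectrum
#'
#' Bar chart of per-group direction-class percentages.
#'
#' @param object A [tally_spectrum()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mutation_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ws_class, y = .data$pct,
                                       fill = .data$ws_class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "direction class", y = "% of synonymous mutations") +
    ggplot2::theme_minimal()
}

#' Plot a sliding-window diversity profile
#'
#' Solid line: diversity at W>S columns; dashed: S>W, echoing the usual
#' presentation of direction-partitioned profiles.
#'
#' @param object A [sliding_profile()] result (possibly several groups
#'   row-bound).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.window_profile <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            c("pi_ws", "pi_sw"),
                            names_to = "class", values_to = "pi")
  df$class <- ifelse(df$class == "pi_ws", "W>S", "S>W")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$center, y = .data$pi,
                                        linetype = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c("W>S" = "solid", "S>W" = "dashed")) +
    ggplot2::labs(x = "window center (alignment bp)",
                  y = expression(pi), linetype = NULL) +
    ggplot2::theme_minimal()
  if (!all(is.na(object$group))) p <- p + ggplot2::facet_wrap(~group, ncol = 1)
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
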