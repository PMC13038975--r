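# ggplot2 presentation layer. All plots work from the tidy result tables so
# they stay honest to what the analysis computed.

#' Heatmap of label occurrence frequencies
#'
#' One panel per stimulus class: time on the x axis, template labels on the
#' y axis, occurrence frequency as fill.
#'
#' @param object A `frequency_map` from [occurrence_frequency()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.frequency_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$time * 1000,
    y = stats::reorder(.data$template, -.data$label),
    fill = .data$freq
  )) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~class) +
    ggplot2::scale_fill_viridis_c(name = "occurrence") +
    ggplot2::labs(x = "time (ms)", y = "microstate label") +
    ggplot2::theme_minimal()
}

#' Diverging heatmap of a target-minus-standard frequency difference
#'
#' @param fd Tibble from [frequency_difference()].
#' @return A ggplot object.
#' @export
plot_frequency_difference <- function(fd) {
  ggplot2::ggplot(fd, ggplot2::aes(
    x = .data$time * 1000,
    y = stats::reorder(.data$template, -.data$label),
    fill = .data$diff
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(name = "target - standard",
                                  low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::labs(x = "time (ms)", y = "microstate label") +
    ggplot2::theme_minimal()
}

#' Temporal generalization matrix heatmap
#'
#' @param object An `ms_tgm` from [temporal_generalization()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ms_tgm <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(
    x = .data$test_time * 1000, y = .data$train_time * 1000, fill = .data$f1
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mean F1") +
    ggplot2::labs(x = "testing time (ms)", y = "training time (ms)") +
    ggplot2::theme_minimal()
}

#' DISS time-series plot per stimulus class
#'
#' @param object An `ms_fidelity` from [reconstruction_fidelity()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ms_fidelity <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$time * 1000, y = .data$diss, colour = .data$class
  )) +
    ggplot2::geom_line() +
    ggplot2::ylim(0, 2) +
    ggplot2::labs(x = "time (ms)", y = "DISS (0 = identical, 2 = inverted)") +
    ggplot2::theme_minimal()
}
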