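#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Kaplan-Meier duration curve
#'
#' Step curve of the product-limit estimate with its pointwise log-log 95%
#' confidence band, on the month scale used for reporting.
#'
#' @param object a `crclot_km` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.crclot_km <- function(object, ...) {
  d <- object$curve
  d$months <- days_to_months(d$time)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$months, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf_low, ymax = .data$conf_high),
                         alpha = 0.2, na.rm = TRUE) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Months from second-line start",
                  y = "Probability of continuing treatment",
                  title = "Second-line antiangiogenic treatment duration") +
    ggplot2::theme_minimal()
}

#' Plot transition rates between lines of therapy
#'
#' @param rates tibble from [transition_rates()].
#' @return a ggplot object.
#' @export
plot_transition_rates <- function(rates) {
  rates$pair <- paste(rates$from_line, "→", rates$to_line)
  ggplot2::ggplot(rates, ggplot2::aes(x = .data$pair, y = .data$rate_percent,
                                      fill = .data$presumed_ras)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~population, scales = "free_x") +
    ggplot2::labs(x = "Line transition", y = "Transition rate (%)",
                  fill = "Presumed RAS") +
    ggplot2::theme_minimal()
}

#' Plot regimen frequencies per line
#'
#' @param seq_tab result of [sequence_table()].
#' @param top_n regimens to keep per line (by frequency).
#' @return a ggplot object.
#' @export
plot_sequence_table <- function(seq_tab, top_n = 8L) {
  d <- seq_tab$regimens |>
    dplyr::slice_max(.data$n, n = top_n, with_ties = FALSE,
                     by = c("population", "presumed_ras", "line_label"))
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$regimen_label, .data$n),
                                  y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_grid(line_label ~ population + presumed_ras, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Patients") +
    ggplot2::theme_minimal()
}
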