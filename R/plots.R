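#' Plot regional product skill from a Condorcet report
#'
#' Bar chart of the regional summary R-squared per product, one facet per
#' region, with the Condorcet winner highlighted.
#'
#' @param object A `condorcet_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.condorcet_report <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$product_id, y = .data$mean_r2,
                                  fill = .data$is_winner)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(ggplot2::vars(.data$region)) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey65",
                                          `TRUE` = "#1b7837"),
                               name = "Condorcet winner") +
    ggplot2::labs(x = NULL, y = expression(mean ~ R^2)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot moving-window skill trajectories
#'
#' Mean R-squared across sites per window midpoint, one line per product
#' — the standard way to see how product quality develops over the
#' record.
#'
#' @param window_fits Fit-results tibble with `scope == "window"`.
#' @return A ggplot.
#' @export
plot_window_skill <- function(window_fits) {
  d <- window_fits[window_fits$scope == "window", ] |>
    dplyr::group_by(.data$product_id, .data$midpoint) |>
    dplyr::summarise(mean_r2 = mean(.data$r_squared, na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$midpoint, y = .data$mean_r2,
                                  colour = .data$product_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "window midpoint (year)",
                  y = expression(mean ~ R^2), colour = "product") +
    ggplot2::theme_minimal()
}

#' Plot a site chronology with its sample depth
#'
#' @param chronology A chronology tibble from [build_chronology()].
#' @return A ggplot.
#' @export
plot_chronology <- function(chronology) {
  ggplot2::ggplot(chronology, ggplot2::aes(x = .data$year,
                                           y = .data$index)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "year", y = "ring-width index") +
    ggplot2::facet_wrap(ggplot2::vars(.data$site_id), scales = "free_y") +
    ggplot2::theme_minimal()
}
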