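#' Plot conformer occurrences from a grid search
#'
#' Bar chart of how many grid starts funnelled into each conformer,
#' the standard diagnostic for whether a torsional mapping oversamples
#' a few basins while barely touching others.
#'
#' @param object a [run_search()] result.
#' @param ... ignored.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.conformer_search <- function(object, ...) {
  df <- object$conformers
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$id),
                                   y = .data$occurrences)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "conformer (by increasing energy)",
                  y = "grid starts funnelled",
                  title = sprintf("%d starts, %d conformers",
                                  nrow(object$records), nrow(df))) +
    ggplot2::theme_minimal()
}

#' Plot Boltzmann populations
#'
#' @param object a [boltzmann_populations()] result.
#' @param ... ignored.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.population_set <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = stats::reorder(.data$id, .data$dG_rel), y = .data$x)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = "conformer", y = "population",
                  title = sprintf("Boltzmann populations at %.2f K",
                                  attr(object, "temperature"))) +
    ggplot2::theme_minimal()
}

#' Energy-level diagram of a conformer set
#'
#' Horizontal level lines of relative energies, optionally faceted by
#' a grouping column (e.g. protonation site).
#'
#' @param data a data frame with an energy column.
#' @param energy column name holding relative energies (kcal/mol).
#' @param group optional grouping column name.
#' @return a ggplot.
#' @export
plot_energy_levels <- function(data, energy = "d_e_e", group = NULL) {
  stopifnot(energy %in% names(data))
  p <- ggplot2::ggplot(data, ggplot2::aes(y = .data[[energy]])) +
    ggplot2::geom_segment(ggplot2::aes(x = 0.1, xend = 0.9,
                                       yend = .data[[energy]]),
                          linewidth = 0.8) +
    ggplot2::labs(x = NULL, y = "relative energy (kcal/mol)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
  if (!is.null(group)) {
    p <- p + ggplot2::facet_wrap(group)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
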