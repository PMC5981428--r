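#' Plot outcome fractions by forager class
#'
#' Stacked bars of the unsuccessful / naturalized / invader percentages,
#' split by alien foraging efficiency (and optionally further groups).
#'
#' @param results A trial table from [run_design()].
#' @param by Additional faceting column name (e.g. `"mortality"`).
#' @return A ggplot object.
#' @export
plot_outcomes <- function(results, by = NULL) {
  d <- dplyr::filter(results, .data$outcome != "gap")
  d$forager <- ifelse(d$alien_efficiency > 1, "efficient", "average")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$forager,
                                       fill = .data$outcome)) +
    ggplot2::geom_bar(position = "fill") +
    ggplot2::scale_y_continuous(labels = function(x) 100 * x) +
    ggplot2::labs(x = "alien forager class", y = "% of introductions",
                  fill = "outcome") +
    ggplot2::theme_minimal()
  if (!is.null(by)) p <- p + ggplot2::facet_wrap(by)
  p
}

#' Plot effects of introductions on native species
#'
#' Box plots of the normalized effect measures, split by alien foraging
#' efficiency.
#'
#' @param results A trial table from [run_design()].
#' @param effects Effect columns to show.
#' @return A ggplot object.
#' @export
plot_effects <- function(results,
                         effects = c("eff_pol_persistence",
                                     "eff_pol_density", "eff_pl_density",
                                     "eff_rewards")) {
  d <- dplyr::filter(results, .data$outcome != "gap")
  d$forager <- ifelse(d$alien_efficiency > 1, "efficient", "average")
  long <- tidyr::pivot_longer(
    d[, c("forager", effects)],
    dplyr::all_of(effects),
    names_to = "response", values_to = "effect"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$response, y = .data$effect,
                                     fill = .data$forager)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "normalized effect E") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.invasion_tree <- function(object, ...) {
  d <- dplyr::filter(object$importance, .data$importance > 0)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$importance,
    y = stats::reorder(.data$predictor, .data$importance)
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "share of split improvement (%)", y = NULL,
      title = sprintf("%s (CV R² = %.2f)", object$response,
                      object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.community_trajectory <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$density,
                                  group = interaction(.data$guild,
                                                      .data$species),
                                  colour = .data$guild)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::labs(x = "time", y = "density") +
    ggplot2::theme_minimal()
}
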