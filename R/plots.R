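#' Plot pulldown observable time courses
#'
#' Time courses of the complex stoichiometry observables, one panel per
#' pulldown, mirroring the layout of published SWATH-MS stoichiometry
#' figures.
#'
#' @param object An `lps_trajectory`.
#' @param observables Observable mapping; defaults to the network's.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lps_trajectory
#' @export
autoplot.lps_trajectory <- function(object, observables = NULL, ...) {
  obs <- observe(object, observables)
  ggplot2::ggplot(obs, ggplot2::aes(
    x = .data$time_min, y = .data$amount_au,
    colour = .data$component
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$pulldown)) +
    ggplot2::labs(
      x = "Time (min)", y = "Amount (A.U.)",
      colour = "Component"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a component distribution report
#'
#' Stacked shares of each component in the Myddosome and the
#' TIRAP-independent MyD88 complex.
#'
#' @param report Output of [complex_distribution()].
#' @return A ggplot object.
#' @export
plot_distribution <- function(report) {
  long <- tidyr::pivot_longer(report,
    c("pct_myddosome", "pct_independent"),
    names_to = "complex", values_to = "pct"
  ) |>
    dplyr::mutate(complex = dplyr::recode(.data$complex,
      pct_myddosome = "Myddosome",
      pct_independent = "TIRAP-independent"
    ))
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$component, y = .data$pct,
    fill = .data$complex
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% of initial amount", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot component:TIRAP stoichiometry ratios
#'
#' @param ratios Output of [stoichiometry_ratios()].
#' @return A ggplot object.
#' @export
plot_stoichiometry_ratios <- function(ratios) {
  ggplot2::ggplot(ratios, ggplot2::aes(
    x = .data$component, y = .data$ratio_to_tirap,
    fill = factor(.data$time_min)
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = NULL, y = "Ratio to TIRAP in the Myddosome",
      fill = "Time (min)"
    ) +
    ggplot2::theme_minimal()
}
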