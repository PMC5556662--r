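#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot age-standardised incidence across the algorithm grid
#'
#' Bar chart of the age-standardised cumulative incidence per 100,000 for
#' every algorithm, faceted by site — the at-a-glance view of how lookback
#' length, confirmation length and confirmatory-event definition move the
#' estimates. Optionally overlays a registry benchmark as a horizontal
#' reference line per site.
#'
#' @param object An `incidence_result` tibble (see [stratified_results()]).
#' @param benchmark Optional benchmark tibble (`site`, `sex`, `state`,
#'   `aci`); its national (`sex = "ALL"`, `state = "ALL"`) rows are drawn.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.incidence_result <- function(object, benchmark = NULL, ...) {
  dat <- object |>
    dplyr::filter(.data$stratum_type == "overall") |>
    dplyr::mutate(algorithm_label = factor(
      .data$algorithm_label,
      levels = names(algorithm_grid())
    ))
  p <- ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$algorithm_label, y = .data$aci)
  ) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$site), scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = "age-standardised cumulative incidence / 100,000",
      title = "Incidence estimates across the case-finding algorithm grid"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
  if (!is.null(benchmark)) {
    ref <- benchmark |>
      dplyr::filter(.data$sex == "ALL", .data$state == "ALL")
    p <- p + ggplot2::geom_hline(
      data = ref,
      ggplot2::aes(yintercept = .data$aci),
      linetype = "dashed", colour = "firebrick"
    )
  }
  p
}

#' Plot claims-based versus registry incidence
#'
#' Scatter of claims-based against registry age-standardised rates across
#' the compared strata with the identity line; points off the diagonal are
#' strata where the algorithm over- or underestimates the registry rate.
#'
#' @param object A `benchmark_comparison` tibble (see
#'   [compare_benchmark()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.benchmark_comparison <- function(object, ...) {
  ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$registry_aci, y = .data$claims_aci,
                 colour = .data$site)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "registry ACI / 100,000", y = "claims-based ACI / 100,000",
      title = "Claims-based vs registry incidence"
    ) +
    ggplot2::theme_minimal()
}
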