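#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot enrichment factors against particle diameter
#'
#' One panel per homolog: the selected mean EF per size fraction with its
#' 95% CI on log-log axes, coloured by estimation method.
#'
#' @param object An [ef_fit()] object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ef_fit
#' @export
autoplot.ef_fit <- function(object, ...) {
  d <- object$records %>%
    filter(!is.na(.data$ef), !is.na(.data$dp_um))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$dp_um, y = .data$ef,
                                  colour = .data$method)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0.05, na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~homolog) +
    ggplot2::labs(x = expression(d[p] ~ (mu * m)),
                  y = "Enrichment factor",
                  colour = "Method") +
    ggplot2::theme_minimal()
}

#' Map a gridded flux field
#'
#' Tile map of a per-cell field (one facet per species if present), on the
#' grid's lon/lat centres.
#'
#' @param field Tibble with `cell`, `value` and optionally `species`.
#' @param grid A [grid_spec()].
#' @param trans Scale transformation for the fill (default `"log10"` for
#'   positive fields, use `"identity"` for signed difference fields).
#' @return A ggplot object.
#' @export
plot_flux_field <- function(field, grid, trans = "log10") {
  d <- field %>%
    left_join(grid$cells %>% select("cell", "lat", "lon"), by = "cell")
  if (trans == "log10") d <- d %>% filter(.data$value > 0)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$lon, y = .data$lat,
                                       fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(trans = trans) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = "Flux") +
    ggplot2::theme_minimal()
  if ("species" %in% names(d)) p <- p + ggplot2::facet_wrap(~species)
  p
}

#' Plot scenario totals
#'
#' Emission and deposition totals per species with low-high scenario
#' ranges.
#'
#' @param object A [run_scenarios()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scenario_set
#' @export
autoplot.scenario_set <- function(object, ...) {
  d <- object$table %>%
    filter(grepl("_t_yr$", .data$metric)) %>%
    tidyr::pivot_wider(names_from = "scenario", values_from = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$species, y = .data$mean,
                                  fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$low,
                                        ymax = .data$high),
                           position = ggplot2::position_dodge(width = 0.9),
                           width = 0.2) +
    ggplot2::labs(x = NULL, y = expression(t ~ yr^-1), fill = NULL) +
    ggplot2::theme_minimal()
}
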