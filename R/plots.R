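#' Plot a near-wall speed map
#'
#' Raster of the near-wall speed over the tooth surface with the
#' peri-bracket region boundaries overlaid; the appliance footprint is
#' blank.
#'
#' @param object A `surface_speed_map`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.surface_speed_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x_mm, .data$y_mm)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$speed_m_s)) +
    ggplot2::geom_point(data = dplyr::filter(object, !is.na(.data$site)),
                        ggplot2::aes(colour = .data$site), size = 0.2,
                        alpha = 0.4) +
    ggplot2::scale_fill_viridis_c(name = "speed (m/s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "mesio-distal (mm)", y = "occluso-gingival (mm)",
                  colour = "site") +
    ggplot2::theme_minimal()
}

#' Plot per-site flow metrics
#'
#' Bar chart of the regional average speed, low-velocity area and vortex
#' area per peri-bracket site and direction.
#'
#' @param object A `region_metrics` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.region_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              c("avg_speed_m_s", "low_velocity_area_mm2",
                                "vortex_area_mm2"),
                              names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$site, .data$value,
                                     fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot longitudinal cohort summaries
#'
#' Mean +/- SD of log10 CFU per site over the three visits.
#'
#' @param records Patient-level clinical records.
#' @return A ggplot object.
#' @export
plot_cohort_cfu <- function(records) {
  sm <- summarize_sites(records, "log10_cfu")
  ggplot2::ggplot(sm, ggplot2::aes(.data$timepoint, .data$mean,
                                   group = .data$site,
                                   colour = .data$site)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.1) +
    ggplot2::labs(x = NULL, y = "log10 CFU") +
    ggplot2::theme_minimal()
}
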