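#' Plot a spatial concentration field
#'
#' Tile map of a per-receptor summary (for example a long-term mean from
#' [field_summary()]) on a regular receptor grid, with road segments
#' overlaid.
#'
#' @param summary A tibble with `x_m`, `y_m` and the value column.
#' @param roads Optional road table from [road_segments()] to overlay.
#' @param value Name of the value column (default `"mean_conc"`).
#' @return A ggplot object.
#' @export
plot_concentration_field <- function(summary, roads = NULL,
                                     value = "mean_conc") {
  p <- ggplot2::ggplot(
    summary,
    ggplot2::aes(x = .data$x_m, y = .data$y_m, fill = .data[[value]])
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = value) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "easting (m)", y = "northing (m)")
  if (!is.null(roads)) {
    p <- p + ggplot2::geom_segment(
      data = roads,
      ggplot2::aes(
        x = .data$x1_m, y = .data$y1_m, xend = .data$x2_m, yend = .data$y2_m
      ),
      inherit.aes = FALSE, linewidth = 1, colour = "grey20"
    )
  }
  p
}

#' Plot a daily concentration series with running means
#'
#' Daily means as points with trailing 5-day and 30-day running-mean
#' lines, faceted by receptor when more than one is present.
#'
#' @param daily Output of [daily_average()] (columns `date`,
#'   `receptor_id`, `conc`).
#' @param windows Running-mean window lengths in days.
#' @return A ggplot object.
#' @export
plot_daily_series <- function(daily, windows = c(5, 30)) {
  dd <- daily |>
    group_by(.data$receptor_id) |>
    arrange(.data$date, .by_group = TRUE)
  for (w in windows) {
    dd <- mutate(dd, "rm{w}" := running_mean(.data$conc, w))
  }
  dd <- ungroup(dd)
  long <- tidyr::pivot_longer(
    dd,
    cols = dplyr::starts_with("rm"),
    names_to = "window", names_prefix = "rm", values_to = "rm"
  )
  long$window <- paste0(long$window, "-day")
  p <- ggplot2::ggplot(dd, ggplot2::aes(x = .data$date)) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$conc),
      size = 0.6, alpha = 0.5
    ) +
    ggplot2::geom_line(
      data = long,
      ggplot2::aes(y = .data$rm, colour = .data$window),
      na.rm = TRUE
    ) +
    ggplot2::labs(x = NULL, y = "daily mean concentration", colour = NULL)
  if (length(unique(dd$receptor_id)) > 1) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$receptor_id))
  }
  p
}
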