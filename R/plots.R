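#' Figure builders
#'
#' ggplot2 views of the pipeline's result tables: latitude profiles of
#' gamma/mean-ES per band (with ocean area), depth profiles per 100-m
#' interval (log-scaled effort with logarithmic trends), and per-cell maps
#' in centroid space.
#'
#' @name plots
NULL

#' Latitudinal band profile plot
#'
#' @param bands A [band_diversity()] table.
#' @param measure Column to plot (`"gamma"`, `"mean_es"`, `"n_records"`).
#' @param trend Overlay an order-6 polynomial trend line.
#' @return A ggplot object.
#' @export
plot_latitude_profile <- function(bands, measure = "mean_es", trend = TRUE) {
  df <- dplyr::filter(bands, !is.na(.data[[measure]]))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$lat_mid, y = .data[[measure]], colour = .data$stratum
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(
      x = "Latitude (deg N, 5-degree band midpoint)", y = measure,
      colour = "stratum"
    ) +
    ggplot2::theme_minimal()
  if (measure == "mean_es" && "se_es" %in% names(df)) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data[[measure]] - .data$se_es,
        ymax = .data[[measure]] + .data$se_es
      ),
      width = 1
    )
  }
  if (trend) {
    for (st in unique(df$stratum)) {
      sub <- df[df$stratum == st, ]
      if (length(unique(sub$lat_mid)) >= 7) {
        tf <- fit_trend(sub$lat_mid, sub[[measure]], "polynomial", 6)
        xs <- seq(min(sub$lat_mid), max(sub$lat_mid), length.out = 200)
        p <- p + ggplot2::geom_line(
          data = tibble::tibble(
            lat_mid = xs, y = tf$predict(xs), stratum = st
          ),
          ggplot2::aes(x = .data$lat_mid, y = .data$y, colour = .data$stratum)
        )
      }
    }
  }
  p
}

#' Bathymetric profile plot
#'
#' @param depth A [depth_profile()] table.
#' @param measure Column to plot (`"gamma"`, `"mean_alpha"`, `"mean_es"`,
#'   `"n_records"`).
#' @param trend Overlay the logarithmic trend `y = a + b ln(depth)`.
#' @return A ggplot object.
#' @export
plot_depth_profile <- function(depth, measure = "gamma", trend = TRUE) {
  df <- dplyr::filter(depth, !is.na(.data[[measure]]))
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$depth_mid, y = .data[[measure]]
  )) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Depth (m, 100-m interval midpoint)", y = measure) +
    ggplot2::theme_minimal()
  if (trend && nrow(df) >= 3) {
    tf <- fit_trend(df$depth_mid, df[[measure]], "logarithmic")
    xs <- seq(min(df$depth_mid), max(df$depth_mid), length.out = 200)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(depth_mid = xs, y = tf$predict(xs)),
      ggplot2::aes(x = .data$depth_mid, y = .data$y)
    )
  }
  p
}

#' Per-cell map plot
#'
#' Cell centroids coloured by a diversity measure (a light-weight stand-in
#' for polygon cartography; polygons are exported via
#' [write_grid_geojson()]).
#'
#' @param cells A [cell_diversity()] table built with `grid =`.
#' @param measure Column to plot (`"alpha"`, `"es"`, `"n_records"`).
#' @param stratum Stratum to display.
#' @return A ggplot object.
#' @export
plot_cell_map <- function(cells, measure = "es", stratum = "all") {
  df <- cells |>
    dplyr::filter(.data$stratum == !!stratum, !is.na(.data[[measure]]))
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$centroid_lon, y = .data$centroid_lat,
    colour = .data[[measure]]
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "Longitude (deg E)", y = "Latitude (deg N)") +
    ggplot2::theme_minimal()
}
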