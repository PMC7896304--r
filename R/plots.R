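#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot one gridded layer
#'
#' Tile map of any per-cell quantity (climate variable, richness, ensemble
#' fraction) on the model grid, with north (row 0) at the top.
#'
#' @param data Tibble with `row`, `col` and the value column.
#' @param value Column to map to fill (tidy-eval).
#' @return A ggplot object.
#' @export
plot_grid_layer <- function(data, value) {
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data$col, y = -.data$row, fill = {{ value }}
  )) +
    ggplot2::geom_tile() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ensemble_projection <- function(object, ...) {
  plot_grid_layer(object, .data$fraction) +
    ggplot2::labs(fill = "occupancy\nfraction")
}

#' @exportS3Method ggplot2::autoplot
autoplot.covariate_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(
    x = .data$x, y = .data$mean_pct_change
  )) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(
      method = "glm", formula = y ~ x, se = TRUE, colour = "steelblue"
    ) +
    ggplot2::labs(
      x = switch(object$covariate,
        governance = "governance score",
        gdp = "log GDP per capita",
        co2 = "log CO2 per capita"
      ),
      y = "mean % richness change"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-border statistics
#'
#' Bar chart of a border-level count or fraction, barrier borders
#' highlighted.
#'
#' @param border_stats A borders tibble with the statistic column.
#' @param stat Column to plot (tidy-eval).
#' @return A ggplot object.
#' @export
plot_border_stats <- function(border_stats, stat) {
  dat <- border_stats |>
    mutate(border = sprintf(
      "%d-%d", .data$country_a, .data$country_b
    ))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$border, {{ stat }}),
    y = {{ stat }}, fill = .data$barrier
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "grey60", `TRUE` = "firebrick")
    ) +
    ggplot2::labs(x = "border (country pair)") +
    ggplot2::theme_minimal()
}
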