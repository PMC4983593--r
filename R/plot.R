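#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Long tibble of cell centers and values, for plotting.
grid_to_tibble <- function(g) {
  tibble::tibble(
    lon = rep(col_center_lon(g, seq_len(g$ncols)), each = g$nrows),
    lat = rep(row_center_lat(g, seq_len(g$nrows)), times = g$ncols),
    value = as.vector(g$values)
  )
}

#' Plot a grid
#'
#' Continuous grids are drawn with a viridis fill; categorical grids (land
#' classes, corridor codes) with a discrete fill. Nodata cells are blank.
#'
#' @param object An [nc_grid].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nc_grid <- function(object, ...) {
  df <- grid_to_tibble(object)
  df <- df[!is.na(df$value), , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$lon, .data$lat)) +
    ggplot2::coord_fixed(1 / cos(mean(df$lat) * pi / 180)) +
    ggplot2::labs(x = "Longitude", y = "Latitude") +
    ggplot2::theme_minimal()
  if (object$kind == "categorical") {
    p + ggplot2::geom_raster(ggplot2::aes(fill = factor(.data$value))) +
      ggplot2::labs(fill = "class")
  } else {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(fill = "suitability")
  }
}

#' Plot a quantification report
#'
#' Bar chart of per-class area; with `per_tile = TRUE`, a tile-by-class
#' heat map of areas.
#'
#' @param object An `nc_quant` from [quantify_classes()].
#' @param per_tile Plot the per-tile breakdown instead of the global totals.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nc_quant <- function(object, per_tile = FALSE, ...) {
  if (per_tile) {
    if (is.null(object$tiles)) stop("report has no tile layout", call. = FALSE)
    ggplot2::ggplot(object$tiles,
                    ggplot2::aes(factor(.data$tile), factor(.data$class),
                                 fill = .data$area_km2)) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_viridis_c() +
      ggplot2::labs(x = "tile", y = "class", fill = "km²") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$classes,
                    ggplot2::aes(factor(.data$class), .data$area_km2)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = "class", y = "area (km²)") +
      ggplot2::theme_minimal()
  }
}
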