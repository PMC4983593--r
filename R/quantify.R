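#' Authalic Earth radius in kilometres
#'
#' Radius of the sphere with the same surface area as the Earth ellipsoid;
#' the default radius for all spherical area formulas in the package.
#' @export
EARTH_RADIUS_KM <- 6371.0072

#' Spherical area of the cells in one grid row
#'
#' On a sphere of radius \eqn{R}, a cell bounded by latitudes
#' \eqn{\phi_{bot} < \phi_{top}} and spanning \eqn{\Delta\lambda} radians of
#' longitude has exact area
#' \deqn{R^2 \, \Delta\lambda \, (\sin\phi_{top} - \sin\phi_{bot}),}
#' which accounts for the curvature of the Earth's surface: cells shrink
#' towards the poles although their angular size is constant. All cells in one
#' grid row share the same latitude band and hence the same area.
#'
#' @param grid An [nc_grid] (or header-like list).
#' @param row 1-based row index or vector of indices; row 1 is the
#'   northernmost.
#' @param radius_km Sphere radius in km; defaults to the authalic radius
#'   [EARTH_RADIUS_KM].
#' @return Cell area(s) in km², one per requested row.
#' @export
cell_band_area <- function(grid, row, radius_km = EARTH_RADIUS_KM) {
  if (any(row < 1 | row > grid$nrows))
    stop("row index out of range 1..", grid$nrows, call. = FALSE)
  d2r <- pi / 180
  phi_top <- row_lat_top(grid, row) * d2r
  phi_bot <- row_lat_bottom(grid, row) * d2r
  radius_km^2 * (grid$cellsize * d2r) * (sin(phi_top) - sin(phi_bot))
}

# Mean cell width (zonal, at each row's mid-latitude) and constant cell
# height (meridional), in metres.
mean_cell_dims_m <- function(grid, radius_km = EARTH_RADIUS_KM) {
  d2r <- pi / 180
  r_m <- radius_km * 1000
  phi_mid <- row_center_lat(grid, seq_len(grid$nrows)) * d2r
  width <- mean(r_m * grid$cellsize * d2r * cos(phi_mid))
  height <- r_m * grid$cellsize * d2r
  c(width_m = width, height_m = height)
}

#' Define a tile layout
#'
#' Splits a raster extent into an `n_rows x n_cols` grid of equal rectangular
#' tiles (at most 225), numbered row-major from the top-left (tile 1 is the
#' north-west corner).
#'
#' @param n_rows,n_cols Positive integers with `n_rows * n_cols <= 225`.
#' @return A `tile_layout` list.
#' @export
tile_layout <- function(n_rows, n_cols) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("tile counts must be positive", call. = FALSE)
  if (n_rows * n_cols > 225L)
    stop("at most 225 tiles are supported (got ", n_rows * n_cols, ")", call. = FALSE)
  structure(list(n_rows = n_rows, n_cols = n_cols), class = "tile_layout")
}

#' Tile bounds for a grid extent
#'
#' @param grid An [nc_grid] or header-like list.
#' @param layout A [tile_layout].
#' @return A tibble with one row per tile: `tile` (row-major from top-left),
#'   `west`, `south`, `east`, `north` in decimal degrees. The tiles exactly
#'   partition the grid's bounding box.
#' @export
tile_bounds <- function(grid, layout) {
  stopifnot(inherits(layout, "tile_layout"))
  ext <- grid_extent(grid)
  dx <- (ext["east"] - ext["west"]) / layout$n_cols
  dy <- (ext["north"] - ext["south"]) / layout$n_rows
  idx <- seq_len(layout$n_rows * layout$n_cols)
  tr <- (idx - 1L) %/% layout$n_cols   # 0-based tile row from top
  tc <- (idx - 1L) %% layout$n_cols    # 0-based tile col from west
  tibble::tibble(
    tile = idx,
    west = unname(ext["west"] + tc * dx),
    south = unname(ext["north"] - (tr + 1) * dy),
    east = unname(ext["west"] + (tc + 1) * dx),
    north = unname(ext["north"] - tr * dy)
  )
}

# Tile index (row-major from top-left) for each cell of `grid`, assigned by
# cell center; centers exactly on an internal tile boundary go to the
# larger-index (south/east) tile. Returns an nrows x ncols integer matrix.
cell_tile_index <- function(grid, layout) {
  ext <- grid_extent(grid)
  dx <- (ext["east"] - ext["west"]) / layout$n_cols
  dy <- (ext["north"] - ext["south"]) / layout$n_rows
  cx <- col_center_lon(grid, seq_len(grid$ncols))
  cy <- row_center_lat(grid, seq_len(grid$nrows))
  tc <- pmin(floor((cx - ext["west"]) / dx), layout$n_cols - 1L)
  tr <- pmin(floor((ext["north"] - cy) / dy), layout$n_rows - 1L)
  outer(tr, tc, function(r, c) as.integer(r * layout$n_cols + c + 1L))
}

#' Quantify class counts and areas of a categorical raster
#'
#' Scenario-8 analysis: per-class cell counts and km² areas for the whole
#' raster and, optionally, per tile of a [tile_layout]. Areas use the exact
#' per-latitude-band spherical formula by default ([cell_band_area]); the
#' `"average"` compatibility mode instead multiplies class counts by the
#' raster-wide mean cell area. Nodata cells are excluded from class rows and
#' reported separately.
#'
#' @param grid A categorical [nc_grid].
#' @param layout Optional [tile_layout]; tiles partition the raster extent and
#'   every cell belongs to exactly one tile (by cell center).
#' @param area_mode `"band"` (exact per-row areas, default) or `"average"`
#'   (count times mean cell area).
#' @param radius_km Sphere radius in km, default [EARTH_RADIUS_KM].
#' @return An object of class `nc_quant` with elements
#'   \describe{
#'     \item{classes}{tibble: `class`, `count`, `area_km2` (global)}
#'     \item{tiles}{tibble: `tile`, `class`, `count`, `area_km2` (if a layout
#'       was given)}
#'     \item{tile_bounds}{tibble of tile rectangles}
#'     \item{totals}{named list: total count, total area, nodata count}
#'     \item{cell_dims_m}{mean cell width/height in metres}
#'   }
#' @export
quantify_classes <- function(grid, layout = NULL,
                             area_mode = c("band", "average"),
                             radius_km = EARTH_RADIUS_KM) {
  stopifnot(inherits(grid, "nc_grid"))
  if (grid$kind != "categorical")
    stop("quantification requires a categorical raster", call. = FALSE)
  area_mode <- match.arg(area_mode)

  band <- cell_band_area(grid, seq_len(grid$nrows), radius_km = radius_km)
  n_cells_total <- sum(!is.na(grid$values))
  mean_cell_area <- sum(band * grid$ncols) / (grid$nrows * grid$ncols)

  cells <- tibble::tibble(
    row = rep(seq_len(grid$nrows), times = grid$ncols),
    class = as.vector(grid$values)
  )
  cells$area <- if (area_mode == "band") band[cells$row] else mean_cell_area
  if (!is.null(layout)) {
    stopifnot(inherits(layout, "tile_layout"))
    cells$tile <- as.vector(cell_tile_index(grid, layout))
  }
  cells <- cells[!is.na(cells$class), , drop = FALSE]

  classes <- cells |>
    dplyr::group_by(class) |>
    dplyr::summarise(count = dplyr::n(), area_km2 = sum(area), .groups = "drop") |>
    dplyr::arrange(class)

  tiles <- NULL
  tb <- NULL
  if (!is.null(layout)) {
    tiles <- cells |>
      dplyr::group_by(tile, class) |>
      dplyr::summarise(count = dplyr::n(), area_km2 = sum(area), .groups = "drop") |>
      tidyr::complete(tile = seq_len(layout$n_rows * layout$n_cols),
                      class = classes$class,
                      fill = list(count = 0L, area_km2 = 0)) |>
      dplyr::arrange(tile, class)
    tb <- tile_bounds(grid, layout)
  }

  structure(
    list(classes = classes, tiles = tiles, tile_bounds = tb,
         totals = list(count = n_cells_total,
                       area_km2 = sum(classes$area_km2),
                       nodata = sum(is.na(grid$values))),
         cell_dims_m = mean_cell_dims_m(grid, radius_km = radius_km),
         area_mode = area_mode),
    class = "nc_quant"
  )
}

#' @export
print.nc_quant <- function(x, ...) {
  cat(sprintf("<nc_quant> %d classes, %d cells, %.6g km2 (%s-area mode)\n",
              nrow(x$classes), x$totals$count, x$totals$area_km2, x$area_mode))
  cat(sprintf("  mean cell: %.0f m x %.0f m; %d nodata cells\n",
              x$cell_dims_m["width_m"], x$cell_dims_m["height_m"], x$totals$nodata))
  if (!is.null(x$tiles))
    cat(sprintf("  tiles: %d\n", max(x$tiles$tile)))
  print(x$classes)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a quantification report
#'
#' @param x An `nc_quant` from [quantify_classes()].
#' @param per_tile If `TRUE` and a tile layout was used, return the long
#'   per-tile table instead of the global per-class table.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.nc_quant <- function(x, per_tile = FALSE, ...) {
  if (per_tile) {
    if (is.null(x$tiles)) stop("report has no tile layout", call. = FALSE)
    return(x$tiles)
  }
  x$classes
}

#' One-row summary of a quantification report
#'
#' @param x An `nc_quant`.
#' @param ... Unused.
#' @return A one-row tibble with class/cell/area totals and mean cell
#'   dimensions in metres.
#' @export
glance.nc_quant <- function(x, ...) {
  tibble::tibble(
    n_classes = nrow(x$classes),
    n_cells = x$totals$count,
    n_nodata = x$totals$nodata,
    total_area_km2 = x$totals$area_km2,
    cell_width_m = unname(x$cell_dims_m["width_m"]),
    cell_height_m = unname(x$cell_dims_m["height_m"]),
    n_tiles = if (is.null(x$tiles)) NA_integer_ else max(x$tiles$tile)
  )
}

#' Summarise suitability-class areas of a merged land-class model
#'
#' Report-level arithmetic over a per-class area table containing the three
#' synthetic suitability classes `highest+1` (baseline only), `highest+2`
#' (both climates) and `highest+3` (projected only): the baseline-suitable
#' area (+1 and +2), the projected-suitable area (+2 and +3), their sum, the
#' grand total over all classes, and the percentage decline from baseline to
#' projected suitability.
#'
#' @param classes A data frame with columns `class` and `area_km2` (e.g.
#'   `tidy()` of an [quantify_classes()] report, or a published table).
#' @param highest The LCM's highest original class code (synthetic classes sit
#'   at `highest + 1:3`).
#' @return A one-row tibble with columns `baseline_only_km2`, `both_km2`,
#'   `projected_only_km2`, `baseline_km2`, `projected_km2`,
#'   `suitability_km2`, `total_km2`, `decline_pct`.
#' @export
corridor_summary <- function(classes, highest) {
  stopifnot(all(c("class", "area_km2") %in% names(classes)))
  area_of <- function(k) {
    a <- classes$area_km2[classes$class == k]
    if (length(a)) sum(a) else 0
  }
  b1 <- area_of(highest + 1); b2 <- area_of(highest + 2); b3 <- area_of(highest + 3)
  baseline <- b1 + b2
  projected <- b2 + b3
  tibble::tibble(
    baseline_only_km2 = b1, both_km2 = b2, projected_only_km2 = b3,
    baseline_km2 = baseline, projected_km2 = projected,
    suitability_km2 = b1 + b2 + b3,
    total_km2 = sum(classes$area_km2),
    decline_pct = if (baseline > 0) 100 * (baseline - projected) / baseline else NA_real_
  )
}

#' Percentage decline between two areas
#'
#' @param before,after Areas in the same units.
#' @return `100 * (before - after) / before`.
#' @export
area_decline_pct <- function(before, after) 100 * (before - after) / before
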