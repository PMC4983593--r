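#' Write a quantification report to CSV
#'
#' The canonical report layout: a `#`-prefixed metadata block (area mode, cell
#' dimensions, totals, tile rectangles if any) followed by one row per class
#' with the global cell count, global km² and one km² column per tile, and a
#' closing `total` row equal to the column sums.
#'
#' @param report An `nc_quant` from [quantify_classes()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "nc_quant"))
  wide <- report$classes
  if (!is.null(report$tiles)) {
    tw <- tidyr::pivot_wider(report$tiles[, c("tile", "class", "area_km2")],
                             names_from = "tile", values_from = "area_km2",
                             names_prefix = "tile_")
    wide <- dplyr::left_join(wide, tw, by = "class")
  }
  total <- wide |>
    dplyr::summarise(dplyr::across(-class, sum)) |>
    dplyr::mutate(class = NA_real_, .before = 1)
  body <- dplyr::bind_rows(wide, total)
  body$label <- c(format(wide$class, trim = TRUE), "total")

  meta <- c(
    "# nichecarve quantification report",
    sprintf("# area_mode,%s", report$area_mode),
    sprintf("# cell_width_m,%.6f", report$cell_dims_m["width_m"]),
    sprintf("# cell_height_m,%.6f", report$cell_dims_m["height_m"]),
    sprintf("# total_count,%d", report$totals$count),
    sprintf("# total_area_km2,%.10g", report$totals$area_km2),
    sprintf("# nodata_count,%d", report$totals$nodata)
  )
  if (!is.null(report$tile_bounds)) {
    meta <- c(meta, sprintf("# tile_%d_bounds,%.10g,%.10g,%.10g,%.10g",
                            report$tile_bounds$tile, report$tile_bounds$west,
                            report$tile_bounds$south, report$tile_bounds$east,
                            report$tile_bounds$north))
  }
  cols <- c("label", "count", "area_km2",
            grep("^tile_", names(body), value = TRUE))
  tab <- body[, cols]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' Read back a CSV quantification report
#'
#' Parses a file written by [write_report()] into its class table, per-tile
#' table and totals, so a report round-trips numerically.
#'
#' @param path Path to the CSV report.
#' @return A list with `classes` (tibble `class`, `count`, `area_km2`),
#'   `tiles` (long tibble or `NULL`) and `totals`.
#' @export
read_report <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")]
  tab <- utils::read.csv(text = paste(lines[!startsWith(lines, "#")],
                                      collapse = "\n"),
                         check.names = FALSE)
  data_rows <- tab[tab$label != "total", , drop = FALSE]
  classes <- tibble::tibble(
    class = as.numeric(data_rows$label),
    count = as.integer(data_rows$count),
    area_km2 = as.numeric(data_rows$area_km2)
  )
  tile_cols <- grep("^tile_", names(tab), value = TRUE)
  tiles <- NULL
  if (length(tile_cols)) {
    tiles <- tidyr::pivot_longer(
      cbind(class = classes$class, data_rows[, tile_cols, drop = FALSE]),
      -class, names_to = "tile", values_to = "area_km2")
    tiles$tile <- as.integer(sub("^tile_", "", tiles$tile))
    tiles <- dplyr::arrange(tibble::as_tibble(tiles[, c("tile", "class", "area_km2")]),
                            tile, class)
  }
  get_meta <- function(key) {
    ln <- meta[startsWith(meta, paste0("# ", key, ","))]
    if (!length(ln)) return(NA_real_)
    as.numeric(strsplit(ln[1], ",")[[1]][2])
  }
  list(classes = classes, tiles = tiles,
       totals = list(count = get_meta("total_count"),
                     area_km2 = get_meta("total_area_km2"),
                     nodata = get_meta("nodata_count")))
}

#' Write a tile grid as GeoJSON polygons
#'
#' One rectangular polygon per tile of the layout, with the 1-based tile index
#' (row-major from the top-left) as the `tile` property. The polygons exactly
#' partition the raster's bounding box and mirror the geographic tile
#' coordinates in the CSV report.
#'
#' @param grid An [nc_grid] or header-like list supplying the extent.
#' @param layout A [tile_layout].
#' @param path Output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_tile_geojson <- function(grid, layout, path) {
  tb <- tile_bounds(grid, layout)
  features <- purrr::pmap(tb, function(tile, west, south, east, north) {
    ring <- rbind(c(west, south), c(east, south), c(east, north),
                  c(west, north), c(west, south))
    list(type = "Feature",
         properties = list(tile = tile),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Published area statistics of the Fraser fir case study
#'
#' The worked example distributed with the package: scenario-8 quantification
#' summaries for Fraser fir (*Abies fraseri*) in the southern Appalachians,
#' where a MaxEnt suitability surface was filtered by STATSGO topsoil class 6
#' (loam) and NLCD 2011 forest classes 41/42/43, and merged into the NLCD land
#' class model (highest class 95, so suitability classes land on 96/97/98).
#'
#' @return A list with
#'   \describe{
#'     \item{class_areas}{tibble: per-land-class km² areas under four model
#'       variants (`maxent_km2` = unfiltered, `lc_km2` = land-class filtered,
#'       `soil_km2` = soil filtered, `lc_soil_km2` = both filters)}
#'     \item{tile_areas}{tibble: km² of classes 96/97/98 per tile of a 3x4
#'       layout for the fully filtered model}
#'     \item{thresholds}{list: the two MaxEnt evaluation thresholds whose mean
#'       is the suitability threshold (`lowest_presence`, `p10_training`)}
#'     \item{highest}{the LCM's highest original class (95)}
#'   }
#' @export
fraser_fir_case_study <- function() {
  read_fix <- function(f) {
    tibble::as_tibble(utils::read.csv(
      system.file("extdata", f, package = "nichecarve", mustWork = TRUE)))
  }
  list(class_areas = read_fix("fraser_fir_class_areas.csv"),
       tile_areas = read_fix("fraser_fir_tile_areas.csv"),
       thresholds = list(lowest_presence = 0.088, p10_training = 0.473),
       highest = 95)
}
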