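#' Specify a synthetic fixture dataset
#'
#' Describes a deterministic synthetic landscape from which ENM pairs, feature
#' rasters and a nested land-class model are generated, with known ground
#' truth. The defaults mimic the scale ratios of a 30-arc-second ENM over a
#' 30-m land cover model at toy size: a 40x40 ENM at 0.05 degrees over a
#' 2-degree window in the southern Appalachians, with the LCM refined 5x
#' (200x200 cells). The two niche centers are offset so that thresholding
#' near 0.28 yields non-empty regions of all three corridor codes.
#'
#' @param extent `(west, south, east, north)` in decimal degrees.
#' @param enm_cellsize ENM cell size in degrees.
#' @param lcm_refinement Integer >= 1; LCM cell size = `enm_cellsize /
#'   lcm_refinement`.
#' @param baseline_center,projected_center `(lon, lat)` niche centers.
#' @param niche_radius Gaussian radius (degrees) of the suitability bumps.
#' @param noise_sd Standard deviation of optional Gaussian noise added to the
#'   suitability surfaces (clamped back to `[0, 1]`); 0 disables noise.
#' @param seed Integer seed driving all randomness in the generators.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(extent = c(-84.5, 34.5, -82.5, 36.5),
                         enm_cellsize = 0.05,
                         lcm_refinement = 5L,
                         baseline_center = c(-83.7, 35.3),
                         projected_center = c(-83.3, 35.7),
                         niche_radius = 0.35,
                         noise_sd = 0,
                         seed = 42L) {
  stopifnot(length(extent) == 4, extent[3] > extent[1], extent[4] > extent[2],
            enm_cellsize > 0, lcm_refinement >= 1, niche_radius > 0,
            noise_sd >= 0)
  structure(
    list(extent = as.double(extent), enm_cellsize = as.double(enm_cellsize),
         lcm_refinement = as.integer(lcm_refinement),
         baseline_center = as.double(baseline_center),
         projected_center = as.double(projected_center),
         niche_radius = as.double(niche_radius),
         noise_sd = as.double(noise_sd), seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

# Empty grid over the spec extent at a given cellsize; cell counts are
# rounded from the extent so the grids nest exactly.
blank_grid <- function(spec, cellsize, kind = "continuous") {
  ncols <- round((spec$extent[3] - spec$extent[1]) / cellsize)
  nrows <- round((spec$extent[4] - spec$extent[2]) / cellsize)
  nc_grid(matrix(0, nrows, ncols), xllcorner = spec$extent[1],
          yllcorner = spec$extent[2], cellsize = cellsize, kind = kind)
}

# lon/lat matrices of cell centers for a grid.
center_coords <- function(g) {
  lon <- col_center_lon(g, seq_len(g$ncols))
  lat <- row_center_lat(g, seq_len(g$nrows))
  list(lon = matrix(lon, g$nrows, g$ncols, byrow = TRUE),
       lat = matrix(lat, g$nrows, g$ncols))
}

gaussian_bump <- function(g, center, radius) {
  cc <- center_coords(g)
  d2 <- (cc$lon - center[1])^2 + (cc$lat - center[2])^2
  exp(-d2 / (2 * radius^2))
}

#' Generate a baseline/projected pair of suitability surfaces
#'
#' Each surface is a radial Gaussian bump in `[0, 1]` centred on its niche
#' center (value exactly 1 at the center cell only if a cell center coincides
#' with it; the analytic peak is 1). With distinct centers, thresholding at a
#' mid value yields non-empty baseline-only, overlap and projected-only
#' corridor regions whose geometry is known analytically: a cell is suitable
#' at threshold `t` iff its center lies within `r * sqrt(2 ln(1/t))` degrees
#' of the niche center.
#'
#' @param spec A [fixture_spec].
#' @return A list with continuous [nc_grid]s `baseline` and `projected`.
#' @export
make_enm_pair <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  g <- blank_grid(spec, spec$enm_cellsize, "continuous")
  base <- gaussian_bump(g, spec$baseline_center, spec$niche_radius)
  proj <- gaussian_bump(g, spec$projected_center, spec$niche_radius)
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    base <- pmin(1, pmax(0, base + stats::rnorm(length(base), sd = spec$noise_sd)))
    proj <- pmin(1, pmax(0, proj + stats::rnorm(length(proj), sd = spec$noise_sd)))
  }
  gb <- g; gb$values <- matrix(base, g$nrows, g$ncols)
  gp <- g; gp$values <- matrix(proj, g$nrows, g$ncols)
  list(baseline = gb, projected = gp)
}

#' Generate a synthetic feature raster
#'
#' Categorical features are vertical class bands with exactly known per-class
#' cell counts (emulating a soil-class map); continuous features are a planar
#' west-to-east gradient over `[0, 1]` with a known value at every column.
#'
#' @param spec A [fixture_spec].
#' @param kind `"categorical"` or `"continuous"`.
#' @param n_bands Number of vertical class bands (categorical only); class
#'   codes are `1..n_bands`, band 1 westmost. Columns are split as evenly as
#'   possible.
#' @param applies_to Climate phases the feature applies to.
#' @return An `nc_feature` accepting, by default, every class/the full range
#'   (callers narrow `accepted` to make the filter bite).
#' @export
make_feature <- function(spec, kind = c("categorical", "continuous"),
                         n_bands = 2L, applies_to = c("baseline", "projected")) {
  stopifnot(inherits(spec, "fixture_spec"))
  kind <- match.arg(kind)
  g <- blank_grid(spec, spec$enm_cellsize, kind)
  if (kind == "categorical") {
    band_of_col <- ceiling(seq_len(g$ncols) / (g$ncols / n_bands))
    g$values <- matrix(band_of_col, g$nrows, g$ncols, byrow = TRUE)
    feature_spec(g, "categorical", accepted = seq_len(n_bands),
                 applies_to = applies_to)
  } else {
    grad <- (seq_len(g$ncols) - 0.5) / g$ncols
    g$values <- matrix(grad, g$nrows, g$ncols, byrow = TRUE)
    feature_spec(g, "continuous", accepted = cbind(lo = 0, hi = 1),
                 applies_to = applies_to)
  }
}

#' Generate a synthetic land-class model
#'
#' A categorical raster at `enm_cellsize / lcm_refinement`, nested exactly
#' inside the ENM extent, carrying an NLCD-like class table: water (11),
#' developed (21), barren (31), the three forest classes 41/42/43, shrub
#' (52), grassland (71), pasture (81), woody wetland (90) and emergent
#' wetland (95). Class 95 is always present, so the highest class is 95 by
#' construction and merged suitability classes land on 96/97/98 as in the
#' Fraser fir example. The spatial arrangement is a seeded random mosaic,
#' deterministic for a given `spec`.
#'
#' @param spec A [fixture_spec].
#' @param class_codes Class table to draw from; must include 95.
#' @param forest_weight Sampling weight given to each forest class (41/42/43)
#'   relative to weight 1 for the others, so filters on forest classes have
#'   plenty of area to act on.
#' @return A categorical [nc_grid].
#' @export
make_lcm <- function(spec, class_codes = c(11, 21, 31, 41, 42, 43, 52, 71, 81, 90, 95),
                     forest_weight = 3) {
  stopifnot(inherits(spec, "fixture_spec"), 95 %in% class_codes)
  g <- blank_grid(spec, spec$enm_cellsize / spec$lcm_refinement, "categorical")
  w <- ifelse(class_codes %in% c(41, 42, 43), forest_weight, 1)
  set.seed(spec$seed)
  vals <- sample(class_codes, g$nrows * g$ncols, replace = TRUE, prob = w / sum(w))
  vals[1] <- 95  # guarantee the highest class is present
  g$values <- matrix(vals, g$nrows, g$ncols)
  g
}

#' Write a complete synthetic scenario dataset to disk
#'
#' Generates the ENM pair, a categorical soil-like feature and the LCM for a
#' [fixture_spec] and writes them as ESRI ASCII grids, plus a ready-to-run
#' YAML configuration for the scenario-7 pipeline.
#'
#' @param spec A [fixture_spec].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
write_fixture_set <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  enms <- make_enm_pair(spec)
  soil <- make_feature(spec, "categorical")
  lcm <- make_lcm(spec)
  paths <- list(
    baseline = file.path(dir, "baseline_enm.asc"),
    projected = file.path(dir, "projected_enm.asc"),
    soil = file.path(dir, "soil_feature.asc"),
    lcm = file.path(dir, "lcm.asc"),
    config = file.path(dir, "scenario7.yml")
  )
  write_ascii_grid(enms$baseline, paths$baseline)
  write_ascii_grid(enms$projected, paths$projected)
  write_ascii_grid(soil$grid, paths$soil)
  write_ascii_grid(lcm, paths$lcm)
  config <- list(
    baseline = "baseline_enm.asc",
    projected = "projected_enm.asc",
    features = list(list(path = "soil_feature.asc", kind = "categorical",
                         accepted = c(1, 2),
                         applies_to = c("baseline", "projected"))),
    lcm = list(path = "lcm.asc", valid_classes = c(41, 42, 43)),
    thresholds = list(baseline = 0.2805, projected = 0.2805)
  )
  yaml::write_yaml(config, paths$config)
  invisible(paths)
}
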