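# Small builders and independent oracles shared across the test files.

# A grid from a matrix with 1-degree cells anchored at (0, 0).
toy_grid <- function(m, kind = "continuous", cellsize = 1,
                     xll = 0, yll = 0, nodata = -9999) {
  nc_grid(as.matrix(m), xllcorner = xll, yllcorner = yll,
          cellsize = cellsize, nodata = nodata, kind = kind)
}

# A mask over the geometry of `g` with the given logical matrix.
toy_mask <- function(g, cells, phase = "baseline") {
  apply_threshold(
    nc_grid(ifelse(cells, 1, 0), g$xllcorner, g$yllcorner, g$cellsize),
    0.5, phase)
}

# Independent cell area oracle: 2-D midpoint rule over an n x n subdivision
# of the cell bounded by latitudes [phi_bot, phi_top] (degrees) and spanning
# `cellsize` degrees of longitude, on a sphere of radius R km.
midpoint_cell_area <- function(phi_bot, phi_top, cellsize,
                               R = EARTH_RADIUS_KM, n = 100) {
  d2r <- pi / 180
  dphi <- (phi_top - phi_bot) / n
  dlam <- cellsize / n
  phi_mid <- (phi_bot + (seq_len(n) - 0.5) * dphi) * d2r
  sum(outer(R^2 * cos(phi_mid) * (dphi * d2r), rep(dlam * d2r, n)))
}

# Brute-force per-class tally of a categorical grid: explicit loop over every
# cell, areas accumulated from the row's band area.
brute_tally <- function(g) {
  acc <- new.env()
  for (i in seq_len(g$nrows)) {
    band <- cell_band_area(g, i)
    for (j in seq_len(g$ncols)) {
      v <- g$values[i, j]
      if (is.na(v)) next
      key <- as.character(v)
      cur <- if (is.null(acc[[key]])) c(0, 0) else acc[[key]]
      acc[[key]] <- cur + c(1, band)
    }
  }
  ks <- sort(as.numeric(ls(acc)))
  tibble::tibble(
    class = ks,
    count = as.integer(unname(vapply(as.character(ks), function(k) acc[[k]][1], double(1)))),
    area_km2 = unname(vapply(as.character(ks), function(k) acc[[k]][2], double(1)))
  )
}

# A seeded random categorical grid.
random_class_grid <- function(seed, nrows = 20, ncols = 20, classes = c(1, 2, 3, 7),
                              cellsize = 0.05, yll = 35, xll = -84,
                              p_na = 0) {
  set.seed(seed)
  v <- sample(classes, nrows * ncols, replace = TRUE)
  if (p_na > 0) v[stats::runif(length(v)) < p_na] <- NA
  nc_grid(matrix(v, nrows, ncols), xll, yll, cellsize, kind = "categorical")
}
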