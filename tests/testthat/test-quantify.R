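test_that("latitude-band cell areas match analytic and numeric references", {
  # one row of two square 180-degree cells covers the whole sphere
  sphere <- nc_grid(matrix(0, 1, 2), xllcorner = -180, yllcorner = -90,
                    cellsize = 180)
  expect_equal(2 * cell_band_area(sphere, 1), 4 * pi * EARTH_RADIUS_KM^2)

  # a degenerate band (zero angular height) has zero area
  flat <- list(nrows = 1L, ncols = 1L, xllcorner = 0, yllcorner = 10, cellsize = 0)
  expect_equal(cell_band_area(flat, 1), 0)

  # mid-latitude cells agree with the 2-D midpoint-rule oracle
  g <- toy_grid(matrix(0, 6, 1), cellsize = 0.25, yll = 35.25, xll = -84)
  for (i in 1:6) {
    oracle <- midpoint_cell_area(35.25 + (6 - i) * 0.25,
                                 35.25 + (6 - i + 1) * 0.25, 0.25)
    expect_equal(cell_band_area(g, i), oracle, tolerance = 1e-6)
  }

  expect_error(cell_band_area(g, 7), "out of range")
  expect_error(cell_band_area(g, 0), "out of range")
})

test_that("cell areas strictly decrease away from the equator", {
  g <- nc_grid(matrix(0, 179, 1), xllcorner = 0, yllcorner = -89.5, cellsize = 1)
  areas <- cell_band_area(g, seq_len(179))
  lat_mid <- 89 - (seq_len(179) - 1)
  expect_true(all(diff(areas[order(abs(lat_mid))]) <= 0))
  expect_true(all(areas > 0))
})

test_that("class counts and areas equal a brute-force per-cell tally", {
  g <- toy_grid(matrix(c(1, 1, 2, NA,
                         3, 1, 2, 2,
                         1, 95, 95, 3,
                         3, 3, 1, 1), 4, byrow = TRUE),
                kind = "categorical", cellsize = 0.1, yll = 35, xll = -84)
  q <- quantify_classes(g)
  expect_equal(tidy(q), brute_tally(g))
  expect_equal(q$totals$count, 15)
  expect_equal(q$totals$nodata, 1)
  expect_equal(q$totals$area_km2, sum(tidy(q)$area_km2))

  expect_error(quantify_classes(toy_grid(matrix(0.5, 2, 2))), "categorical")
})

test_that("a single tile reproduces the global table; tile sums are conserved", {
  g <- random_class_grid(11, p_na = 0.1)
  q1 <- quantify_classes(g, tile_layout(1, 1))
  expect_equal(q1$tiles[, c("class", "count", "area_km2")],
               q1$classes[, c("class", "count", "area_km2")])

  q <- quantify_classes(g, tile_layout(3, 4))
  sums <- q$tiles |>
    dplyr::group_by(class) |>
    dplyr::summarise(count = sum(count), area_km2 = sum(area_km2))
  expect_equal(sums$count, as.double(q$classes$count))
  expect_equal(sums$area_km2, q$classes$area_km2, tolerance = 1e-9)
})

test_that("average-cell mode multiplies counts by the mean cell area", {
  g <- random_class_grid(7)
  q <- quantify_classes(g, area_mode = "average")
  mean_area <- mean(rep(cell_band_area(g, seq_len(g$nrows)), each = g$ncols))
  expect_equal(q$classes$area_km2, q$classes$count * mean_area)
  # both modes agree on the total over all cells
  qb <- quantify_classes(g)
  expect_equal(sum(q$classes$area_km2), sum(qb$classes$area_km2), tolerance = 1e-12)
})

test_that("tile grids partition the extent, numbered row-major from the north-west", {
  g <- toy_grid(matrix(0, 40, 40), cellsize = 0.05, xll = -84.5, yll = 34.5,
                kind = "categorical")
  tb <- tile_bounds(g, tile_layout(3, 4))
  expect_equal(nrow(tb), 12)
  expect_equal(tb$west[tb$tile == 1], -84.5)
  expect_equal(tb$north[tb$tile == 1], 36.5)   # tile 1 is north-west
  expect_equal(tb$east[tb$tile == 12], -82.5)
  expect_equal(tb$south[tb$tile == 12], 34.5)  # tile 12 is south-east
  # planar union equals the extent area
  expect_equal(sum((tb$east - tb$west) * (tb$north - tb$south)), 2 * 2)

  expect_equal(nrow(tile_bounds(g, tile_layout(15, 15))), 225)
  expect_error(tile_layout(16, 15), "225")
})

test_that("quantification reports round-trip through CSV and GeoJSON", {
  g <- random_class_grid(3, classes = c(0, 11, 41, 96))
  q <- quantify_classes(g, tile_layout(2, 3))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_report(q, csv)
  back <- read_report(csv)
  expect_equal(back$classes$class, q$classes$class)
  expect_equal(back$classes$count, q$classes$count)
  expect_equal(back$classes$area_km2, q$classes$area_km2, tolerance = 1e-9)
  expect_equal(back$tiles$area_km2, q$tiles$area_km2, tolerance = 1e-9)
  expect_equal(back$totals$area_km2, q$totals$area_km2, tolerance = 1e-9)

  # totals row equals column sums
  tab <- utils::read.csv(text = paste(grep("^#", readLines(csv),
                                           invert = TRUE, value = TRUE),
                                      collapse = "\n"))
  tot <- tab[tab$label == "total", -1]
  expect_equal(unlist(tot), colSums(tab[tab$label != "total", -1]),
               ignore_attr = TRUE, tolerance = 1e-9)

  gj_path <- withr::local_tempfile(fileext = ".geojson")
  write_tile_geojson(g, tile_layout(2, 3), gj_path)
  gj <- jsonlite::read_json(gj_path)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, 6)
  expect_equal(gj$features[[1]]$properties$tile, 1)
  ring <- gj$features[[1]]$geometry$coordinates[[1]]
  expect_length(ring, 5)  # closed rectangle
  tb <- tile_bounds(g, tile_layout(2, 3))
  expect_equal(ring[[1]][[1]], tb$west[1])
  expect_equal(ring[[3]][[2]], tb$north[1])
})

test_that("corridor summaries derive suitability areas from a class table", {
  classes <- tibble::tibble(class = c(11, 41, 96, 97, 98),
                            area_km2 = c(100, 200, 30, 50, 7))
  s <- corridor_summary(classes, highest = 95)
  expect_equal(s$baseline_km2, 80)
  expect_equal(s$projected_km2, 57)
  expect_equal(s$suitability_km2, 87)
  expect_equal(s$total_km2, 387)
  expect_equal(s$decline_pct, 100 * (80 - 57) / 80)
  expect_equal(area_decline_pct(3998, 3328), 100 * 670 / 3998)
})
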