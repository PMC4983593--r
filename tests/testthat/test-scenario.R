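test_that("scenario detection matches the full input-combination table", {
  # independent oracle: explicit enumeration of all 2 x 2 x {0,1} x 2
  # input combinations and the scenario each should map to (NA = not runnable)
  combos <- expand.grid(b = c(FALSE, TRUE), p = c(FALSE, TRUE),
                        f = c(0L, 1L), l = c(FALSE, TRUE))
  expected <- function(b, p, f, l) {
    if (p && !b) return(NA_integer_)
    if (!b && !p && f == 0 && l) return(8L)
    if (!b) return(NA_integer_)
    if (!p && f > 0 && !l) return(1L)
    if (p && f == 0 && !l) return(2L)
    if (p && f > 0 && !l) return(3L)
    if (!p && f == 0 && l) return(4L)
    if (!p && f > 0 && l) return(5L)
    if (p && f == 0 && l) return(6L)
    if (p && f > 0 && l) return(7L)
    NA_integer_
  }
  for (k in seq_len(nrow(combos))) {
    want <- with(combos[k, ], expected(b, p, f, l))
    if (is.na(want)) {
      expect_error(with(combos[k, ], detect_scenario(b, p, f, l)),
                   "no runnable scenario")
    } else {
      expect_identical(with(combos[k, ], detect_scenario(b, p, f, l)), want)
    }
  }
  # features may number up to three, never more
  expect_identical(detect_scenario(TRUE, TRUE, 3L, TRUE), 7L)
  expect_error(detect_scenario(TRUE, TRUE, 4L, TRUE), "3")
})

test_that("the suitability threshold is the mean of the two evaluation thresholds", {
  expect_equal(compute_threshold_average(0.088, 0.473), 0.2805)
  expect_equal(compute_threshold_average(0.3, 0.3), 0.3)
  expect_equal(compute_threshold_average(0, 1), 0.5)
})

test_that("thresholding is strict by default and nodata is never suitable", {
  g <- toy_grid(matrix(c(0.473, 0.2805, NA, 0.281), 2))
  m <- apply_threshold(g, 0.2805)
  expect_true(m$cells[1, 1])    # 0.473 exceeds the threshold
  expect_false(m$cells[2, 1])   # exactly equal does not "exceed"
  expect_false(m$cells[1, 2])   # nodata
  expect_true(m$cells[2, 2])
  m2 <- apply_threshold(g, 0.2805, strict = FALSE)
  expect_true(m2$cells[2, 1])   # boundary cell kept in >= mode
  expect_false(m2$cells[1, 2])
})

test_that("feature filtering keeps accepted cells, respects phase, fails nodata", {
  g <- toy_grid(matrix(1, 2, 2))
  mask <- apply_threshold(g, 0.5)  # all suitable
  soil <- toy_grid(matrix(c(6, 3, NA, 6), 2), kind = "categorical")
  f <- feature_spec(soil, "categorical", accepted = 6)
  out <- apply_feature_filter(mask, f)
  expect_equal(out$cells, matrix(c(TRUE, FALSE, FALSE, TRUE), 2))

  # feature not applicable to the mask's phase: unchanged
  f_base_only <- feature_spec(soil, "categorical", accepted = 6,
                              applies_to = "baseline")
  proj_mask <- apply_threshold(g, 0.5, "projected")
  expect_equal(apply_feature_filter(proj_mask, f_base_only)$cells, proj_mask$cells)

  # continuous intervals include their endpoints
  elev <- toy_grid(matrix(c(100, 250, 300, 400), 2))
  f_cont <- feature_spec(elev, "continuous", accepted = rbind(c(100, 250), c(400, 500)))
  out2 <- apply_feature_filter(mask, f_cont)
  expect_equal(out2$cells, matrix(c(TRUE, TRUE, FALSE, TRUE), 2))

  # misaligned feature raster is an error naming the mismatch
  off <- feature_spec(toy_grid(matrix(1, 2, 2), xll = 5), "categorical", accepted = 1)
  expect_error(apply_feature_filter(mask, off), "incompatible.*xllcorner")
})

test_that("masked-suitability output keeps values under the mask, zeroes the rest", {
  vals <- matrix(c(0.9, 0.4, NA, 0.6, 0.1, 0.8, 0.3, NA, 0.7), 3)
  enm <- toy_grid(vals)
  keep <- matrix(c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE), 3)
  out <- scenario1_output(enm, toy_mask(enm, keep))
  # cell-by-cell select oracle
  expected <- vals
  for (i in 1:3) for (j in 1:3) {
    if (!is.na(vals[i, j]) && !keep[i, j]) expected[i, j] <- 0
  }
  expect_equal(out$values, expected)

  all_true <- scenario1_output(enm, toy_mask(enm, matrix(TRUE, 3, 3)))
  expect_equal(all_true$values, vals)
  all_false <- scenario1_output(enm, toy_mask(enm, matrix(FALSE, 3, 3)))
  expect_equal(all_false$values, ifelse(is.na(vals), NA, 0))
})

test_that("corridor codes follow the suitability truth table", {
  g <- toy_grid(matrix(0, 2, 2))
  base <- toy_mask(g, matrix(c(FALSE, TRUE, FALSE, TRUE), 2), "baseline")
  proj <- toy_mask(g, matrix(c(FALSE, FALSE, TRUE, TRUE), 2), "projected")
  cg <- corridor(base, proj)
  # (F,F)->0 unsuitable; (T,F)->1 baseline only; (F,T)->3 projected only;
  # (T,T)->2 both climates
  expect_equal(cg$values, matrix(c(0, 1, 3, 2), 2))
  expect_equal(cg$kind, "categorical")
  expect_error(corridor(proj, base), "baseline")
})

test_that("corridor codes merge into the LCM as highest+code on valid classes", {
  # one coarse corridor cell (code 2) over a 2x2 LCM block
  corr <- toy_grid(matrix(c(2, 0, 1, 3), 2), kind = "categorical", cellsize = 1)
  lcm <- toy_grid(matrix(c(42, 11, 42, 42,
                           42, 42, 11, 42,
                           42, 42, 42, 42,
                           95, 42, 42, NA), 4, byrow = TRUE),
                  kind = "categorical", cellsize = 0.5)
  merged <- merge_into_lcm(corr, lcm, valid_classes = c(41, 42, 43))
  # NW quadrant: code 2 -> 97; NE: code 1 -> 96; SW: code 0 -> unchanged;
  # SE: code 3 -> 98. Class 11 and 95 cells and nodata never relabeled.
  expect_equal(merged$values[1, 1], 97)
  expect_equal(merged$values[1, 2], 11)
  expect_equal(merged$values[1, 3], 96)
  expect_equal(merged$values[3, 1], 42)   # code 0, unchanged
  expect_equal(merged$values[3, 3], 98)
  expect_equal(merged$values[4, 1], 95)   # not a valid class
  expect_true(is.na(merged$values[4, 4]))

  # corridor all zero: merge is the identity
  no_op <- merge_into_lcm(toy_grid(matrix(0, 2, 2), kind = "categorical"),
                          lcm, valid_classes = c(41, 42, 43))
  expect_equal(no_op$values, lcm$values)

  # LCM not contained in corridor extent
  far <- toy_grid(matrix(42, 2, 2), kind = "categorical", xll = 10)
  expect_error(merge_into_lcm(corr, far, 42), "extent")

  # synthetic classes colliding with existing ones
  clash <- toy_grid(matrix(c(42, 96, 42, 42), 2), kind = "categorical",
                    cellsize = 0.5)
  expect_error(merge_into_lcm(corr, clash, 42, highest = 95), "collision")
})

test_that("cell centers on coarse edges resolve to the south/east cell", {
  # 2x2 coarse corridor; fine grid built so some centers sit exactly on the
  # internal coarse edges at x=1, y=1
  corr <- toy_grid(matrix(c(1, 2, 3, 0), 2, byrow = TRUE),
                   kind = "categorical", cellsize = 1)
  lcm3 <- nc_grid(matrix(42, 1, 1), xllcorner = 0.875, yllcorner = 0.875,
                  cellsize = 0.25, kind = "categorical")
  # center (1.0, 1.0): exactly on both internal edges -> south/east coarse
  # cell, i.e. corridor row 2, col 2 (code 0) -> unchanged
  m3 <- merge_into_lcm(corr, lcm3, valid_classes = 42, highest = 95)
  expect_equal(m3$values[1, 1], 42)
})
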