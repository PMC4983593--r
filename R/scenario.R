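#' Detect the runnable scenario from the input combination
#'
#' Eight scenarios are distinguished purely by which inputs are present:
#' \describe{
#'   \item{1}{baseline ENM + feature file(s): threshold + filter, output keeps
#'     original suitability values}
#'   \item{2}{baseline + projected ENM: temporal-corridor codes 0/1/2/3}
#'   \item{3}{baseline + projected + features: filtered corridor}
#'   \item{4}{baseline + LCM: thresholded baseline merged into the land-class
#'     model as class highest+1}
#'   \item{5}{baseline + features + LCM: as 4, filtered}
#'   \item{6}{baseline + projected + LCM: corridor merged as highest+1/2/3}
#'   \item{7}{baseline + projected + features + LCM: filtered corridor merged}
#'   \item{8}{LCM alone: quantification analysis}
#' }
#' Any other combination (e.g. a baseline ENM alone, or a projected ENM
#' without a baseline) is not runnable.
#'
#' @param has_baseline,has_projected,has_lcm Logical flags.
#' @param n_features Number of feature files supplied (0--3).
#' @return The scenario id, an integer in 1--8.
#' @export
detect_scenario <- function(has_baseline, has_projected, n_features, has_lcm) {
  stopifnot(is.logical(has_baseline), is.logical(has_projected), is.logical(has_lcm))
  if (n_features < 0 || n_features > 3)
    stop("between 0 and 3 feature files are supported", call. = FALSE)
  if (has_projected && !has_baseline)
    stop("no runnable scenario: a projected ENM requires a baseline ENM", call. = FALSE)
  f <- n_features > 0
  id <- if (!has_baseline && !has_projected && !f && has_lcm) 8L
    else if (has_baseline && !has_projected && f && !has_lcm) 1L
    else if (has_baseline && has_projected && !f && !has_lcm) 2L
    else if (has_baseline && has_projected && f && !has_lcm) 3L
    else if (has_baseline && !has_projected && !f && has_lcm) 4L
    else if (has_baseline && !has_projected && f && has_lcm) 5L
    else if (has_baseline && has_projected && !f && has_lcm) 6L
    else if (has_baseline && has_projected && f && has_lcm) 7L
    else NA_integer_
  if (is.na(id))
    stop("no runnable scenario for this input combination", call. = FALSE)
  id
}

#' Average two suitability thresholds
#'
#' The environmental suitability threshold used throughout the Fraser fir
#' worked example is the arithmetic mean of two MaxEnt evaluation thresholds:
#' the lowest presence threshold and the 10-percentile training presence.
#'
#' @param lpt,p10 Threshold values in `[0, 1]`.
#' @return Their arithmetic mean.
#' @examples
#' compute_threshold_average(0.088, 0.473)  # 0.2805
#' @export
compute_threshold_average <- function(lpt, p10) {
  stopifnot(lpt >= 0, lpt <= 1, p10 >= 0, p10 <= 1)
  (lpt + p10) / 2
}

# Internal constructor for a boolean suitability mask over a grid geometry.
new_mask <- function(grid, cells, phase) {
  structure(
    list(ncols = grid$ncols, nrows = grid$nrows, xllcorner = grid$xllcorner,
         yllcorner = grid$yllcorner, cellsize = grid$cellsize,
         cells = cells, phase = phase),
    class = "nc_mask"
  )
}

#' @export
print.nc_mask <- function(x, ...) {
  cat(sprintf("<nc_mask> %d x %d, phase '%s', %d suitable cells\n",
              x$nrows, x$ncols, x$phase, sum(x$cells)))
  invisible(x)
}

#' Threshold a suitability surface into a boolean mask
#'
#' A cell is climatically suitable when its suitability value *exceeds* the
#' threshold (strict `>`; nodata cells are never suitable). The strict reading
#' can be relaxed to `>=` with `strict = FALSE`.
#'
#' @param enm A continuous [nc_grid] of suitability values.
#' @param thr Finite suitability threshold.
#' @param phase `"baseline"` or `"projected"`; carried on the mask so feature
#'   applicability can be enforced.
#' @param strict If `TRUE` (default) use `value > thr`, else `value >= thr`.
#' @return An `nc_mask`.
#' @export
apply_threshold <- function(enm, thr, phase = c("baseline", "projected"),
                            strict = TRUE) {
  stopifnot(inherits(enm, "nc_grid"), is.finite(thr))
  phase <- match.arg(phase)
  cells <- if (strict) enm$values > thr else enm$values >= thr
  cells[is.na(cells)] <- FALSE
  new_mask(enm, cells, phase)
}

#' Describe a feature filter raster
#'
#' A feature file trims the climatic mask with an auxiliary raster: a
#' categorical one (e.g. soil class) keeps cells whose code is in an accepted
#' set; a continuous one (e.g. elevation) keeps cells whose value falls in any
#' of a list of closed intervals. A feature applies to one or both climate
#' phases.
#'
#' @param grid The feature [nc_grid].
#' @param data_kind `"categorical"` or `"continuous"`.
#' @param accepted For categorical features a non-empty vector of class codes;
#'   for continuous features a two-column matrix or data frame of `lo`, `hi`
#'   interval bounds (endpoints inclusive, `lo <= hi`).
#' @param applies_to Non-empty subset of `c("baseline", "projected")`.
#' @return An object of class `nc_feature`.
#' @export
feature_spec <- function(grid, data_kind = c("categorical", "continuous"),
                         accepted, applies_to = c("baseline", "projected")) {
  data_kind <- match.arg(data_kind)
  stopifnot(inherits(grid, "nc_grid"))
  applies_to <- match.arg(applies_to, several.ok = TRUE)
  if (data_kind == "categorical") {
    accepted <- as.numeric(accepted)
    if (!length(accepted)) stop("accepted class set must be non-empty", call. = FALSE)
  } else {
    accepted <- as.matrix(as.data.frame(accepted))
    if (ncol(accepted) != 2L) stop("continuous 'accepted' needs lo/hi columns", call. = FALSE)
    if (any(accepted[, 1] > accepted[, 2]))
      stop("continuous intervals require lo <= hi", call. = FALSE)
  }
  structure(list(grid = grid, data_kind = data_kind, accepted = accepted,
                 applies_to = applies_to),
            class = "nc_feature")
}

#' Filter a suitability mask with a feature raster
#'
#' Keeps a suitable cell only if the co-located feature cell is accepted.
#' Feature nodata fails the filter (a cell with unknown soil is not presumed
#' suitable). A feature whose `applies_to` does not include the mask's phase
#' returns the mask unchanged.
#'
#' @param mask An `nc_mask` from [apply_threshold()].
#' @param feature An `nc_feature` from [feature_spec()].
#' @return The filtered `nc_mask`.
#' @export
apply_feature_filter <- function(mask, feature) {
  stopifnot(inherits(mask, "nc_mask"), inherits(feature, "nc_feature"))
  if (!(mask$phase %in% feature$applies_to)) return(mask)
  assert_aligned(mask, feature$grid, what = "feature grid and mask")
  fv <- feature$grid$values
  ok <- if (feature$data_kind == "categorical") {
    matrix(fv %in% feature$accepted, nrow = nrow(fv))
  } else {
    acc <- matrix(FALSE, nrow = nrow(fv), ncol = ncol(fv))
    for (k in seq_len(nrow(feature$accepted))) {
      acc <- acc | (fv >= feature$accepted[k, 1] & fv <= feature$accepted[k, 2])
    }
    acc[is.na(acc)] <- FALSE
    acc
  }
  mask$cells <- mask$cells & ok
  mask
}

#' Masked suitability surface (scenario 1 output)
#'
#' Returns the original ENM values where the mask is suitable, zero elsewhere;
#' ENM nodata cells stay nodata.
#'
#' @param enm The continuous suitability [nc_grid].
#' @param mask An `nc_mask` on the same geometry.
#' @return A continuous [nc_grid].
#' @export
scenario1_output <- function(enm, mask) {
  stopifnot(inherits(enm, "nc_grid"), inherits(mask, "nc_mask"))
  assert_aligned(enm, mask, what = "ENM and mask")
  out <- enm
  keep <- mask$cells & !is.na(enm$values)
  out$values[!keep & !is.na(enm$values)] <- 0
  out
}

#' Temporal-corridor classification of two suitability masks
#'
#' Codes each cell by its suitability under the baseline and projected
#' climates: 0 = unsuitable under both, 1 = baseline only, 2 = both (the
#' temporal corridor where a population can persist in place), 3 = projected
#' only.
#'
#' @param base_mask,proj_mask `nc_mask` objects with phases `"baseline"` and
#'   `"projected"` on the same geometry.
#' @return A categorical [nc_grid] over codes `{0, 1, 2, 3}`.
#' @export
corridor <- function(base_mask, proj_mask) {
  stopifnot(inherits(base_mask, "nc_mask"), inherits(proj_mask, "nc_mask"))
  if (base_mask$phase != "baseline" || proj_mask$phase != "projected")
    stop("corridor() needs a baseline-phase and a projected-phase mask", call. = FALSE)
  assert_aligned(base_mask, proj_mask, what = "baseline and projected masks")
  codes <- matrix(0, nrow = base_mask$nrows, ncol = base_mask$ncols)
  codes[base_mask$cells & !proj_mask$cells] <- 1
  codes[base_mask$cells & proj_mask$cells] <- 2
  codes[!base_mask$cells & proj_mask$cells] <- 3
  nc_grid(codes, xllcorner = base_mask$xllcorner, yllcorner = base_mask$yllcorner,
          cellsize = base_mask$cellsize, kind = "categorical")
}

# A baseline-only mask expressed as a corridor over codes {0, 1}
# (scenarios 4 and 5 merge this, relabeling suitable cells as highest+1).
mask_as_corridor <- function(mask) {
  stopifnot(inherits(mask, "nc_mask"))
  nc_grid(matrix(as.numeric(mask$cells), nrow = mask$nrows),
          xllcorner = mask$xllcorner, yllcorner = mask$yllcorner,
          cellsize = mask$cellsize, kind = "categorical")
}

#' Highest class code of a categorical grid
#'
#' @param lcm A categorical [nc_grid].
#' @return The maximum class code present (nodata excluded).
#' @export
lcm_highest <- function(lcm) {
  stopifnot(inherits(lcm, "nc_grid"), lcm$kind == "categorical")
  max(lcm$values, na.rm = TRUE)
}

#' Merge corridor codes into a land-class model
#'
#' Projects a coarse corridor classification onto a (typically much finer)
#' categorical land-class model (LCM). Each LCM cell whose class is in
#' `valid_classes` samples the corridor code at its cell center
#' (nearest-by-center point lookup on the coarse grid, no interpolation); if
#' the code is 1, 2 or 3 the cell is relabeled `highest + code`, encoding
#' baseline-only / both-climates / projected-only suitability above the LCM's
#' class table. All other cells, and all cells outside `valid_classes`, keep
#' their class. The output keeps the LCM geometry, so only labels change --
#' cell counts, extent and the nodata pattern are conserved.
#'
#' A cell center falling exactly on a coarse-grid edge is assigned to the cell
#' with the larger row/column index (south/east), a fixed deterministic
#' tie-break.
#'
#' @param corridor_grid Categorical [nc_grid] over codes `{0,1,2,3}` (or
#'   `{0,1}` for a baseline-only run).
#' @param lcm Categorical [nc_grid]; its extent must be contained in the
#'   corridor grid's extent.
#' @param valid_classes Class codes eligible for relabeling (e.g. the forest
#'   classes 41/42/43 in the Fraser fir example).
#' @param highest Class code above which the synthetic classes are placed;
#'   defaults to the maximum class observed in the LCM.
#' @return The merged categorical [nc_grid].
#' @export
merge_into_lcm <- function(corridor_grid, lcm, valid_classes, highest = NULL) {
  stopifnot(inherits(corridor_grid, "nc_grid"), inherits(lcm, "nc_grid"))
  if (lcm$kind != "categorical") stop("the LCM must be categorical", call. = FALSE)
  if (is.null(highest)) highest <- lcm_highest(lcm)
  ext_c <- grid_extent(corridor_grid)
  ext_l <- grid_extent(lcm)
  eps <- 1e-9 * max(1, abs(ext_c))
  if (ext_l["west"] < ext_c["west"] - eps || ext_l["south"] < ext_c["south"] - eps ||
      ext_l["east"] > ext_c["east"] + eps || ext_l["north"] > ext_c["north"] + eps)
    stop("LCM extent is not contained in the corridor grid extent", call. = FALSE)
  existing <- unique(lcm$values[!is.na(lcm$values)])
  clash <- intersect(highest + 1:3, c(existing, lcm$nodata))
  if (length(clash))
    stop("class collision: synthetic class(es) ", paste(clash, collapse = ", "),
         " already used by the LCM or its nodata sentinel", call. = FALSE)

  # corridor column for each LCM column: index of the coarse cell containing
  # the fine cell-center longitude; floor() sends a center exactly on an edge
  # to the eastern (larger-index) cell
  cx <- col_center_lon(lcm, seq_len(lcm$ncols))
  jj <- pmin(floor((cx - corridor_grid$xllcorner) / corridor_grid$cellsize) + 1L,
             corridor_grid$ncols)
  # corridor row for each LCM row: measured down from the corridor's top edge,
  # an exact edge hit goes to the southern (larger-index) cell
  cy <- row_center_lat(lcm, seq_len(lcm$nrows))
  top <- corridor_grid$yllcorner + corridor_grid$nrows * corridor_grid$cellsize
  ii <- pmin(floor((top - cy) / corridor_grid$cellsize) + 1L, corridor_grid$nrows)

  code <- corridor_grid$values[ii, jj, drop = FALSE]
  code[is.na(code)] <- 0
  out <- lcm
  relabel <- !is.na(lcm$values) & (lcm$values %in% valid_classes) & code > 0
  out$values[relabel] <- highest + code[relabel]
  out
}
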