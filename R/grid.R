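#' Construct an in-memory grid
#'
#' `nc_grid` is the universal raster carrier of the package: an ESRI-ASCII-style
#' geographic grid with square cells in decimal degrees. Cell values are held
#' in an `nrows x ncols` numeric matrix whose **first row is the northernmost
#' row**, matching the on-disk order of the ASCII grid format. Nodata cells are
#' stored as `NA` in memory and serialized with the header's nodata sentinel.
#'
#' @param values Numeric matrix, row 1 = north. `NA` marks nodata.
#' @param xllcorner,yllcorner Longitude/latitude of the grid's lower-left
#'   corner, decimal degrees.
#' @param cellsize Cell edge length in decimal degrees (cells are square).
#' @param nodata Sentinel value used when writing nodata cells. Default -9999.
#' @param kind `"continuous"` or `"categorical"`. Categorical grids must hold
#'   integer-valued cells (class codes).
#' @return An object of class `nc_grid`.
#' @examples
#' g <- nc_grid(matrix(1:4, 2, byrow = TRUE), xllcorner = 0, yllcorner = 0,
#'              cellsize = 1, kind = "categorical")
#' g
#' @export
nc_grid <- function(values, xllcorner, yllcorner, cellsize,
                    nodata = -9999, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  nrows <- nrow(values)
  ncols <- ncol(values)
  if (nrows < 1L || ncols < 1L) stop("grid must have at least one row and one column", call. = FALSE)
  if (cellsize <= 0) stop("cellsize must be positive", call. = FALSE)
  if (yllcorner < -90 || yllcorner + nrows * cellsize > 90 + 1e-9)
    stop("grid latitude span must lie within [-90, 90] degrees", call. = FALSE)
  if (kind == "categorical") {
    v <- values[!is.na(values)]
    if (length(v) && any(v != round(v)))
      stop("categorical grid contains non-integer cell values", call. = FALSE)
  }
  structure(
    list(ncols = as.integer(ncols), nrows = as.integer(nrows),
         xllcorner = as.double(xllcorner), yllcorner = as.double(yllcorner),
         cellsize = as.double(cellsize), nodata = as.double(nodata),
         values = values, kind = kind),
    class = "nc_grid"
  )
}

#' @export
print.nc_grid <- function(x, ...) {
  cat(sprintf("<nc_grid> %d rows x %d cols, %s\n", x$nrows, x$ncols, x$kind))
  cat(sprintf("  extent : %.6g, %.6g, %.6g, %.6g (W, S, E, N degrees)\n",
              x$xllcorner, x$yllcorner,
              x$xllcorner + x$ncols * x$cellsize,
              x$yllcorner + x$nrows * x$cellsize))
  cat(sprintf("  cell   : %.6g degrees, nodata sentinel %g, %d nodata cells\n",
              x$cellsize, x$nodata, sum(is.na(x$values))))
  if (any(!is.na(x$values))) {
    rng <- range(x$values, na.rm = TRUE)
    cat(sprintf("  values : [%.6g, %.6g]\n", rng[1], rng[2]))
  }
  invisible(x)
}

# Bounding box (W, S, E, N) of a grid or any header-like list.
grid_extent <- function(g) {
  c(west = g$xllcorner, south = g$yllcorner,
    east = g$xllcorner + g$ncols * g$cellsize,
    north = g$yllcorner + g$nrows * g$cellsize)
}

# Latitude of the top edge of 1-based row i (row 1 = north).
row_lat_top <- function(g, i) g$yllcorner + (g$nrows - i + 1) * g$cellsize
row_lat_bottom <- function(g, i) g$yllcorner + (g$nrows - i) * g$cellsize

# Cell-center coordinates for 1-based row/column indices.
col_center_lon <- function(g, j) g$xllcorner + (j - 0.5) * g$cellsize
row_center_lat <- function(g, i) g$yllcorner + (g$nrows - i + 0.5) * g$cellsize

#' Read an ESRI ASCII grid
#'
#' Parses the six-key ESRI ASCII header (`NODATA_value` optional; keys accepted
#' in any case) followed by `nrows x ncols` whitespace-separated cell values,
#' north row first. Both the corner (`xllcorner`/`yllcorner`) and the center
#' (`xllcenter`/`yllcenter`) dialects are accepted; center form is normalized
#' to corner form by subtracting half a cell. Cells equal to the nodata
#' sentinel become `NA`.
#'
#' @param path Path to a `.asc` file.
#' @param kind Value kind of the grid, `"continuous"` (default) or
#'   `"categorical"`.
#' @return An [nc_grid].
#' @export
read_ascii_grid <- function(path, kind = c("continuous", "categorical")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty file: ", path, call. = FALSE)

  header <- list()
  body_start <- 1L
  for (i in seq_along(lines)) {
    tok <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(tok) == 2L && grepl("^[A-Za-z_]+$", tok[1])) {
      key <- tolower(tok[1])
      val <- suppressWarnings(as.numeric(tok[2]))
      if (is.na(val)) stop("malformed header value for key '", tok[1], "'", call. = FALSE)
      header[[key]] <- val
      body_start <- i + 1L
    } else break
  }

  need <- c("ncols", "nrows", "cellsize")
  miss <- setdiff(need, names(header))
  if (length(miss)) stop("malformed header: missing key '", miss[1], "'", call. = FALSE)
  for (k in c("ncols", "nrows")) {
    if (header[[k]] < 1 || header[[k]] != round(header[[k]]))
      stop("malformed header: '", k, "' must be a positive integer", call. = FALSE)
  }

  # corner/center dialect normalization
  xll <- if (!is.null(header$xllcorner)) header$xllcorner
         else if (!is.null(header$xllcenter)) header$xllcenter - header$cellsize / 2
         else stop("malformed header: missing key 'xllcorner'", call. = FALSE)
  yll <- if (!is.null(header$yllcorner)) header$yllcorner
         else if (!is.null(header$yllcenter)) header$yllcenter - header$cellsize / 2
         else stop("malformed header: missing key 'yllcorner'", call. = FALSE)

  nodata <- header$nodata_value
  if (is.null(nodata)) {
    nodata <- -9999
    warning("NODATA_value absent; assuming -9999 (ESRI convention)", call. = FALSE)
  }

  ncols <- as.integer(header$ncols)
  nrows <- as.integer(header$nrows)
  vals <- scan(text = paste(lines[body_start:length(lines)], collapse = "\n"),
               what = double(), quiet = TRUE)
  if (length(vals) != nrows * ncols)
    stop(sprintf("cell count mismatch: expected %d (%d x %d), found %d",
                 nrows * ncols, nrows, ncols, length(vals)), call. = FALSE)
  m <- matrix(vals, nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA_real_
  nc_grid(m, xllcorner = xll, yllcorner = yll, cellsize = header$cellsize,
          nodata = nodata, kind = kind)
}

#' Write an ESRI ASCII grid
#'
#' Serializes an [nc_grid] in corner-form ESRI ASCII. Nodata (`NA`) cells are
#' written as the grid's nodata sentinel; categorical grids are written with
#' integer tokens (no decimal point).
#'
#' @param grid An [nc_grid].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  stopifnot(inherits(grid, "nc_grid"))
  m <- grid$values
  m[is.na(m)] <- grid$nodata
  fmt_num <- function(x) {
    if (grid$kind == "categorical") sprintf("%d", as.integer(round(x)))
    else format(x, digits = 15, trim = TRUE, scientific = FALSE)
  }
  header <- c(
    sprintf("ncols %d", grid$ncols),
    sprintf("nrows %d", grid$nrows),
    sprintf("xllcorner %s", format(grid$xllcorner, digits = 15, scientific = FALSE)),
    sprintf("yllcorner %s", format(grid$yllcorner, digits = 15, scientific = FALSE)),
    sprintf("cellsize %s", format(grid$cellsize, digits = 15, scientific = FALSE)),
    sprintf("NODATA_value %s", fmt_num(grid$nodata))
  )
  body <- apply(m, 1, function(r) paste(vapply(r, fmt_num, character(1)), collapse = " "))
  ok <- tryCatch({ writeLines(c(header, body), path); TRUE },
                 error = function(e) stop("cannot write grid to '", path, "': ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Check that two grids share range and resolution
#'
#' All rasters except the land-class model must share extent and cell size
#' before they can be combined cell-by-cell. Column/row counts are compared
#' exactly; corner coordinates and cell size with a relative tolerance, since
#' files written by different GIS differ in trailing digits.
#'
#' @param a,b Grids ([nc_grid]) or any header-like list with fields `ncols`,
#'   `nrows`, `xllcorner`, `yllcorner`, `cellsize`.
#' @param tol Relative tolerance for the float header fields. Default `1e-9`.
#' @return A list with `compatible` (logical) and `mismatches`, a tibble with
#'   columns `field`, `a`, `b` (empty iff compatible).
#' @export
check_alignment <- function(a, b, tol = 1e-9) {
  rel_eq <- function(x, y) abs(x - y) <= tol * max(1, abs(x), abs(y))
  mism <- list()
  for (f in c("ncols", "nrows")) {
    if (a[[f]] != b[[f]]) mism[[f]] <- c(a[[f]], b[[f]])
  }
  for (f in c("xllcorner", "yllcorner", "cellsize")) {
    if (!rel_eq(a[[f]], b[[f]])) mism[[f]] <- c(a[[f]], b[[f]])
  }
  mismatches <- tibble::tibble(
    field = names(mism),
    a = vapply(mism, `[`, double(1), 1),
    b = vapply(mism, `[`, double(1), 2)
  )
  list(compatible = nrow(mismatches) == 0L, mismatches = mismatches)
}

# Abort with a readable listing if two grids are incompatible.
assert_aligned <- function(a, b, what = "grids", tol = 1e-9) {
  rep <- check_alignment(a, b, tol = tol)
  if (!rep$compatible) {
    det <- paste(sprintf("%s: %.10g vs %.10g", rep$mismatches$field,
                         rep$mismatches$a, rep$mismatches$b), collapse = "; ")
    stop("incompatible ", what, " (", det, ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Summarise grid values as a tibble
#'
#' For categorical grids, one row per class with its cell count; for continuous
#' grids, a one-row numeric summary. Used by the command line `inspect`
#' subcommand.
#'
#' @param grid An [nc_grid].
#' @return A tibble.
#' @export
grid_summary <- function(grid) {
  stopifnot(inherits(grid, "nc_grid"))
  v <- grid$values[!is.na(grid$values)]
  if (grid$kind == "categorical") {
    tb <- table(v)
    tibble::tibble(class = as.numeric(names(tb)), count = as.integer(tb))
  } else {
    tibble::tibble(n = length(v), min = min(v), mean = mean(v), max = max(v),
                   nodata = sum(is.na(grid$values)))
  }
}
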