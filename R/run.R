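#' Run a complete scenario from a configuration
#'
#' Dispatches on the scenario detected from the configured inputs, executes
#' the pipeline (threshold, optional feature filtering, corridor
#' classification, optional merge into the land-class model), writes every
#' output raster as ESRI ASCII and echoes a time-stamped run log to
#' `log.txt` in the output directory.
#'
#' The configuration is a named list (or a YAML file parsed with
#' [read_run_config()]) with elements:
#' \describe{
#'   \item{baseline, projected}{paths to the suitability ASCII grids}
#'   \item{features}{list of up to three entries, each with `path`, `kind`
#'     (`"categorical"`/`"continuous"`), `accepted` (class codes, or a list
#'     of `c(lo, hi)` intervals) and `applies_to`}
#'   \item{lcm}{list with `path`, `valid_classes` and optional `highest`}
#'   \item{thresholds}{list with `baseline` and (optionally) `projected`
#'     suitability thresholds; a single value is used for both}
#'   \item{strict}{logical, strict `>` thresholding (default `TRUE`)}
#' }
#'
#' @param config Configuration list as above.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with the `scenario` id, the output `rasters`
#'   (named list of [nc_grid]s), the `files` written and the `log` path.
#' @export
run_scenario <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "log.txt")
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  fail <- function(stage, e) {
    say("ERROR in stage '%s': %s", stage, conditionMessage(e))
    writeLines(log_lines, log_path)
    stop("scenario run failed in stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  t0 <- Sys.time()

  stage <- "configuration"
  res <- tryCatch({
    has_b <- !is.null(config$baseline)
    has_p <- !is.null(config$projected)
    n_f <- length(config$features)
    has_l <- !is.null(config$lcm)
    id <- detect_scenario(has_b, has_p, n_f, has_l)
    say("scenario %d detected (baseline=%s projected=%s features=%d lcm=%s)",
        id, has_b, has_p, n_f, has_l)

    if (id == 8) {
      stage <- "quantification"
      lcm <- read_ascii_grid(config$lcm$path, "categorical")
      layout <- if (!is.null(config$tiles))
        tile_layout(config$tiles[[1]], config$tiles[[2]])
      rep <- quantify_classes(lcm, layout,
                              area_mode = config$area_mode %||% "band")
      files <- c(report = file.path(out_dir, "quantification.csv"))
      write_report(rep, files[["report"]])
      say("wrote %s", files[["report"]])
      if (!is.null(layout)) {
        files["tiles"] <- file.path(out_dir, "tile_grid.geojson")
        write_tile_geojson(lcm, layout, files[["tiles"]])
        say("wrote %s", files[["tiles"]])
      }
      say("run complete in %.2f s",
          as.numeric(difftime(Sys.time(), t0, units = "secs")))
      writeLines(log_lines, log_path)
      return(invisible(list(scenario = 8L, report = rep, files = files,
                            log = log_path)))
    }

    if (is.null(config$thresholds))
      stop("suitability thresholds are required for scenarios 1-7", call. = FALSE)
    thr_b <- config$thresholds$baseline %||% config$thresholds[[1]]
    thr_p <- config$thresholds$projected %||% thr_b
    strict <- config$strict %||% TRUE

    stage <- "read inputs"
    baseline <- if (has_b) {
      say("baseline ENM: %s", config$baseline)
      read_ascii_grid(config$baseline, "continuous")
    }
    projected <- if (has_p) {
      say("projected ENM: %s", config$projected)
      read_ascii_grid(config$projected, "continuous")
    }
    features <- purrr::map(config$features, function(f) {
      say("feature (%s): %s", f$kind, f$path)
      acc <- if (identical(f$kind, "continuous")) {
        do.call(rbind, lapply(f$accepted, function(iv) c(lo = iv[[1]], hi = iv[[2]])))
      } else unlist(f$accepted)
      feature_spec(read_ascii_grid(f$path, f$kind), f$kind, accepted = acc,
                   applies_to = unlist(f$applies_to %||% c("baseline", "projected")))
    })
    lcm <- if (has_l) {
      say("land-class model: %s", config$lcm$path)
      read_ascii_grid(config$lcm$path, "categorical")
    }

    stage <- "threshold"
    filt <- function(mask) {
      for (f in features) mask <- apply_feature_filter(mask, f)
      mask
    }
    base_mask <- NULL
    if (has_b) {
      say("baseline threshold %.6g (%s)", thr_b, if (strict) ">" else ">=")
      base_mask <- apply_threshold(baseline, thr_b, "baseline", strict = strict)
      say("baseline suitable cells: %d", sum(base_mask$cells))
    }
    proj_mask <- NULL
    if (has_p) {
      say("projected threshold %.6g (%s)", thr_p, if (strict) ">" else ">=")
      proj_mask <- apply_threshold(projected, thr_p, "projected", strict = strict)
      say("projected suitable cells: %d", sum(proj_mask$cells))
    }

    stage <- "feature filtering"
    if (length(features)) {
      if (!is.null(base_mask)) {
        base_mask <- filt(base_mask)
        say("baseline suitable cells after filtering: %d", sum(base_mask$cells))
      }
      if (!is.null(proj_mask)) {
        proj_mask <- filt(proj_mask)
        say("projected suitable cells after filtering: %d", sum(proj_mask$cells))
      }
    }

    rasters <- list()
    stage <- "classification"
    if (id == 1) {
      rasters$masked_enm <- scenario1_output(baseline, base_mask)
    } else if (id %in% c(2, 3)) {
      rasters$corridor <- corridor(base_mask, proj_mask)
    } else if (id %in% c(4, 5)) {
      rasters$corridor <- mask_as_corridor(base_mask)
    } else if (id %in% c(6, 7)) {
      rasters$corridor <- corridor(base_mask, proj_mask)
    }
    if (!is.null(rasters$corridor)) {
      cnt <- grid_summary(rasters$corridor)
      say("corridor code counts: %s",
          paste(sprintf("%d=%d", cnt$class, cnt$count), collapse = " "))
    }

    stage <- "merge into LCM"
    if (id %in% c(4, 5, 6, 7)) {
      highest <- config$lcm$highest %||% lcm_highest(lcm)
      say("LCM highest class: %g; valid classes: %s", highest,
          paste(config$lcm$valid_classes, collapse = ", "))
      rasters$merged_lcm <- merge_into_lcm(rasters$corridor, lcm,
                                           valid_classes = unlist(config$lcm$valid_classes),
                                           highest = highest)
      added <- grid_summary(rasters$merged_lcm)
      added <- added[added$class > highest, , drop = FALSE]
      say("suitability class counts: %s",
          paste(sprintf("%g=%d", added$class, added$count), collapse = " "))
    }

    stage <- "write outputs"
    files <- character()
    for (nm in names(rasters)) {
      p <- file.path(out_dir, paste0(nm, ".asc"))
      write_ascii_grid(rasters[[nm]], p)
      say("wrote %s", p)
      files[nm] <- p
    }
    say("run complete in %.2f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
    writeLines(log_lines, log_path)
    list(scenario = id, rasters = rasters, files = files, log = log_path)
  }, error = function(e) fail(stage, e))
  invisible(res)
}

#' Read a run configuration from a YAML file
#'
#' Relative raster paths in the file are resolved against the file's own
#' directory.
#'
#' @param path Path to a YAML configuration (see [run_scenario()]).
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  config <- yaml::read_yaml(path)
  base_dir <- dirname(normalizePath(path))
  fix <- function(p) {
    if (is.null(p)) return(NULL)
    if (file.exists(p)) p else file.path(base_dir, p)
  }
  config$baseline <- fix(config$baseline)
  config$projected <- fix(config$projected)
  if (!is.null(config$lcm)) config$lcm$path <- fix(config$lcm$path)
  config$features <- lapply(config$features, function(f) {
    f$path <- fix(f$path)
    f
  })
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a
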