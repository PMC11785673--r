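#' Read a pixel EVI (or reflectance) table
#'
#' Accepts the pipeline's delimited interchange schema: `pixel_id`, `date`
#' (ISO-8601), then either an `evi` column or the three reflectance bands
#' `rho_nir`, `rho_red`, `rho_blue` (EVI is then computed), an optional `qa`
#' column (non-zero/`"bad"` entries are discarded) and an optional `flag`
#' column as written by [write_evi_table()].
#'
#' @param path CSV path (or a data.frame already in the schema).
#' @param coeffs [evi_coefficients()] used when reflectances are supplied.
#' @param cadence nominal cadence in days of the stored series (default 8).
#' @return named list of [evi_series()], one per pixel.
#' @export
read_evi_table <- function(path, coeffs = evi_coefficients(), cadence = 8) {
  tab <- if (is.character(path)) utils::read.csv(path) else path
  if (!all(c("pixel_id", "date") %in% names(tab)))
    phen_error("phen_bad_input", "need pixel_id and date columns")
  if (!"evi" %in% names(tab)) {
    bands <- c("rho_nir", "rho_red", "rho_blue")
    if (!all(bands %in% names(tab)))
      phen_error("phen_bad_input", "need either evi or rho_nir/rho_red/rho_blue")
    tab$evi <- as.numeric(compute_evi(tab$rho_nir, tab$rho_red, tab$rho_blue,
                                      coeffs))
  }
  if (!"flag" %in% names(tab)) {
    tab$flag <- ifelse(is.na(tab$evi), "missing", "ok")
    if ("qa" %in% names(tab)) {
      bad_qa <- !(tab$qa %in% c(0, "0", "ok", "good", NA, ""))
      tab$flag[bad_qa & tab$flag == "ok"] <- "discarded"
    }
  }
  out <- lapply(split(tab, tab$pixel_id), function(px) {
    px <- px[order(as.Date(px$date)), , drop = FALSE]
    evi_series(px$pixel_id[1], px$date, px$evi, px$flag, cadence = cadence)
  })
  out[order(names(out))]
}

#' Write pixel series to the interchange CSV schema
#' @param series named list of [evi_series()] (or a single one).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_evi_table <- function(series, path) {
  if (inherits(series, "evi_ts")) series <- list(series)
  rows <- do.call(rbind, lapply(series, function(s) {
    data.frame(pixel_id = attr(s, "pixel_id"),
               date = format(s$date, "%Y-%m-%d"),
               evi = s$evi, flag = s$flag)
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

log_line <- function(log_path, stage, pixel_id, year, event) {
  line <- sprintf("%s\tstage=%s\tpixel=%s\tyear=%s\t%s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage, pixel_id, year, event)
  if (!is.null(log_path)) cat(line, "\n", file = log_path, append = TRUE)
  invisible(line)
}

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run. Unknown entries are
#' rejected so config typos fail loudly.
#'
#' @param rules a [quality_rules()].
#' @param smoothing an [sg_config()].
#' @param min_obs,amplitude_floor,pad_days fitting controls, see
#'   [fit_double_logistic()].
#' @param onset_rule `"first-seen"` or `"median-seen"`.
#' @param metric_names metrics carried through the comparison.
#' @param min_n minimum pairs per comparison cell.
#' @param coverage_split coverage stratification threshold.
#' @param seed seed recorded in the run log.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(rules = quality_rules(), smoothing = sg_config(),
                            min_obs = 10, amplitude_floor = 0.05,
                            pad_days = 32, onset_rule = "first-seen",
                            metric_names = .metric_names, min_n = 3,
                            coverage_split = 0.75, seed = 42) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full pipeline on pixel series and survey observations
#'
#' preprocess (quality filter + smoothing) -> fit per pixel-year -> extract
#' phenometrics -> ground phase onsets -> metric-by-phase comparison. All
#' stage outputs are written as CSV under `out_dir` together with a run log;
#' pixel-years that fail a stage are logged and skipped, the run continues.
#'
#' @param series named list of [evi_series()] (e.g. from [read_evi_table()]
#'   or [simulate_series()]).
#' @param observations survey data.frame (`orchard_id`, `date`, `code`), or
#'   `NULL` to skip the ground/comparison stages.
#' @param out_dir output directory (created if needed).
#' @param config a [pipeline_config()].
#' @param link optional pixel-to-orchard link table.
#' @param coverage optional data.frame `pixel_id`, `coverage`.
#' @param mapping scale mapping for [load_observations()].
#' @return list with `smoothed`, `curves`, `metrics`, `filter_reports`,
#'   `onsets`, `comparison` (NULL where skipped), invisibly also on disk.
#' @export
run_pipeline <- function(series, observations = NULL, out_dir,
                         config = pipeline_config(), link = NULL,
                         coverage = NULL, mapping = default_scale_mapping()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat(sprintf("run start seed=%s config_hash=%s\n", config$seed,
              sum(utf8ToInt(paste(deparse(config), collapse = "")))),
      file = log_path)

  smoothed <- list(); reports <- list(); curves <- list(); sets <- list()
  for (pid in names(series)) {
    filt <- apply_quality_filter(series[[pid]], config$rules)
    reports[[pid]] <- filt$report
    log_line(log_path, "filter", pid, "all",
             sprintf("discarded=%d of %d", attr(filt$report, "n_discarded"),
                     attr(filt$report, "n_evaluated")))
    sm <- tryCatch(smooth_savitzky_golay(filt$series, config$smoothing),
                   phenomatch_error = function(e) e)
    if (inherits(sm, "error")) {
      log_line(log_path, "smooth", pid, "all",
               paste("skipped:", conditionMessage(sm)))
      next
    }
    smoothed[[pid]] <- sm
    for (year in sort(unique(as.integer(format(sm$date, "%Y"))))) {
      cv <- tryCatch(
        fit_double_logistic(sm, year, min_obs = config$min_obs,
                            amplitude_floor = config$amplitude_floor,
                            pad_days = config$pad_days),
        phenomatch_error = function(e) e)
      if (inherits(cv, "error")) {
        log_line(log_path, "fit", pid, year,
                 paste("skipped:", conditionMessage(cv)))
        next
      }
      log_line(log_path, "fit", pid, year,
               sprintf("converged=%s rmse=%.5f", cv$converged, cv$fit_rmse))
      curves[[paste(pid, year, sep = "_")]] <- cv
      sets[[paste(pid, year, sep = "_")]] <- extract_all(cv)
    }
  }
  metrics <- if (length(sets)) phenometric_table(sets) else NULL

  filter_df <- do.call(rbind, lapply(names(reports), function(pid) {
    r <- reports[[pid]]
    data.frame(pixel_id = pid, rule = r$rule, count = r$count,
               n_evaluated = attr(r, "n_evaluated"),
               fraction = attr(r, "fraction"))
  }))
  utils::write.csv(filter_df, file.path(out_dir, "filter_report.csv"),
                   row.names = FALSE)
  if (length(smoothed))
    write_evi_table(smoothed, file.path(out_dir, "smoothed.csv"))
  if (length(curves)) {
    par_df <- do.call(rbind, lapply(curves, function(cv) {
      data.frame(pixel_id = cv$pixel_id, year = cv$year,
                 baseline = cv$params$baseline, amplitude = cv$params$amplitude,
                 t_up = cv$params$t_up, s_up = cv$params$s_up,
                 t_down = cv$params$t_down, s_down = cv$params$s_down,
                 greendown = cv$params$greendown,
                 fit_rmse = cv$fit_rmse, converged = cv$converged)
    }))
    utils::write.csv(par_df, file.path(out_dir, "fitted_params.csv"),
                     row.names = FALSE)
  }
  if (!is.null(metrics))
    utils::write.csv(metrics, file.path(out_dir, "phenometrics.csv"),
                     row.names = FALSE, na = "")

  onsets <- NULL; comparison <- NULL
  if (!is.null(observations) && !is.null(metrics)) {
    loaded <- load_observations(observations, mapping)
    log_line(log_path, "ground", "all", "all",
             sprintf("mapped=%d unmapped=%d duplicates=%d",
                     loaded$report$mapped, loaded$report$unmapped,
                     loaded$report$duplicates))
    onsets <- phase_onsets(loaded$observations, rule = config$onset_rule)
    utils::write.csv(onsets, file.path(out_dir, "phase_onsets.csv"),
                     row.names = FALSE)
    comparison <- compare_all(metrics, onsets, link = link,
                              metric_names = config$metric_names,
                              min_n = config$min_n, coverage = coverage,
                              coverage_split = config$coverage_split)
    utils::write.csv(comparison, file.path(out_dir, "comparison.csv"),
                     row.names = FALSE)
  }
  log_line(log_path, "done", "all", "all",
           sprintf("pixel_years=%d", length(curves)))
  invisible(list(smoothed = smoothed, curves = curves, metrics = metrics,
                 filter_reports = reports, onsets = onsets,
                 comparison = comparison))
}

#' Export a start-of-season map
#'
#' Writes a point table (longitude, latitude, DOY of the chosen metric) and,
#' when the pixels form a regular lon/lat grid, an ESRI ASCII raster grid of
#' the same values. Pixels without the metric get the no-data value.
#'
#' @param metrics data.frame from [phenometric_table()].
#' @param metadata data.frame `pixel_id`, `longitude`, `latitude`, ...
#' @param metric metric column to map (default `"trs5_sos"`).
#' @param year year to map (default: earliest in `metrics`).
#' @param points_path output CSV path for the point table.
#' @param raster_path optional output path for the ASCII grid.
#' @param nodata no-data value for the raster (default -9999).
#' @return data.frame of the point table, invisibly.
#' @export
export_sos_map <- function(metrics, metadata, metric = "trs5_sos",
                           year = min(metrics$year), points_path,
                           raster_path = NULL, nodata = -9999) {
  my <- metrics[metrics$year == year, c("pixel_id", metric)]
  pts <- merge(metadata[c("pixel_id", "longitude", "latitude")], my,
               by = "pixel_id", all.x = TRUE)
  names(pts)[names(pts) == metric] <- "doy"
  pts <- pts[order(-pts$latitude, pts$longitude), , drop = FALSE]
  utils::write.csv(pts, points_path, row.names = FALSE, na = "")
  if (!is.null(raster_path)) {
    lons <- sort(unique(pts$longitude)); lats <- sort(unique(pts$latitude))
    dx <- diff(lons); dy <- diff(lats)
    regular <- length(lons) > 1 && length(lats) > 1 &&
      max(abs(dx - dx[1])) < 1e-9 && max(abs(dy - dy[1])) < 1e-9 &&
      abs(dx[1] - dy[1]) < 1e-9 &&
      nrow(pts) == length(lons) * length(lats)
    if (!regular) {
      warning("pixels do not form a regular grid; raster export skipped",
              call. = FALSE)
    } else {
      cell <- dx[1]
      grid <- matrix(nodata, nrow = length(lats), ncol = length(lons))
      for (r in seq_len(nrow(pts))) {
        i <- match(pts$latitude[r], rev(lats))   # top row = max latitude
        j <- match(pts$longitude[r], lons)
        if (!is.na(pts$doy[r])) grid[i, j] <- pts$doy[r]
      }
      con <- file(raster_path, "w")
      writeLines(c(sprintf("ncols %d", length(lons)),
                   sprintf("nrows %d", length(lats)),
                   sprintf("xllcorner %.10f", min(lons) - cell / 2),
                   sprintf("yllcorner %.10f", min(lats) - cell / 2),
                   sprintf("cellsize %.10f", cell),
                   sprintf("NODATA_value %d", nodata)), con)
      utils::write.table(grid, con, row.names = FALSE, col.names = FALSE)
      close(con)
    }
  }
  invisible(pts)
}
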