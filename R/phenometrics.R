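## All extractors report whole days (the field convention): continuous
## locations on the analytic curve are rounded to the nearest grid day, with
## ties broken to the earlier day, and searches are restricted to the rising
## segment [trough, peak] so autumn structure never leaks into spring metrics.

.metric_names <- c("der_sos", "der_pos", "trs2_sos", "trs5_sos",
                   "gu_ud", "gu_sd", "greenup", "maturity")

round_half_down <- function(x) ceiling(x - 0.5)

## refine a grid-located maximum of `fn` to the continuous optimum
refine_max <- function(fn, at, lo, hi) {
  a <- max(lo, at - 1); b <- min(hi, at + 1)
  if (a >= b) return(at)
  stats::optimize(fn, c(a, b), maximum = TRUE, tol = 1e-6)$maximum
}

#' Threshold (TRS) start of season
#'
#' The day the fitted curve first reaches `baseline + fraction * amplitude`
#' on its rising limb. The crossing is located on the continuous analytic
#' curve between the bracketing grid days and rounded to the nearest whole
#' day; fractions 0.2 and 0.5 give the TRS2 and TRS5 start-of-season dates.
#'
#' @param curve a [fitted_curve()].
#' @param geometry a [derive_season_geometry()] result.
#' @param fraction amplitude fraction in (0, 1).
#' @return day of year (integer), or `NA` with a `"reason"` attribute when
#'   the curve never crosses the threshold.
#' @export
extract_trs <- function(curve, geometry, fraction) {
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction >= 1)
    stop("fraction must be a single number in (0, 1)", call. = FALSE)
  thr <- geometry$baseline_value + fraction * geometry$amplitude
  seg <- curve$doy >= geometry$trough_doy & curve$doy <= geometry$peak_doy
  g <- curve$doy[seg]; v <- curve$values[seg]
  hit <- which(v >= thr)
  if (length(hit) == 0L)
    return(structure(NA_integer_, reason = "no_threshold_crossing"))
  i <- hit[1]
  if (i == 1L) return(g[1])
  root <- stats::uniroot(function(t) evaluate_curve(curve$params, t) - thr,
                         lower = g[i - 1], upper = g[i], tol = 1e-6)$root
  as.integer(round_half_down(root))
}

#' Derivative-method phenometrics
#'
#' `der_sos` is the day of the fastest index increase (argmax of the first
#' derivative of the fitted curve on the rising limb, earliest day on ties);
#' `der_pos` is the peak-of-season day, the curve's maximum.
#'
#' @inheritParams extract_trs
#' @return named integer vector `c(der_sos, der_pos)`.
#' @export
extract_der <- function(curve, geometry) {
  seg <- curve$doy >= geometry$trough_doy & curve$doy <= geometry$peak_doy
  g <- curve$doy[seg]
  d1 <- curve_derivative(curve$params, g, 1)
  c(der_sos = g[which.max(d1)], der_pos = geometry$peak_doy)
}

#' Gu-method upturn and stabilization dates
#'
#' The recovery line is the tangent to the fitted curve at the day of
#' maximum first derivative. Its intersection with the baseline gives the
#' upturn date (UD); with the peak line, the stabilization date (SD). Dates
#' falling outside the daily grid are clipped and flagged low-confidence.
#'
#' @inheritParams extract_trs
#' @return named integer vector `c(gu_ud, gu_sd)`; `NA` with a reason when
#'   the maximum slope is not positive.
#' @export
extract_gu <- function(curve, geometry) {
  der <- extract_der(curve, geometry)
  t_star <- refine_max(function(t) curve_derivative(curve$params, t, 1),
                       der[["der_sos"]], geometry$trough_doy, geometry$peak_doy)
  k <- curve_derivative(curve$params, t_star, 1)
  if (!is.finite(k) || k <= 0)
    return(structure(c(gu_ud = NA_integer_, gu_sd = NA_integer_),
                     reason = "non_positive_slope"))
  v <- evaluate_curve(curve$params, t_star)
  ud <- t_star + (geometry$baseline_value - v) / k
  sd <- t_star + (geometry$peak_value - v) / k
  lo <- min(curve$doy); hi <- max(curve$doy)
  clipped <- ud < lo || sd > hi
  out <- c(gu_ud = as.integer(round_half_down(max(ud, lo))),
           gu_sd = as.integer(round_half_down(min(sd, hi))))
  if (clipped) attr(out, "low_confidence") <- TRUE
  out
}

#' Zhang curvature-change-rate greenup and maturity
#'
#' On the rising limb, computes the rate of change K'(t) of the curve's
#' curvature K = f'' / (1 + f'^2)^(3/2) from the analytic derivatives of
#' the fitted model. Greenup is the first local maximum of K'; maturity is
#' the next one, i.e. the second curvature-rate maximum of the sigmoid rise
#' (a greendown-capable curve can show a further K' maximum where the
#' summer decline bends the plateau, which marks greendown onset, not
#' canopy maturity, and is ignored). Each grid-located maximum is refined
#' on the continuous curve before rounding to a whole day.
#'
#' @inheritParams extract_trs
#' @return named integer vector `c(greenup, maturity)`; `NA` with a reason
#'   when fewer than two local maxima exist on the limb.
#' @export
extract_zhang <- function(curve, geometry) {
  seg <- curve$doy >= geometry$trough_doy & curve$doy <= geometry$peak_doy
  g <- curve$doy[seg]
  if (length(g) < 3L)
    return(structure(c(greenup = NA_integer_, maturity = NA_integer_),
                     reason = "segment_too_short"))
  kp <- curvature_rate(curve$params, g)
  interior <- which(diff(sign(diff(kp))) < 0) + 1L  # grid local maxima
  # ignore numerically flat ripples: genuine curvature-rate maxima on the
  # rising limb are a sizeable fraction of the global one
  interior <- interior[kp[interior] > 0.05 * max(kp)]
  if (length(interior) < 2L)
    return(structure(c(greenup = NA_integer_, maturity = NA_integer_),
                     reason = "fewer_than_two_curvature_maxima"))
  fn <- function(t) curvature_rate(curve$params, t)
  gu <- refine_max(fn, g[interior[1]], g[1], g[length(g)])
  mt <- refine_max(fn, g[interior[2]], g[1], g[length(g)])
  c(greenup = as.integer(round_half_down(gu)),
    maturity = as.integer(round_half_down(mt)))
}

#' Extract all eight spring phenometrics
#'
#' Runs the threshold (TRS2/TRS5), derivative (SOS/POS), Gu (UD/SD) and
#' Zhang (greenup/maturity) extractors on one fitted pixel-year, collecting
#' per-metric missing reasons instead of failing on degenerate metrics. An
#' unconverged curve yields an all-missing set.
#'
#' @param curve a [fitted_curve()].
#' @return a `phenometric_set`: list with `pixel_id`, `year`, the eight
#'   metrics (integer DOY or `NA`), and a named `reasons` list for the
#'   missing ones.
#' @export
extract_all <- function(curve) {
  stopifnot(inherits(curve, "fitted_curve"))
  empty <- stats::setNames(rep(NA_integer_, 8), .metric_names)
  if (!isTRUE(curve$converged)) {
    return(structure(list(pixel_id = curve$pixel_id, year = curve$year,
                          metrics = empty,
                          reasons = list(all = "fit_not_converged")),
                     class = "phenometric_set"))
  }
  reasons <- list()
  metrics <- empty
  geom <- tryCatch(suppressWarnings(derive_season_geometry(curve)),
                   phenomatch_error = function(e) e)
  if (inherits(geom, "error")) {
    return(structure(list(pixel_id = curve$pixel_id, year = curve$year,
                          metrics = empty,
                          reasons = list(all = conditionMessage(geom))),
                     class = "phenometric_set"))
  }
  grab <- function(x, nm) {
    for (n in nm) {
      val <- if (length(x) > 1L) x[[n]] else x
      metrics[[n]] <<- val
      if (is.na(val) && !is.null(attr(x, "reason")))
        reasons[[n]] <<- attr(x, "reason")
    }
  }
  grab(extract_trs(curve, geom, 0.2), "trs2_sos")
  grab(extract_trs(curve, geom, 0.5), "trs5_sos")
  grab(extract_der(curve, geom), c("der_sos", "der_pos"))
  grab(extract_gu(curve, geom), c("gu_ud", "gu_sd"))
  grab(extract_zhang(curve, geom), c("greenup", "maturity"))
  structure(list(pixel_id = curve$pixel_id, year = curve$year,
                 metrics = metrics, reasons = reasons),
            class = "phenometric_set")
}

#' @export
print.phenometric_set <- function(x, ...) {
  cat(sprintf("<phenometric_set> pixel %s year %d\n", x$pixel_id, x$year))
  print(x$metrics)
  if (length(x$reasons))
    cat("missing:", paste(names(x$reasons), unlist(x$reasons),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' One-row data.frame of a phenometric set
#' @param x a `phenometric_set`.
#' @param ... unused.
#' @export
as.data.frame.phenometric_set <- function(x, ...) {
  out <- data.frame(pixel_id = x$pixel_id, year = x$year)
  for (m in .metric_names) out[[m]] <- x$metrics[[m]]
  out$missing_reasons <- if (length(x$reasons))
    paste(names(x$reasons), unlist(x$reasons), sep = ":", collapse = ";")
  else ""
  out
}

#' Bind phenometric sets into a long-format table
#' @param sets list of `phenometric_set` objects.
#' @return data.frame, one row per pixel-year.
#' @export
phenometric_table <- function(sets) {
  do.call(rbind, lapply(sets, as.data.frame))
}
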