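#' EVI algorithm coefficients
#'
#' Gain and aerosol-resistance coefficients of the Enhanced Vegetation Index.
#' The defaults are the standard MODIS values: gain G = 2.5, aerosol
#' coefficients C1 = 6 and C2 = 7.5, canopy background adjustment L = 1.
#'
#' @param G gain factor.
#' @param C1,C2 aerosol resistance coefficients (red, blue).
#' @param L canopy background adjustment.
#' @return a named list of class `evi_coefficients`.
#' @export
evi_coefficients <- function(G = 2.5, C1 = 6, C2 = 7.5, L = 1) {
  vals <- c(G = G, C1 = C1, C2 = C2, L = L)
  if (!all(is.finite(vals))) phen_error("phen_bad_input", "coefficients must be finite")
  structure(as.list(vals), class = "evi_coefficients")
}

#' Compute the Enhanced Vegetation Index from surface reflectance
#'
#' EVI = G (rho_nir - rho_red) / (rho_nir + C1 rho_red - C2 rho_blue + L),
#' with atmospherically corrected surface reflectances in \[0, 1\]. Values
#' whose denominator is near zero, or that fall outside the index's valid
#' range \[-1, 1\], are invalid and returned as `NA` rather than clipped:
#' the range is a definition of validity, not a transform.
#'
#' @param rho_nir,rho_red,rho_blue surface reflectance vectors in \[0, 1\].
#' @param coeffs an [evi_coefficients()] object.
#' @param denom_tol denominators smaller than this in absolute value are
#'   treated as zero.
#' @return numeric vector of EVI values; invalid samples are `NA` and their
#'   reasons are available in the `"invalid"` attribute (`"denominator"` or
#'   `"out_of_range"`).
#' @export
compute_evi <- function(rho_nir, rho_red, rho_blue,
                        coeffs = evi_coefficients(), denom_tol = 1e-8) {
  n <- length(rho_nir)
  stopifnot(length(rho_red) == n, length(rho_blue) == n)
  refl <- c(rho_nir, rho_red, rho_blue)
  if (any(refl < 0 | refl > 1, na.rm = TRUE))
    phen_error("phen_bad_input", "reflectances must lie in [0, 1]")
  denom <- rho_nir + coeffs$C1 * rho_red - coeffs$C2 * rho_blue + coeffs$L
  evi <- coeffs$G * (rho_nir - rho_red) / denom
  invalid <- rep(NA_character_, n)
  bad_den <- !is.na(denom) & abs(denom) < denom_tol
  invalid[bad_den] <- "denominator"
  evi[bad_den] <- NA_real_
  oor <- !is.na(evi) & (evi < -1 | evi > 1)
  invalid[oor] <- "out_of_range"
  evi[oor] <- NA_real_
  structure(evi, invalid = invalid)
}

#' Maximum value compositing
#'
#' Reduces a time series to one entry per fixed-length period by keeping the
#' highest index value within the period (the MVC noise-reduction rule for
#' optical imagery). The period calendar restarts every January 1, and each
#' composite is dated at its period start; an 8-day calendar therefore yields
#' 46 periods per year, the last starting December 27 in a non-leap year.
#' Periods with no usable entry are emitted with flag `"missing"`.
#'
#' @param series an [evi_series()].
#' @param period_days length of the compositing period in days (default 8).
#' @return an `evi_ts` with `cadence = period_days`.
#' @export
composite_mvc <- function(series, period_days = 8) {
  stopifnot(inherits(series, "evi_ts"), period_days >= 1)
  period_days <- as.integer(period_days)
  if (nrow(series) == 0L)
    return(evi_ts_like(series, as.Date(character()), numeric(), character(),
                       cadence = period_days))
  yr <- as.integer(format(series$date, "%Y"))
  years <- seq(min(yr), max(yr))
  out <- lapply(years, function(y) {
    jan1 <- as.Date(sprintf("%d-01-01", y))
    n_periods <- (days_in_year(y) - 1L) %/% period_days + 1L
    starts <- jan1 + (seq_len(n_periods) - 1L) * period_days
    in_year <- series[yr == y, , drop = FALSE]
    idx <- (doy(in_year$date) - 1L) %/% period_days + 1L
    val <- rep(NA_real_, n_periods)
    for (p in unique(idx)) {
      ok <- in_year$flag == "ok" & idx == p & !is.na(in_year$evi)
      if (any(ok)) val[p] <- max(in_year$evi[ok])
    }
    data.frame(date = starts, evi = val,
               flag = ifelse(is.na(val), "missing", "ok"))
  })
  out <- do.call(rbind, out)
  evi_ts_like(series, out$date, out$evi, out$flag, cadence = period_days)
}

#' Expert quality-filter rules
#'
#' EVI floors used to discard implausible composites in evergreen-free
#' orchard pixels: an annual floor applied year-round and a stricter floor
#' inside the summer window, when a closed hazelnut canopy must be green.
#'
#' @param annual_min EVI floor applied year-round (default 0.1).
#' @param summer_min EVI floor inside the summer window (default 0.3).
#' @param summer_window month-day start/end of the summer window, inclusive
#'   (default June 1 to August 31).
#' @return a `quality_rules` list.
#' @export
quality_rules <- function(annual_min = 0.1, summer_min = 0.3,
                          summer_window = c("06-01", "08-31")) {
  if (annual_min >= summer_min)
    phen_error("phen_bad_input", "annual_min must be below summer_min")
  structure(list(annual_min = annual_min, summer_min = summer_min,
                 summer_window = summer_window),
            class = "quality_rules")
}

#' Apply the expert quality filter
#'
#' Flags entries violating the rules as `"discarded"` (an entry is counted
#' under the first rule it violates, so totals never double count) and
#' reports per-rule counts plus the discarded fraction of evaluated entries.
#'
#' @param series an [evi_series()].
#' @param rules a [quality_rules()] object.
#' @return a list with elements `series` (flags updated) and `report`
#'   (data.frame `rule`, `count`, plus attributes `n_evaluated`, `fraction`).
#' @export
apply_quality_filter <- function(series, rules = quality_rules()) {
  stopifnot(inherits(series, "evi_ts"))
  md <- format(series$date, "%m-%d")
  in_summer <- md >= rules$summer_window[1] & md <= rules$summer_window[2]
  evaluable <- series$flag == "ok" & !is.na(series$evi)
  below_annual <- evaluable & series$evi <= rules$annual_min
  below_summer <- evaluable & !below_annual & in_summer &
    series$evi <= rules$summer_min
  flag <- series$flag
  flag[below_annual | below_summer] <- "discarded"
  report <- data.frame(
    rule = c("annual_min", "summer_min"),
    count = c(sum(below_annual), sum(below_summer))
  )
  attr(report, "n_evaluated") <- sum(evaluable)
  attr(report, "n_discarded") <- sum(below_annual | below_summer)
  attr(report, "fraction") <-
    if (sum(evaluable) > 0) sum(below_annual | below_summer) / sum(evaluable) else 0
  list(series = evi_ts_like(series, series$date, series$evi, flag),
       report = report)
}

#' Savitzky-Golay smoothing configuration
#'
#' @param half_width number of composite steps on each side of the window
#'   (default 9, i.e. a 19-point window).
#' @param degree polynomial degree (default 3); must be below the window
#'   length `2 * half_width + 1`.
#' @return an `sg_config` list.
#' @export
sg_config <- function(half_width = 9, degree = 3) {
  if (degree >= 2 * half_width + 1)
    phen_error("phen_bad_input", "degree must be below the window length")
  structure(list(half_width = as.integer(half_width), degree = as.integer(degree)),
            class = "sg_config")
}

#' Savitzky-Golay smoothing of a composite series
#'
#' Applies a least-squares polynomial (Savitzky-Golay) filter to the series
#' values. Discarded and missing entries are linearly interpolated before
#' filtering so the filter sees a regular grid, and keep their flags
#' afterwards. Window edges use the filter's least-squares transient
#' treatment, which reproduces polynomials up to the filter degree exactly
#' at the boundaries — January and December values are smoothed, not
#' truncated.
#'
#' @param series an [evi_series()].
#' @param config an [sg_config()].
#' @return a smoothed `evi_ts` at the same dates with the same flags.
#' @export
smooth_savitzky_golay <- function(series, config = sg_config()) {
  stopifnot(inherits(series, "evi_ts"), inherits(config, "sg_config"))
  ok <- series$flag == "ok" & !is.na(series$evi)
  window <- 2L * config$half_width + 1L
  if (sum(ok) < window)
    phen_error("phen_too_few_points", sprintf(
      "pixel %s: %d valid points, need >= %d for smoothing",
      attr(series, "pixel_id"), sum(ok), window))
  x <- as.numeric(series$date)
  filled <- series$evi
  filled[!ok] <- stats::approx(x[ok], series$evi[ok], xout = x[!ok],
                               rule = 2)$y
  smoothed <- signal::sgolayfilt(filled, p = config$degree, n = window)
  evi_ts_like(series, series$date, smoothed, series$flag)
}
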