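#' Double-logistic model parameters
#'
#' Parameters of the greendown-capable double-logistic seasonal model
#' \deqn{f(t) = b + (A - g r(t)) [\sigma_{up}(t) - \sigma_{down}(t)]}
#' with \eqn{\sigma(t) = 1 / (1 + e^{-(t - m)/s})} and the smooth ramp
#' \eqn{r(t) = s_{up} \log(1 + e^{(t - t_{up})/s_{up}})}, which behaves as
#' \eqn{t - t_{up}} past the spring midpoint and vanishes before it. `b` is
#' the winter baseline, `A` the seasonal amplitude, `t_up`/`s_up` the spring
#' midpoint (day of year) and scale (days), `t_down`/`s_down` the autumn
#' midpoint and scale, and `greendown` the linear summer decline of the
#' effective amplitude (index units per day). The ramp is infinitely
#' differentiable, so the curvature-based phenometrics are well defined
#' everywhere; with `greendown = 0` the model reduces exactly to the plain
#' symmetric double logistic.
#'
#' @param baseline winter baseline value.
#' @param amplitude seasonal amplitude, > 0.
#' @param t_up,s_up spring midpoint (DOY) and scale (days), `s_up > 0`.
#' @param t_down,s_down autumn midpoint and scale, `t_down > t_up`, `s_down > 0`.
#' @param greendown linear summer decline per day (>= 0 in practice).
#' @return a `dl_params` list.
#' @export
dl_params <- function(baseline, amplitude, t_up, s_up, t_down, s_down,
                      greendown = 0) {
  if (amplitude <= 0) phen_error("phen_bad_input", "amplitude must be > 0")
  if (s_up <= 0 || s_down <= 0) phen_error("phen_bad_input", "scales must be > 0")
  if (t_up >= t_down) phen_error("phen_bad_input", "t_up must precede t_down")
  structure(list(baseline = baseline, amplitude = amplitude,
                 t_up = t_up, s_up = s_up, t_down = t_down, s_down = s_down,
                 greendown = greendown),
            class = "dl_params")
}

#' Evaluate the double-logistic model
#'
#' @param params a [dl_params()] object.
#' @param t day-of-year vector (may extend beyond the calendar year).
#' @return fitted values at `t`.
#' @export
evaluate_curve <- function(params, t) {
  p <- params
  s_up <- stats::plogis((t - p$t_up) / p$s_up)
  s_dn <- stats::plogis((t - p$t_down) / p$s_down)
  # softplus ramp: ~ (t - t_up) for t >> t_up, -> 0 for t << t_up
  ramp <- p$s_up * log1p(exp(-abs(t - p$t_up) / p$s_up)) +
    pmax(t - p$t_up, 0)
  amp <- p$amplitude - p$greendown * ramp
  p$baseline + amp * (s_up - s_dn)
}

## Analytic derivatives of the model. The softplus ramp r(t) has
## r' = sigma_up, r'' = sigma_up', r''' = sigma_up'', so every term below is
## smooth. logistic sigma: sigma' = sigma (1 - sigma) / s
##                 sigma'' = sigma (1 - sigma) (1 - 2 sigma) / s^2
##                 sigma''' = sigma (1 - sigma) (1 - 6 sigma + 6 sigma^2) / s^3
curve_derivative <- function(params, t, order = 1) {
  p <- params
  su <- stats::plogis((t - p$t_up) / p$s_up)
  sd <- stats::plogis((t - p$t_down) / p$s_down)
  d1u <- su * (1 - su) / p$s_up
  d1d <- sd * (1 - sd) / p$s_down
  d2u <- su * (1 - su) * (1 - 2 * su) / p$s_up^2
  d2d <- sd * (1 - sd) * (1 - 2 * sd) / p$s_down^2
  d3u <- su * (1 - su) * (1 - 6 * su + 6 * su^2) / p$s_up^3
  d3d <- sd * (1 - sd) * (1 - 6 * sd + 6 * sd^2) / p$s_down^3
  ramp <- p$s_up * log1p(exp(-abs(t - p$t_up) / p$s_up)) +
    pmax(t - p$t_up, 0)
  amp <- p$amplitude - p$greendown * ramp
  a1 <- -p$greendown * su          # amp'
  a2 <- -p$greendown * d1u         # amp''
  a3 <- -p$greendown * d2u         # amp'''
  S <- su - sd; S1 <- d1u - d1d; S2 <- d2u - d2d; S3 <- d3u - d3d
  switch(order,
         a1 * S + amp * S1,
         a2 * S + 2 * a1 * S1 + amp * S2,
         a3 * S + 3 * a2 * S1 + 3 * a1 * S2 + amp * S3)
}

## Curvature K = f'' / (1 + f'^2)^(3/2) and its rate of change
## K' = [f''' (1 + f'^2) - 3 f' f''^2] / (1 + f'^2)^(5/2)
curvature_rate <- function(params, t) {
  f1 <- curve_derivative(params, t, 1)
  f2 <- curve_derivative(params, t, 2)
  f3 <- curve_derivative(params, t, 3)
  (f3 * (1 + f1^2) - 3 * f1 * f2^2) / (1 + f1^2)^2.5
}

#' Daily fitted curve for one pixel-year
#'
#' Builds the daily-resolution reconstruction of a pixel-year from model
#' parameters: a day-of-year grid at 1-day step (padded past the year edges
#' so January transitions are not truncated), fitted values, and fit
#' diagnostics.
#'
#' @param params a [dl_params()] object.
#' @param year calendar year.
#' @param pixel_id pixel identifier.
#' @param pad_days days of padding on each side of the year (default 32).
#' @param fit_rmse root-mean-square residual of the fit (NA if not fitted).
#' @param converged logical convergence flag.
#' @return a `fitted_curve` list with fields `pixel_id`, `year`, `doy`,
#'   `values`, `params`, `fit_rmse`, `converged`.
#' @export
fitted_curve <- function(params, year, pixel_id = "px", pad_days = 32,
                         fit_rmse = NA_real_, converged = TRUE) {
  grid <- seq(1L - as.integer(pad_days),
              days_in_year(year) + as.integer(pad_days))
  structure(list(pixel_id = pixel_id, year = as.integer(year),
                 doy = grid, values = evaluate_curve(params, grid),
                 params = params, fit_rmse = fit_rmse, converged = converged),
            class = "fitted_curve")
}

#' @export
print.fitted_curve <- function(x, ...) {
  cat(sprintf(
    "<fitted_curve> pixel %s year %d: t_up %.1f (s %.1f), t_down %.1f (s %.1f), b %.3f, A %.3f, rmse %.4g, %s\n",
    x$pixel_id, x$year, x$params$t_up, x$params$s_up, x$params$t_down,
    x$params$s_down, x$params$baseline, x$params$amplitude, x$fit_rmse,
    if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

## deterministic multi-start jitter table (fractions of scale / days)
.jitter_table <- rbind(
  c(0,   0,   0,    0),
  c(-12, 0.5, 12,  -0.5),
  c(12, -0.5, -12,  0.5),
  c(-24, 1,   24,   1),
  c(24,  1,  -24,   1)
)

#' Fit the double-logistic model to one pixel-year
#'
#' Bounded nonlinear least squares on the ok entries of the year, with a
#' fitting window extended by `pad_days` into the neighbouring years when
#' those composites are present (January transitions sit near the year
#' edge). Starting values come from the data (baseline = 5th percentile,
#' amplitude = 95th - 5th percentile, midpoints from the half-amplitude
#' crossings, scales 10 days); if the first attempt does not converge a
#' small deterministic ladder of jittered starts is tried.
#'
#' @param series an [evi_series()] (typically smoothed composites spanning
#'   one or more years).
#' @param year calendar year to fit.
#' @param min_obs minimum number of ok entries required (default 10).
#' @param amplitude_floor seasonal amplitude below which the year is
#'   declared to have no seasonality (default 0.05).
#' @param pad_days fitting-window padding in days (default 32).
#' @param pixel_id pixel identifier; defaults to the series' own.
#' @return a [fitted_curve()].
#' @export
fit_double_logistic <- function(series, year, min_obs = 10,
                                amplitude_floor = 0.05, pad_days = 32,
                                pixel_id = NULL) {
  stopifnot(inherits(series, "evi_ts"))
  pixel_id <- pixel_id %||% attr(series, "pixel_id")
  jan1 <- as.Date(sprintf("%d-01-01", year))
  t_all <- as.numeric(series$date - jan1) + 1   # DOY relative to `year`
  ndays <- days_in_year(year)
  in_win <- t_all >= 1 - pad_days & t_all <= ndays + pad_days
  ok <- in_win & series$flag == "ok" & !is.na(series$evi)
  in_year_ok <- ok & t_all >= 1 & t_all <= ndays
  if (sum(in_year_ok) < min_obs)
    phen_error("phen_too_few_points", sprintf(
      "pixel %s year %d: %d ok entries, need >= %d",
      pixel_id, year, sum(in_year_ok), min_obs))
  t <- t_all[ok]; y <- series$evi[ok]

  q <- stats::quantile(y, c(0.05, 0.95), names = FALSE, type = 7)
  b0 <- q[1]; A0 <- q[2] - q[1]
  if (A0 < amplitude_floor)
    phen_error("phen_no_seasonality", sprintf(
      "pixel %s year %d: amplitude %.3f below floor %.3f",
      pixel_id, year, A0, amplitude_floor))

  half <- b0 + A0 / 2
  above <- y >= half
  t_up0 <- if (any(above)) t[which(above)[1]] else stats::median(t)
  t_dn0 <- if (any(above)) t[rev(which(above))[1]] else t_up0 + 120
  if (t_dn0 <= t_up0 + 20) t_dn0 <- t_up0 + 120

  lower <- c(baseline = -0.2, amplitude = amplitude_floor,
             t_up = 1 - pad_days, s_up = 1,
             t_down = 1 - pad_days, s_down = 1, greendown = 0)
  upper <- c(baseline = 0.6, amplitude = 1.2,
             t_up = ndays + pad_days, s_up = 60,
             t_down = ndays + pad_days, s_down = 60, greendown = 0.01)

  resid_fn <- function(par) {
    p <- list(baseline = par[1], amplitude = par[2], t_up = par[3],
              s_up = par[4], t_down = par[5], s_down = par[6],
              greendown = par[7])
    evaluate_curve(p, t) - y
  }

  best <- NULL
  for (k in seq_len(nrow(.jitter_table))) {
    j <- .jitter_table[k, ]
    start <- c(b0, A0, t_up0 + j[1], 10 * (1 + 0.2 * j[2]),
               t_dn0 + j[3], 10 * (1 + 0.2 * j[4]), 0)
    start <- pmin(pmax(start, lower), upper)
    if (start[3] >= start[5]) start[5] <- min(start[3] + 60, upper[5])
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = 1e-10, ptol = 1e-10, maxiter = 400)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rmse <- sqrt(mean(fit$fvec^2))
    conv <- fit$info %in% 1:4 && fit$par[3] < fit$par[5]
    if (conv && (is.null(best) || rmse < best$rmse - 1e-12)) {
      best <- list(par = fit$par, rmse = rmse)
      if (rmse < 5e-3) break   # good enough; stop the ladder
    }
  }

  if (is.null(best)) {
    p0 <- dl_params(b0, max(A0, amplitude_floor), t_up0, 10,
                    max(t_dn0, t_up0 + 30), 10, 0)
    return(fitted_curve(p0, year, pixel_id, pad_days,
                        fit_rmse = NA_real_, converged = FALSE))
  }
  par <- best$par
  params <- dl_params(par[1], par[2], par[3], par[4], par[5], par[6], par[7])
  fitted_curve(params, year, pixel_id, pad_days,
               fit_rmse = best$rmse, converged = TRUE)
}

#' Season geometry of a fitted curve
#'
#' Locates the seasonal peak (argmax of the daily values, earliest day on
#' ties) and the pre-season trough (argmin over days before the peak), and
#' reports the baseline value, peak value and annual amplitude used by the
#' threshold and Gu phenometrics. A peak on the first or last grid day
#' triggers a boundary-season warning and marks the geometry low-confidence.
#'
#' @param curve a [fitted_curve()].
#' @return a `season_geometry` list: `trough_doy`, `peak_doy`,
#'   `baseline_value`, `peak_value`, `amplitude`, `low_confidence`.
#' @export
derive_season_geometry <- function(curve) {
  stopifnot(inherits(curve, "fitted_curve"))
  if (!isTRUE(curve$converged))
    phen_error("phen_not_converged", "cannot derive geometry of unconverged curve")
  v <- curve$values; g <- curve$doy
  peak_i <- which.max(v)
  trough_i <- which.min(v[seq_len(peak_i)])
  low_conf <- FALSE
  if (peak_i %in% c(1L, length(v))) {
    warning("seasonal peak lies on the grid boundary; metrics low-confidence",
            call. = FALSE)
    low_conf <- TRUE
  }
  amp <- v[peak_i] - v[trough_i]
  if (amp <= 0) phen_error("phen_no_seasonality", "non-positive amplitude")
  structure(list(trough_doy = g[trough_i], peak_doy = g[peak_i],
                 baseline_value = v[trough_i], peak_value = v[peak_i],
                 amplitude = amp, low_confidence = low_conf),
            class = "season_geometry")
}
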