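#' Simulation configuration
#'
#' Study conditions for the synthetic fixture: ~20 orchard pixels observed
#' as 8-day composites over several years, each pixel-year a double-logistic
#' season with winter baseline 0.15-0.30, amplitude 0.3-0.6 and spring
#' midpoint around DOY 85-110 (a Black-Sea-like deciduous orchard setting),
#' plus additive Gaussian noise, random composite dropouts and an optional
#' early understory-greening bump. Ground phases are placed at configured
#' offsets from true phenometrics and observed by weekly surveys.
#'
#' @param n_pixels number of orchard pixels (default 20).
#' @param years calendar years simulated (default 2019:2022; at most 6).
#' @param cadence_days composite cadence (default 8).
#' @param baseline_range,amplitude_range,midpoint_range,s_up_range,t_down_range,s_down_range,greendown_range
#'   per-pixel base parameter draw ranges. Each pixel keeps its base
#'   parameters across years (a site property), with small seeded
#'   interannual deviations controlled by `interannual`.
#' @param interannual list of interannual jitter standard deviations:
#'   `t_sd` (days, midpoints), `value_sd` (index units, baseline),
#'   `amp_sd` (index units, amplitude), `scale_sd` (days, scales).
#' @param noise_sd additive Gaussian noise on sampled composites (default 0.02).
#' @param dropout_prob probability a composite is missing (default 0.1).
#' @param understory `NULL`, or list `amplitude`, `center_doy`, `width_days`
#'   for a Gaussian understory-greening bump added to the observations (not
#'   to the truth curve); `understory = "default"` gives amplitude 0.05 at
#'   DOY 45, width 15.
#' @param coverage_range per-pixel hazelnut coverage fraction draw range.
#' @param east_shift_days added to the spring midpoint of East-region pixels
#'   (second half of the ids), giving the two regions distinct phenology.
#' @param phase_links data.frame `bbch`, `metric`, `offset_days`: the true
#'   phase date is the linked true metric plus the offset (so the pipeline
#'   bias metric - phase should recover minus the offset).
#' @param phase_jitter_sd Gaussian jitter of true phase dates (default 4 d).
#' @param survey_weekday weekday of the weekly survey visit (1 = Monday).
#' @param seed base seed; per-pixel-year substreams are derived from it so
#'   adding pixels or years never changes earlier pixels' draws.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_pixels = 20, years = 2019:2022, cadence_days = 8,
                       baseline_range = c(0.15, 0.30),
                       amplitude_range = c(0.3, 0.6),
                       midpoint_range = c(85, 110),
                       s_up_range = c(6, 15),
                       t_down_range = c(270, 300),
                       s_down_range = c(6, 15),
                       greendown_range = c(0, 5e-4),
                       interannual = list(t_sd = 4, value_sd = 0.01,
                                          amp_sd = 0.02, scale_sd = 1),
                       noise_sd = 0.02, dropout_prob = 0.1,
                       understory = NULL,
                       coverage_range = c(0.3, 1),
                       east_shift_days = 10,
                       phase_links = default_phase_links(),
                       phase_jitter_sd = 4,
                       survey_weekday = 1,
                       seed = 42) {
  if (identical(understory, "default"))
    understory <- list(amplitude = 0.05, center_doy = 45, width_days = 15)
  ranges <- list(baseline_range, amplitude_range, midpoint_range, s_up_range,
                 t_down_range, s_down_range, greendown_range, coverage_range)
  if (any(vapply(ranges, function(r) r[1] > r[2], logical(1))))
    phen_error("phen_bad_input", "parameter ranges must be ordered")
  if (amplitude_range[1] <= 0)
    phen_error("phen_bad_input", "amplitude range must be positive")
  if (dropout_prob < 0 || dropout_prob > 1)
    phen_error("phen_bad_input", "dropout_prob must be in [0, 1]")
  if (length(years) > 6)
    phen_error("phen_bad_input", "at most 6 years per simulation")
  structure(as.list(environment()), class = "sim_config")
}

#' Default BBCH-phase to phenometric links
#'
#' Offsets (phase date minus linked true metric, days) chosen to emulate the
#' ordering observed in hazelnut: female flowering well before greenup,
#' budbreak near the 20% threshold, leaf phases around the 50% threshold,
#' clusters visible near the Gu stabilization date. These are test
#' scaffolding for the generator, not biological claims.
#'
#' @return data.frame `bbch`, `metric`, `offset_days`.
#' @export
default_phase_links <- function() {
  data.frame(
    bbch = c("61P", "64P", "67P", "70P", "71P",
             "03VP", "07VP", "10V", "13V", "15V"),
    metric = c("greenup", "gu_ud", "gu_ud", "der_sos", "gu_sd",
               "trs2_sos", "trs2_sos", "trs5_sos", "trs5_sos", "trs5_sos"),
    offset_days = c(-15, -2, 20, -5, 5, 3, 14, 0, 17, 39)
  )
}

understory_bump <- function(t, understory) {
  if (is.null(understory)) return(0)
  understory$amplitude *
    exp(-0.5 * ((t - understory$center_doy) / understory$width_days)^2)
}

#' Simulate pixel EVI time series with known truth
#'
#' For every pixel-year, draws double-logistic parameters from the
#' configured ranges in a seeded per-pixel-year substream, computes the true
#' phenometrics of the noiseless curve with the dense-grid brute-force
#' oracle, then samples the curve at the composite cadence, adds the
#' optional understory bump, Gaussian noise and dropouts.
#'
#' @param config a [sim_config()].
#' @return list with `series` (named list of [evi_series()], one per pixel,
#'   spanning all years), `truth` (per pixel-year parameters + true metrics),
#'   `phase_truth` (per pixel-year-BBCH true phase dates), `metadata`
#'   (pixel coordinates, coverage, region) and `config`.
#' @export
simulate_series <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  runifr <- function(r) stats::runif(1, r[1], r[2])
  n_side <- ceiling(sqrt(cfg$n_pixels))
  series <- list(); truth <- list(); phase_truth <- list(); meta <- list()
  for (i in seq_len(cfg$n_pixels)) {
    pid <- sprintf("px%02d", i)
    # parity-based so region assignment never depends on n_pixels
    region <- if (i %% 2 == 1L) "West" else "East"
    meta[[i]] <- with_seed(derive_seed(cfg$seed, i, 7L), data.frame(
      pixel_id = pid,
      longitude = 31 + ((i - 1) %% n_side) * 0.0025 +
        if (region == "East") 6 else 0,
      latitude = 41 + ((i - 1) %/% n_side) * 0.0025,
      coverage = runifr(cfg$coverage_range),
      region = region))
    # per-pixel site parameters, constant across years (lane 0)
    base <- with_seed(derive_seed(cfg$seed, i, 0L), list(
      baseline = runifr(cfg$baseline_range),
      amplitude = runifr(cfg$amplitude_range),
      t_up = runifr(cfg$midpoint_range) +
        if (region == "East") cfg$east_shift_days else 0,
      s_up = runifr(cfg$s_up_range),
      t_down = runifr(cfg$t_down_range),
      s_down = runifr(cfg$s_down_range),
      greendown = runifr(cfg$greendown_range)))
    px_dates <- c(); px_evi <- c(); px_flag <- c()
    for (j in seq_along(cfg$years)) {
      year <- cfg$years[j]
      drawn <- with_seed(derive_seed(cfg$seed, i, j), {
        ia <- cfg$interannual
        p <- dl_params(
          baseline = base$baseline + stats::rnorm(1, 0, ia$value_sd),
          amplitude = max(base$amplitude + stats::rnorm(1, 0, ia$amp_sd), 0.1),
          t_up = base$t_up + stats::rnorm(1, 0, ia$t_sd),
          s_up = max(base$s_up + stats::rnorm(1, 0, ia$scale_sd), 3),
          t_down = base$t_down + stats::rnorm(1, 0, ia$t_sd),
          s_down = max(base$s_down + stats::rnorm(1, 0, ia$scale_sd), 3),
          greendown = base$greendown)
        jan1 <- as.Date(sprintf("%d-01-01", year))
        n_periods <- (days_in_year(year) - 1L) %/% cfg$cadence_days + 1L
        start_doy <- (seq_len(n_periods) - 1L) * cfg$cadence_days + 1L
        clean <- evaluate_curve(p, start_doy)
        obs <- clean + understory_bump(start_doy, cfg$understory) +
          stats::rnorm(n_periods, 0, cfg$noise_sd)
        obs <- pmin(pmax(obs, -1), 1)
        drop <- stats::runif(n_periods) < cfg$dropout_prob
        list(p = p, dates = jan1 + start_doy - 1L,
             evi = ifelse(drop, NA_real_, obs),
             flag = ifelse(drop, "missing", "ok"))
      })
      p <- drawn$p
      tm <- phenometrics_bruteforce(function(t) evaluate_curve(p, t))
      truth[[length(truth) + 1L]] <- data.frame(
        pixel_id = pid, year = year,
        baseline = p$baseline, amplitude = p$amplitude,
        t_up = p$t_up, s_up = p$s_up, t_down = p$t_down,
        s_down = p$s_down, greendown = p$greendown,
        as.list(tm))
      phase_truth[[length(phase_truth) + 1L]] <- data.frame(
        pixel_id = pid, year = year, bbch = cfg$phase_links$bbch,
        true_doy = as.numeric(tm[cfg$phase_links$metric]) +
          cfg$phase_links$offset_days)
      px_dates <- c(px_dates, drawn$dates)
      px_evi <- c(px_evi, drawn$evi)
      px_flag <- c(px_flag, drawn$flag)
    }
    series[[pid]] <- evi_series(pid, as.Date(px_dates, origin = "1970-01-01"),
                                px_evi, px_flag, cadence = cfg$cadence_days)
  }
  list(series = series,
       truth = do.call(rbind, truth),
       phase_truth = do.call(rbind, phase_truth),
       metadata = do.call(rbind, meta),
       config = cfg)
}

#' Simulate weekly ground surveys from phase truth
#'
#' Each orchard (one per pixel) is visited weekly on the configured weekday.
#' The realized date of a phase is its true date plus seeded Gaussian
#' jitter; the phase is recorded on the first visit on or after that date,
#' so first-seen onsets overshoot truth by at most 6 days at zero jitter.
#'
#' @param sim a [simulate_series()] result.
#' @param config a [sim_config()]; defaults to the one stored in `sim`.
#' @return data.frame `orchard_id`, `date`, `code` (survey rows, one per
#'   recorded phase onset observation), sorted by orchard and date.
#' @export
simulate_surveys <- function(sim, config = sim$config) {
  cfg <- config
  links <- cfg$phase_links
  pt <- sim$phase_truth
  rows <- list()
  pixel_index <- stats::setNames(seq_along(sim$series), names(sim$series))
  # one jitter substream per pixel-year (base shifted so it never reuses the
  # series-sampling substream), all phases drawn at once
  jitter_of <- function(i, j) with_seed(
    derive_seed(cfg$seed + 1L, i, j),
    stats::rnorm(nrow(links), 0, cfg$phase_jitter_sd))
  for (r in seq_len(nrow(pt))) {
    pid <- pt$pixel_id[r]; year <- pt$year[r]
    if (is.na(pt$true_doy[r])) next
    i <- pixel_index[[pid]]; j <- match(year, cfg$years)
    jit <- jitter_of(i, j)[match(pt$bbch[r], links$bbch)]
    # realized onset: first whole day on which the phase is visible
    real_date <- as.Date(sprintf("%d-01-01", year)) +
      ceiling(pt$true_doy[r] + jit) - 1L
    # first weekly visit on/after the realized date
    wd <- as.integer(format(real_date, "%u"))
    visit <- real_date + (cfg$survey_weekday - wd) %% 7
    rows[[length(rows) + 1L]] <- data.frame(
      orchard_id = pid, date = visit, code = pt$bbch[r])
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$orchard_id, out$date, out$code), , drop = FALSE]
  rownames(out) <- NULL
  out
}
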