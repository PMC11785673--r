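# shared fixtures: standard curves and sampled series, built in code

# single-logistic rising limb: autumn transition pushed far beyond the grid
limb_params <- function(b = 0.2, A = 0.5, m = 100, s = 10) {
  dl_params(baseline = b, amplitude = A, t_up = m, s_up = s,
            t_down = 600, s_down = 10, greendown = 0)
}

# full-season curve with both transitions inside the year
season_params <- function(b = 0.2, A = 0.5, t_up = 100, s_up = 10,
                          t_down = 280, s_down = 12, g = 0) {
  dl_params(b, A, t_up, s_up, t_down, s_down, g)
}

# sample a params curve at composite cadence over one year
sample_series <- function(params, year = 2021, cadence = 8, noise_sd = 0,
                          seed = 1, pixel_id = "px") {
  jan1 <- as.Date(sprintf("%d-01-01", year))
  n <- (phenomatch:::days_in_year(year) - 1L) %/% cadence + 1L
  d <- (seq_len(n) - 1L) * cadence + 1L
  v <- evaluate_curve(params, d)
  if (noise_sd > 0)
    v <- v + phenomatch:::with_seed(seed, rnorm(n, 0, noise_sd))
  evi_series(pixel_id, jan1 + d - 1L, pmin(pmax(v, -1), 1), cadence = cadence)
}

# draw generator-range parameters in a seeded substream
draw_params <- function(seed) {
  phenomatch:::with_seed(seed, season_params(
    b = runif(1, 0.15, 0.30), A = runif(1, 0.3, 0.6),
    t_up = runif(1, 85, 110), s_up = runif(1, 6, 15),
    t_down = runif(1, 270, 300), s_down = runif(1, 6, 15),
    g = runif(1, 0, 5e-4)))
}

bruteforce_of <- function(params) {
  phenometrics_bruteforce(function(t) evaluate_curve(params, t))
}
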