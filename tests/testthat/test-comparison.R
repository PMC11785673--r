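pairs_of <- function(metric, phase) {
  structure(data.frame(orchard_id = sprintf("o%d", seq_along(metric)),
                       year = rep(2021L, length(metric)),
                       metric_doy = metric, phase_doy = phase),
            class = c("metric_phase_pairs", "data.frame"))
}

test_that("bias and RMSD follow their hand formulas and sign convention", {
  p <- pairs_of(c(63, 74), c(60, 70))   # differences 3 and 4
  expect_equal(bias_days(p), 3.5)
  expect_equal(rmsd_days(p), sqrt(12.5))
  expect_equal(bias_days(pairs_of(c(50, 60), c(50, 60))), 0)
  # a metric 15 days after the ground phase gives bias +15
  expect_equal(bias_days(pairs_of(c(115, 130, 90), c(100, 115, 75))), 15)
  expect_error(bias_days(pairs_of(numeric(), numeric())),
               class = "phen_undefined")
  expect_error(rmsd_days(pairs_of(numeric(), numeric())),
               class = "phen_undefined")
})

test_that("rmsd dominates |bias| and their gap is the difference variance", {
  set.seed(9)
  for (i in 1:10) {
    d <- sample(30:150, 12)
    p <- pairs_of(d + rnorm(12, 2, 5), d)
    expect_gte(rmsd_days(p), abs(bias_days(p)))
    diffs <- p$metric_doy - p$phase_doy
    expect_equal(rmsd_days(p)^2 - bias_days(p)^2,
                 mean((diffs - mean(diffs))^2), tolerance = 1e-9)
    # both are invariant to row order
    shuf <- p[sample(nrow(p)), ]
    expect_equal(bias_days(shuf), bias_days(p))
    expect_equal(rmsd_days(shuf), rmsd_days(p))
  }
})

test_that("Spearman correlation handles monotone, tied and constant inputs", {
  inc <- pairs_of(1:12, (1:12)^2)
  expect_equal(spearman_rs(inc)$r_s, 1)
  dec <- pairs_of(1:12, 40 - (1:12)^3 / 10)
  expect_equal(spearman_rs(dec)$r_s, -1)

  # tie handling equals a brute-force rank-then-Pearson computation
  x <- c(10, 20, 20, 35, 50, 65); y <- c(5, 12, 18, 20, 33, 31)
  got <- spearman_rs(pairs_of(x, y))
  expect_equal(got$r_s, stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_equal(got$method, "exact-permutation")

  # invariant under strictly monotone transforms of either column
  p <- pairs_of(c(30, 45, 60, 80, 95, 110, 130, 150, 170, 190),
                c(28, 50, 55, 85, 90, 105, 140, 145, 180, 185))
  r0 <- spearman_rs(p)$r_s
  expect_equal(spearman_rs(pairs_of(exp(p$metric_doy / 50), p$phase_doy))$r_s, r0)
  expect_equal(spearman_rs(pairs_of(p$metric_doy, p$phase_doy^3))$r_s, r0)

  const <- spearman_rs(pairs_of(rep(100, 5), c(1, 2, 3, 4, 5)))
  expect_true(is.na(const$r_s))
  expect_equal(const$method, "undefined_constant_column")
  expect_error(spearman_rs(pairs_of(1:2, 1:2)), class = "phen_undefined")
})

test_that("permutation p-values agree with the t approximation in spirit", {
  # a clear monotone signal is significant under both regimes
  small <- pairs_of(c(60, 70, 80, 90, 100, 110), c(55, 68, 77, 95, 101, 118))
  expect_lt(spearman_rs(small)$p_value, 0.05)
  big <- pairs_of(seq(50, 160, by = 10) + c(2, -3, 1, 0, -2, 3, 1, -1, 2, 0, -2, 1),
                  seq(50, 160, by = 10))
  res <- spearman_rs(big)
  expect_equal(res$method, "t-approximation")
  expect_lt(res$p_value, 0.01)
})

test_that("date distributions summarize with linear-interpolation percentiles", {
  s <- summarize_dates(c(10, 20, 30, 40))
  expect_equal(s$p50, 25)
  expect_equal(s$p25, 17.5)
  one <- summarize_dates(77)
  expect_equal(c(one$p25, one$p50, one$p75), c(77, 77, 77))
  set.seed(3)
  r <- summarize_dates(sample(1:365, 40, replace = TRUE))
  expect_true(r$p25 <= r$p50 && r$p50 <= r$p75)
  expect_error(summarize_dates(numeric()), class = "phen_undefined")
})

test_that("pairing inner-joins orchard-years and counts the unpaired", {
  metrics <- data.frame(pixel_id = c("p1", "p1", "p2", "p2"),
                        year = c(2020, 2021, 2020, 2021),
                        trs5_sos = c(95, 100, 105, NA))
  onsets <- data.frame(orchard_id = c("o1", "o1", "o2"),
                       year = c(2020, 2021, 2020),
                       bbch = "10V", onset_doy = c(93, 99, 104), n_obs = 1L)
  link <- data.frame(pixel_id = c("p1", "p2"), orchard_id = c("o1", "o2"))
  pr <- pair_metric_phase(metrics, onsets, "trs5_sos", "10V", link)
  expect_equal(nrow(pr), 3L)
  # p2/2021 has a missing metric and o2/2021 no onset: absent, not NA
  expect_false(any(is.na(pr$metric_doy)))
  expect_error(pair_metric_phase(metrics, onsets, "nope", "10V", link))
  expect_warning(pair_metric_phase(metrics, onsets, "trs5_sos", "61P", link),
                 "no paired")
})

test_that("independent 10% missingness on each side pairs ~81% of 80 rows", {
  ns <- vapply(1:30, function(k) {
    set.seed(4000 + k)
    grid <- expand.grid(pixel_id = sprintf("p%02d", 1:20), year = 2019:2022,
                        stringsAsFactors = FALSE)
    m <- grid; m$trs5_sos <- ifelse(runif(80) < 0.1, NA, 100)
    o <- data.frame(orchard_id = grid$pixel_id, year = grid$year,
                    bbch = "10V", onset_doy = 98, n_obs = 1L)
    o <- o[runif(80) >= 0.1, ]
    nrow(suppressWarnings(pair_metric_phase(m, o, "trs5_sos", "10V")))
  }, numeric(1))
  # E[n] = 80 * 0.9 * 0.9 = 64.8, sd(n) ~ 3.5, so the mean of 30 draws
  # should sit within ~2 of the expectation
  expect_lt(abs(mean(ns) - 64.8), 2)
})

test_that("compare_all fills the metric-by-phase matrix and stratifies", {
  set.seed(5)
  grid <- expand.grid(pixel_id = sprintf("p%02d", 1:12), year = 2019:2022,
                      stringsAsFactors = FALSE)
  metrics <- grid
  for (m in c("der_sos", "der_pos", "trs2_sos", "trs5_sos",
              "gu_ud", "gu_sd", "greenup", "maturity"))
    metrics[[m]] <- sample(40:170, nrow(grid), replace = TRUE)
  onsets <- do.call(rbind, lapply(bbch_phases()$code, function(ph) {
    data.frame(orchard_id = grid$pixel_id, year = grid$year, bbch = ph,
               onset_doy = sample(30:160, nrow(grid), replace = TRUE),
               n_obs = 1L)
  }))
  cmp <- compare_all(metrics, onsets)
  expect_equal(nrow(cmp), 80L)   # 8 metrics x 10 phases, one stratum
  expect_true(all(cmp$rmsd >= abs(cmp$bias) - 1e-12))

  cov <- data.frame(pixel_id = sprintf("p%02d", 1:12),
                    coverage = rep(c(0.9, 0.5), 6))
  strat <- compare_all(metrics, onsets, coverage = cov)
  hi <- strat[strat$stratum == "coverage_ge_split", ]
  lo <- strat[strat$stratum == "coverage_lt_split", ]
  all_n <- strat[strat$stratum == "all", ]
  one <- function(d) d$n[d$metric == "trs5_sos" & d$phase == "10V"]
  expect_equal(one(hi) + one(lo), one(all_n))

  adj <- compare_all(metrics, onsets, p_adjust = TRUE)
  expect_true(all(adj$p_value >= cmp$p_value - 1e-12))
})
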