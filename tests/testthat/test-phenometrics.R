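# closed forms on a single-logistic rising limb (baseline b, amplitude A,
# midpoint m, scale s): trs5 = m, trs2 = m - s ln 4, der_sos = m,
# gu_ud = m - 2s, gu_sd = m + 2s (tangent slope A/4s at the midpoint)

test_that("threshold metrics match the logistic closed forms", {
  cv <- fitted_curve(limb_params(b = 0.2, A = 0.5, m = 100, s = 10), 2021)
  g <- suppressWarnings(derive_season_geometry(cv))
  expect_equal(extract_trs(cv, g, 0.5), 100L)
  expect_equal(extract_trs(cv, g, 0.2), as.integer(round(100 - 10 * log(4))))
  expect_lt(abs(extract_trs(cv, g, 0.2) - (100 - 10 * log(4))), 1)
  expect_error(extract_trs(cv, g, 1.5), "fraction")
  expect_error(extract_trs(cv, g, 0), "fraction")
})

test_that("derivative metrics find the inflection and the peak", {
  cv <- fitted_curve(limb_params(m = 100, s = 10), 2021)
  g <- suppressWarnings(derive_season_geometry(cv))
  der <- extract_der(cv, g)
  expect_equal(der[["der_sos"]], 100L)
  # peak equals a brute-force scan of the daily values
  expect_equal(der[["der_pos"]], cv$doy[which.max(cv$values)])
  # plateaued maximum: the earlier day wins the tie
  expect_equal(g$peak_doy, cv$doy[which(cv$values == max(cv$values))[1]])
})

test_that("Gu tangent dates hit m - 2s and m + 2s on the logistic limb", {
  for (s in c(6, 10, 14)) {
    cv <- fitted_curve(limb_params(m = 100, s = s), 2021)
    g <- suppressWarnings(derive_season_geometry(cv))
    gu <- extract_gu(cv, g)
    expect_equal(gu[["gu_ud"]], as.integer(100 - 2 * s))
    expect_equal(gu[["gu_sd"]], as.integer(100 + 2 * s))
  }
})

test_that("Zhang curvature dates match the brute-force dense-grid search", {
  p <- limb_params(m = 100, s = 10)
  cv <- fitted_curve(p, 2021)
  g <- suppressWarnings(derive_season_geometry(cv))
  z <- extract_zhang(cv, g)
  bf <- bruteforce_of(p)
  expect_lte(abs(z[["greenup"]] - bf[["greenup"]]), 1)
  expect_lte(abs(z[["maturity"]] - bf[["maturity"]]), 1)
  expect_lt(z[["greenup"]], z[["maturity"]])
})

test_that("the eight metrics keep their temporal ordering on a logistic limb", {
  cv <- fitted_curve(limb_params(m = 100, s = 10), 2021)
  m <- extract_all(cv)$metrics
  expect_true(m[["greenup"]] < m[["gu_ud"]])
  expect_true(m[["gu_ud"]] < m[["trs2_sos"]])
  expect_true(m[["trs2_sos"]] < m[["trs5_sos"]])
  expect_true(m[["trs5_sos"]] <= m[["der_sos"]])
  expect_true(m[["der_sos"]] < m[["gu_sd"]])
  expect_true(m[["gu_sd"]] < m[["maturity"]])
  expect_true(m[["maturity"]] <= m[["der_pos"]])
})

test_that("extract_all equals the individual extractors and collects reasons", {
  cv <- fitted_curve(season_params(), 2021)
  set <- extract_all(cv)
  g <- derive_season_geometry(cv)
  expect_equal(set$metrics[["trs2_sos"]], extract_trs(cv, g, 0.2))
  expect_equal(set$metrics[["trs5_sos"]], extract_trs(cv, g, 0.5))
  expect_equal(set$metrics[c("der_sos", "der_pos")],
               extract_der(cv, g)[c("der_sos", "der_pos")])
  expect_equal(set$metrics[c("gu_ud", "gu_sd")],
               extract_gu(cv, g)[c("gu_ud", "gu_sd")])
  expect_equal(set$metrics[c("greenup", "maturity")],
               extract_zhang(cv, g)[c("greenup", "maturity")])
  expect_length(set$reasons, 0)

  # an unconverged curve propagates one reason for the whole set
  bad <- fitted_curve(season_params(), 2021, converged = FALSE)
  all_missing <- extract_all(bad)
  expect_true(all(is.na(all_missing$metrics)))
  expect_equal(all_missing$reasons$all, "fit_not_converged")

  df <- as.data.frame(set)
  expect_equal(nrow(df), 1L)
  expect_true(all(c("der_sos", "der_pos", "trs2_sos", "trs5_sos", "gu_ud",
                    "gu_sd", "greenup", "maturity") %in% names(df)))
})

test_that("translating the season shifts every metric by the same amount", {
  base <- extract_all(fitted_curve(season_params(t_up = 95, t_down = 275),
                                   2021))$metrics
  for (d in c(-14L, 9L, 21L)) {
    shifted <- extract_all(fitted_curve(
      season_params(t_up = 95 + d, t_down = 275 + d), 2021))$metrics
    expect_equal(shifted, base + d)
  }
})

test_that("rescaling the seasonal amplitude leaves all eight dates unchanged", {
  p <- season_params(b = 0.2, A = 0.4, g = 2e-4)
  base <- extract_all(fitted_curve(p, 2021))$metrics
  for (c in c(0.5, 2)) {
    ps <- season_params(b = 0.2, A = 0.4 * c, g = 2e-4 * c)
    expect_equal(extract_all(fitted_curve(ps, 2021))$metrics, base)
  }
})

test_that("trs2 never follows trs5 and metrics agree with brute force", {
  for (k in 1:20) {
    p <- draw_params(700 + k)
    m <- extract_all(fitted_curve(p, 2021))$metrics
    expect_lte(m[["trs2_sos"]], m[["trs5_sos"]])
    bf <- bruteforce_of(p)
    for (nm in names(bf))
      if (!is.na(bf[[nm]]) && !is.na(m[[nm]]))
        expect_lte(abs(m[[nm]] - bf[[nm]]), 1)
  }
})

test_that("degenerate metrics go missing with a reason instead of failing", {
  # slope forced non-positive cannot happen on a valid curve, but a curve
  # whose threshold is never crossed reports a reason
  p <- limb_params(m = 100, s = 10)
  cv <- fitted_curve(p, 2021)
  g <- suppressWarnings(derive_season_geometry(cv))
  g$baseline_value <- g$peak_value + 1   # impossible threshold
  g$amplitude <- 0.1
  res <- extract_trs(cv, g, 0.5)
  expect_true(is.na(res))
  expect_equal(attr(res, "reason"), "no_threshold_crossing")
})
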