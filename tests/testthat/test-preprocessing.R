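test_that("EVI formula matches hand arithmetic and handles invalid samples", {
  # numerator vanishes when NIR equals red
  expect_equal(as.numeric(compute_evi(0.3, 0.3, 0.1)), 0)
  # hand-computed: 2.5 * 0.3 / (0.4 + 6*0.1 - 7.5*0.05 + 1) = 0.75/1.625
  expect_equal(as.numeric(compute_evi(0.4, 0.1, 0.05)), 2.5 * 0.3 / 1.625,
               tolerance = 1e-12)
  # omitting coefficients is the same as passing the standard MODIS set
  expect_identical(compute_evi(0.37, 0.12, 0.06),
                   compute_evi(0.37, 0.12, 0.06,
                               evi_coefficients(2.5, 6, 7.5, 1)))
  # near-zero denominator is an invalid sample, not a crash:
  # rho_blue chosen so rho_nir + 6 rho_red - 7.5 rho_blue + 1 = 0
  expect_true(is.na(as.numeric(compute_evi(0.1, 0.1, (0.1 + 0.6 + 1) / 7.5))))
  expect_equal(attr(compute_evi(0.1, 0.1, (0.1 + 0.6 + 1) / 7.5), "invalid"),
               "denominator")
  # out-of-range result flagged invalid rather than clipped
  big <- compute_evi(0.9, 0.05, 0.16)
  if (is.na(as.numeric(big))) expect_equal(attr(big, "invalid"), "out_of_range")
  expect_error(compute_evi(1.2, 0.1, 0.1), "0, 1")
})

test_that("EVI sign flips when NIR and red are swapped (numerator negates)", {
  set.seed(11)
  for (i in 1:20) {
    r <- round(runif(3, 0.02, 0.6), 3)
    if (r[1] == r[2]) next
    a <- as.numeric(compute_evi(r[1], r[2], r[3]))
    b <- as.numeric(compute_evi(r[2], r[1], r[3]))
    # denominators stay positive for reflectances in this range, so the
    # sign of EVI follows the sign of the numerator
    if (!is.na(a) && !is.na(b)) expect_equal(sign(a), -sign(b))
  }
})

test_that("MVC keeps the period maximum and emits the composite calendar", {
  d <- as.Date("2021-01-01") + 0:7
  s <- evi_series("p", d[c(1, 4, 7)], c(0.2, 0.5, 0.3), cadence = 1)
  out <- composite_mvc(s, 8)
  expect_equal(out$evi[1], 0.5)

  # one non-leap year at 8 days: 46 periods, last starting Dec 27
  full <- evi_series("p", as.Date("2021-01-01") + 0:364,
                     rep(0.2, 365), cadence = 1)
  cal <- composite_mvc(full, 8)
  expect_equal(nrow(cal), 46L)
  expect_equal(cal$date[46], as.Date("2021-12-27"))
  expect_equal(attr(cal, "cadence"), 8L)

  # all entries of a period missing -> flagged missing
  gap <- evi_series("p", d, c(NA, NA, NA, NA, NA, NA, NA, NA),
                    flag = rep("missing", 8), cadence = 1)
  expect_equal(composite_mvc(gap, 8)$flag[1], "missing")

  # brute-force period maximum property on a random daily year
  set.seed(4)
  vals <- runif(365, 0, 0.9)
  ts <- evi_series("p", as.Date("2021-01-01") + 0:364, vals, cadence = 1)
  cmp <- composite_mvc(ts, 8)
  idx <- (0:364) %/% 8
  ref <- tapply(vals, idx, max)
  expect_equal(cmp$evi, as.numeric(ref))

  # empty input -> empty output
  empty <- evi_series("p", as.Date(character()), numeric())
  expect_equal(nrow(composite_mvc(empty, 8)), 0L)
})

test_that("expert filter discards exactly the violating entries and counts once", {
  dates <- as.Date(c("2021-03-15", "2021-04-10", "2021-06-20",
                     "2021-07-10", "2021-08-31", "2021-09-01"))
  evi <- c(0.05, 0.25, 0.05, 0.25, 0.29, 0.29)
  s <- evi_series("p", dates, evi)
  res <- apply_quality_filter(s)
  # annual floor: 0.05 in March and June; summer floor: 0.25 Jul, 0.29 Aug 31;
  # 0.25 in April and 0.29 in September pass (outside the summer window)
  expect_equal(res$series$flag,
               c("discarded", "ok", "discarded", "discarded", "discarded", "ok"))
  expect_equal(res$report$count[res$report$rule == "annual_min"], 2L)
  expect_equal(res$report$count[res$report$rule == "summer_min"], 2L)
  # June entry below both floors is counted once, under the annual rule
  expect_equal(attr(res$report, "n_discarded"), sum(res$report$count))
  expect_equal(attr(res$report, "fraction"), 4 / 6)
})

test_that("quality rules validate and the summer window is configurable", {
  expect_error(quality_rules(annual_min = 0.4, summer_min = 0.3))
  r <- quality_rules(summer_window = c("05-01", "09-30"))
  s <- evi_series("p", as.Date("2021-05-10"), 0.25)
  expect_equal(apply_quality_filter(s, r)$series$flag, "discarded")
})

test_that("Savitzky-Golay filter preserves cubics, constants, and flags", {
  d <- as.Date("2021-01-01") + seq(0, 364, by = 8)
  x <- seq_along(d)
  cubic <- 0.3 + 0.01 * x - 4e-4 * x^2 + 5e-6 * x^3
  s <- evi_series("p", d, cubic)
  sm <- smooth_savitzky_golay(s)   # defaults: half-width 9, degree 3
  expect_lt(max(abs(sm$evi - cubic)), 1e-9)

  const <- evi_series("p", d, rep(0.4, length(d)))
  expect_equal(smooth_savitzky_golay(const)$evi, rep(0.4, length(d)))

  # gaps are interpolated for filtering but keep their flags
  flag <- rep("ok", length(d)); flag[10] <- "discarded"
  gap <- evi_series("p", d, replace(cubic, 10, 0.9), flag)
  smg <- smooth_savitzky_golay(gap)
  expect_equal(smg$flag[10], "discarded")
  # linear gap interpolation on a curved signal is inexact but small
  expect_lt(max(abs(smg$evi - cubic)), 1e-3)

  # too few valid points is a typed error, not a crash
  short <- evi_series("p", d[1:10], cubic[1:10])
  expect_error(smooth_savitzky_golay(short), class = "phen_too_few_points")
  expect_error(sg_config(half_width = 1, degree = 4))
})
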