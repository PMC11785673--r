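# phenomatch

Land-surface phenology of deciduous orchard systems from satellite
vegetation-index time series, and its validation against ground surveys.

Satellite sensors see orchards as the seasonal rise and fall of a greenness
index over mixed 250 m pixels. Agronomists see them as BBCH developmental
stages scored tree by tree. `phenomatch` implements the full chain needed
to connect the two for a single-season crop such as hazelnut:

1. **Preprocessing** — Enhanced Vegetation Index from surface reflectance,
   `EVI = G (ρ_NIR − ρ_red) / (ρ_NIR + C1 ρ_red − C2 ρ_blue + L)` with
   `G = 2.5, C1 = 6, C2 = 7.5, L = 1`; 8-day maximum-value composites
   (46 per year, Jan 1 – Dec 27); expert quality floors (EVI > 0.1
   year-round, > 0.3 in June–August); Savitzky–Golay smoothing (half-width
   9, degree 3).
2. **Curve fitting** — a greendown-capable double logistic
   `f(t) = b + (A − g·r(t)) [σ_up(t) − σ_down(t)]`, `σ(t) = 1/(1+e^{−(t−m)/s})`,
   fitted per pixel-year by bounded Levenberg–Marquardt least squares and
   evaluated at daily resolution.
3. **Phenometrics** — eight spring transition dates from the daily curve:
   amplitude thresholds (TRS2 SOS at 20%, TRS5 SOS at 50%), derivatives
   (DER SOS = fastest increase, DER POS = curve maximum), the Gu tangent
   construction (upturn UD, stabilization SD), and the Zhang
   curvature-change-rate extrema (greenup, maturity).
4. **Ground observations** — weekly surveys mapped to ten 3-digit BBCH
   spring phases and reduced to per-orchard-year onset dates (first-seen or
   median-seen rule; December joins the next phenological year).
5. **Comparison** — per (metric, phase) pair over orchard-years: bias
   (mean metric − phase, positive = satellite later), RMSD, Spearman r_s
   with small-sample permutation p-values, 25/50/75th-percentile
   summaries, optional stratification at 75% orchard coverage.
6. **Synthetic study** — a seeded generator with known transition dates
   (truth computed by an independent dense-grid brute-force oracle), so
   the whole pipeline is testable without any satellite download.

## Worked example

```r
library(phenomatch)

sim <- simulate_series(sim_config(n_pixels = 4, years = 2021, seed = 42))
px <- sim$series[["px01"]]
px
#> <evi_ts> pixel px01: 46 entries (36 ok), 2021-01-01 to 2021-12-27, cadence 8 d

filtered <- apply_quality_filter(px)$series
smoothed <- smooth_savitzky_golay(filtered)
curve    <- fit_double_logistic(smoothed, 2021)
curve
#> <fitted_curve> pixel px01 year 2021: t_up 112.7 (s 16.9), t_down 279.3 (s 15.2),
#>   b 0.274, A 0.617, rmse 0.01478, converged

extract_all(curve)
#> <phenometric_set> pixel px01 year 2021
#>  der_sos  der_pos trs2_sos trs5_sos    gu_ud    gu_sd  greenup maturity
#>      112      174       87      109       78      141       73      150

sim$truth[sim$truth$pixel_id == "px01", "trs5_sos"]
#> [1] 109.6
```

Reading the numbers: this pixel's canopy crossed 20% of its seasonal
amplitude on day-of-year 87, 50% on day 109 (within half a day of the
generator's true value, 109.6), had its fastest greening on day 112 and
peaked on day 174; the Gu tangent brackets the steep rise (78–141) and the
Zhang curvature dates bracket it more widely (73–150). Dates are whole
days; `NA` metrics carry a reason code instead of crashing the pixel-year.

## The analysis workflow

Numbered drivers under `analysis/` rebuild the whole study from nothing
and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R       # fixture: 20 pixels x 4 years + surveys
Rscript analysis/02_preprocess.R     # expert filter + SG smoothing
Rscript analysis/03_fit_extract.R    # double-logistic fits + 8 phenometrics
Rscript analysis/04_ground_onsets.R  # BBCH mapping + onset dates
Rscript analysis/05_compare.R        # bias / RMSD / Spearman matrix
Rscript analysis/06_map.R            # TRS5 SOS map export (points + regions)
```

Each script prints what it found (convergence rates, median dates,
strongest correlations, regional timing contrast) and is deterministic for
a fixed configuration seed.

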