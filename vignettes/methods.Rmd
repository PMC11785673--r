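---
title: "Satellite phenometrics and their ground-truth matchup: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Satellite phenometrics and their ground-truth matchup: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenomatch)
```

# The problem

Deciduous orchard systems such as hazelnut show a pronounced seasonal cycle
in satellite vegetation indices: a winter baseline, a steep spring rise as
the canopy closes, a summer plateau with a slow "greendown" decline, and an
autumn senescence. Dates extracted from this curve — phenometrics — are the
only way to monitor phenology wall-to-wall, but they measure the mixed
greenness signal of a 250 m pixel, not the developmental stage of a tree.
`phenomatch` implements the full chain needed to quantify that gap: from
reflectance to the Enhanced Vegetation Index (EVI), through compositing,
quality filtering and smoothing, to a daily fitted curve, eight spring
phenometrics, and their statistical comparison with BBCH-coded ground
surveys.

# Preprocessing

**EVI.** For surface reflectances $\rho_{NIR}, \rho_{red}, \rho_{blue}$,

$$EVI = G\,\frac{\rho_{NIR}-\rho_{red}}
{\rho_{NIR} + C_1\rho_{red} - C_2\rho_{blue} + L},$$

with the standard coefficients $G=2.5$, $C_1=6$, $C_2=7.5$, $L=1$. Values
outside $[-1, 1]$, and samples with a near-zero denominator, are treated as
invalid rather than clipped: the range statement defines validity, it is
not a transform.

**Compositing.** Maximum-value composites keep the highest EVI within each
fixed period; the period calendar restarts every January 1 and composites
are dated at the period start, so an 8-day calendar gives 46 periods per
year, the last starting December 27 in a non-leap year. Empty periods are
emitted as `missing` so the series stays on a regular grid.

**Quality filter.** Two expert floors for evergreen-free orchard pixels:
EVI must exceed 0.1 year-round and 0.3 inside the summer window (June 1 -
August 31 inclusive, configurable; the month-granular window is
interpreted at day resolution). An entry violating both floors is counted
once, under the annual rule, so the report's per-rule counts add up to the
total. The report exposes the evaluated count and the discarded fraction
both per pixel and pooled.

**Smoothing.** A Savitzky-Golay filter with half-width 9 (19 composite
window) and polynomial degree 3. Discarded and missing entries are linearly
interpolated before filtering so the filter sees a regular grid, and keep
their flags afterwards. For the window edges we rely on the filter's
least-squares transient treatment, which fits the full polynomial to the
first and last windows: it reproduces any signal of degree $\le 3$ exactly
*including at the boundaries*, which matters because some January
transition dates sit near the year edge. (A mirror-pad alternative was
considered and rejected: it degrades exactly those boundary values.)

# The fitted seasonal model

Daily curves come from a greendown-capable double logistic,

$$f(t) = b + \bigl(A - g\,r(t)\bigr)\,
\bigl[\sigma_{up}(t) - \sigma_{down}(t)\bigr],
\qquad \sigma(t) = \frac{1}{1+e^{-(t-m)/s}},$$

with baseline $b$, amplitude $A$, spring midpoint/scale $t_{up}, s_{up}$,
autumn midpoint/scale $t_{down}, s_{down}$, and greendown slope $g$ (index
units per day). The ramp $r(t) = s_{up}\log(1+e^{(t-t_{up})/s_{up}})$ is
the softplus function: it behaves as $t - t_{up}$ well past the spring
midpoint and vanishes before it, so $g$ acts as a linear summer decline of
the effective amplitude. We use the smooth ramp rather than the piecewise
ramp $(t-t_{up})\,\mathbf{1}[t>t_{up}]$ deliberately: a kink in $f$ makes
the curvature undefined at $t_{up}$ and injects a large spurious spike into
any discretised curvature computation, which corrupts the curvature-based
phenometrics below. With $g = 0$ the model reduces exactly to the plain
symmetric double logistic, so the fitted family nests the textbook case.

**Fitting.** Bounded nonlinear least squares (Levenberg-Marquardt via
`minpack.lm`) on the `ok` entries of one calendar year, extended by 32 days
into the neighbouring years when those composites exist, because January
transitions sit near the year edge. Starting values are data-driven
(baseline = 5th percentile, amplitude = 95th$-$5th, midpoints from the
half-amplitude crossings, scales 10 d); a deterministic ladder of four
jittered restarts handles the rare non-convergent first attempt, so
refitting the same data always returns the same parameters. Bounds
(baseline $\in[-0.2, 0.6]$, amplitude $\in[0.05, 1.2]$, scales
$\in[1, 60]$ d, midpoints inside the padded year, $g\in[0, 0.01]$) prevent
degenerate sigmoid collapse. A year whose 5th-95th percentile spread is
below 0.05 is declared to have no seasonality and is skipped with a typed
error; the pipeline logs and continues.

# The eight phenometrics

All extractors operate on the analytic fitted curve, restricted to the
rising segment between the pre-season trough and the seasonal peak, and
report whole days (ties to the earlier day), matching the field convention
of day-of-year reporting. Continuous locations (threshold crossings,
refined maxima) are computed on the continuous curve first and rounded
last, so the discretisation error is at most half a day.

* **TRS2 / TRS5** — first crossing of baseline $+$ 20% / 50% of the
  seasonal amplitude. On a logistic limb the closed forms are
  $m - s\ln 4$ and $m$.
* **DER SOS / POS** — day of maximum first derivative (the inflection $m$
  on a logistic) and day of the curve maximum.
* **GU UD / SD** — the tangent at the maximum-slope day (the "recovery
  line") intersected with the baseline and the peak line; on a logistic
  limb, $m - 2s$ and $m + 2s$.
* **Greenup / Maturity** — the first two local maxima of the curvature
  change rate $K'(t)$, with
  $K = f''/(1+f'^2)^{3/2}$, computed from analytic derivatives of the
  fitted model (finite differences of a noise-amplifying third-derivative
  quantity are avoided by construction). Maturity is defined as the local
  maximum *immediately following* greenup — the second curvature-rate
  extremum of the sigmoid rise — because a greendown curve exhibits one
  further $K'$ maximum where the summer decline bends the plateau; that
  point marks greendown onset, not canopy maturity.

On smooth single-season curves the metrics obey the temporal gradient
greenup $<$ GU UD $<$ TRS2 $<$ TRS5 $\le$ DER SOS $<$ GU SD $<$ maturity
$\le$ DER POS, which the tests assert.

A deliberately independent brute-force implementation
(`phenometrics_bruteforce`) recomputes all eight dates from sampled curve
values on a 0.01-day grid with central finite differences and exhaustive
scans. It shares no code with the analytic path and serves as the
numerical oracle in the test suite and as the truth generator for
simulations. Two numerical guards are documented: curvature-rate maxima
below 5% of the limb's global maximum are ignored (floating-point ripple in
flat tails), and grid maxima closer than 2 days are merged into one
(ripple can split a single extremum).

Strict invariances hold by construction for threshold, derivative and Gu
dates: translating the season shifts every date equally, and rescaling
$(f - b)$ by $c > 0$ changes none of them. For the curvature dates the
$(1+f'^2)$ term breaks exact scale invariance, but for EVI-scale curves
$f'^2 \lesssim 10^{-4}$ and the displacement is far below the 1-day grid;
the tests assert equality after rounding.

# Ground observations

Weekly surveys record phase codes per orchard; codes are mapped to ten
3-digit BBCH spring phases (female reproductive 61P, 64P, 67P, 70P, 71P;
vegetative 03VP, 07VP, 10V, 13V, 15V) through an editable CSV mapping
shipped with identity entries. The reduction of weekly sightings to one
onset per orchard-year-phase is not uniquely defined by survey practice,
so both a `first-seen` (default) and a `median-seen` rule are provided.
First-seen overshoots the true onset by at most the survey cadence; for a
true onset uniform within the week the expected overshoot is 3.5 days,
which the tests verify and which matters when interpreting bias values.
Because female flowering brackets the calendar boundary, December
observations belong to the following phenological year by default, and
onset days are carried on a continuous axis (December = negative DOY) so a
December-to-January comparison never produces a ~330-day artifact.

# Comparison statistics

For a metric and a phase paired per orchard-year (inner join through a
pixel-orchard link table): bias = mean(metric $-$ phase), positive when
the satellite metric is later; RMSD = root mean square of the same
differences (so RMSD $\ge |$bias$|$, and RMSD$^2-$bias$^2$ is the
difference variance); Spearman $r_s$ with average ranks. The $p$-value
uses the $t$ approximation for $n \ge 10$ and a permutation null below
that (complete enumeration for $n \le 7$, $10^5$ seeded draws otherwise),
because stratified cells can be small. Cells are flagged at $p<0.05$
without multiplicity correction by default — each (metric, phase) cell is
reported on its own terms — with an optional Benjamini-Hochberg
adjustment. Years are pooled per cell by default. Distribution summaries
report the 25th/50th/75th percentiles (linear interpolation) and mean.
Optional stratification splits pixels at 75% orchard coverage.

# The synthetic study

The raw observations this kind of study uses are typically not shareable,
so the package carries a generator whose defaults define the study
conditions: 20 orchard pixels, years 2019-2022, 8-day cadence, winter
baseline 0.15-0.30, amplitude 0.3-0.6, spring midpoint DOY 85-110, scales
6-15 d, autumn midpoint DOY 270-300, greendown 0-5e-4 d$^{-1}$ — ranges
consistent with a Black-Sea-like deciduous orchard setting where TRS5 SOS
falls around DOY 90-120. Gaussian noise (sd 0.02) and composite dropouts
(10%) are applied after the truth metrics are computed from the noiseless
curve with the brute-force oracle, closing the loop between oracle and
implementation. An optional Gaussian "understory bump" (amplitude 0.05 at
DOY 45, width 15 d) emulates early understory greening, the classic
confounder of early-season metrics; it perturbs the observations, never
the truth.

Pixels keep their base parameters across years — a site property — with
small seeded interannual deviations (midpoints sd 4 d, baseline sd 0.01,
amplitude sd 0.02, scales sd 1 d). This matters numerically as well as
biologically: the fitting window of one year includes up to 32 days of the
neighbouring years' composites, and independently redrawn baselines would
create artificial discontinuities at year boundaries that bias the fit.
Seeding is counter-based per pixel-year, so enlarging the simulation never
changes the draws of earlier pixels. Ground surveys place each phase at a
linked true metric plus a configured offset (scaffolding, not biology)
plus jitter, and record it on the first weekly visit on or after the
realized date. The half of pixels with even indices form an "East" region
whose spring midpoint is shifted later (default 10 d), giving the map
export a detectable spatial contrast.

What the generator does *not* emulate: radiative-transfer realism, spatial
autocorrelation, mixed-pixel composition drift, observer disagreement, and
low cloud-contaminated spikes (its noise is symmetric Gaussian). Passing
tests therefore demonstrate the correctness of the algorithms under the
stated noise model, not performance on real imagery; in particular the
expert filter discards almost nothing on clean synthetics and is exercised
by constructed violations instead.

# Numerical choices and degenerate inputs

* Threshold crossings are bracketed on the daily grid and solved by root
  finding on the analytic curve (tolerance $10^{-6}$ d) before rounding.
* Grid maxima of $f'$ and $K'$ are refined by golden-section search within
  $\pm 1$ day before rounding.
* Optimiser tolerances: `ftol = ptol = 1e-10`, at most 400 iterations per
  start; the restart ladder stops early once a fit reaches RMSE below
  5e-3.
* Ties in any argmax or threshold search resolve to the earliest day.
* A seasonal peak on the first or last grid day raises a boundary-season
  warning and marks the geometry low-confidence; Gu dates clipped to the
  grid are flagged likewise.
* Unconverged curves yield an all-missing metric set with a propagated
  reason; individual degenerate metrics (no threshold crossing,
  non-positive slope, fewer than two curvature maxima) go missing with a
  per-metric reason and never abort the pixel-year.

# Problem sizes

The shipped analyses and tests run the full pipeline at 20 pixels x 4
years, the oracle comparison at 100 curves, the noisy recovery study at 50
pixel-years, and the offset-recovery study at 200 pixel-year pairs; these
sizes give stable medians and rates while keeping any single script within
a couple of minutes on one core.

# Known limitations

* The exact parameterization of the published "fine-fitting" double
  logistic family this model emulates is not standardised; ours is
  documented above and nests the symmetric case, but parameter values are
  not interchangeable with other implementations.
* Single growing season per year; double-cropped or bimodal canopies are
  out of scope.
* The comparison treats orchard-years as independent; repeated measures on
  the same orchard are not modelled.
* Raster export writes an ESRI ASCII grid for regular pixel layouts and
  falls back to a point table otherwise; no projection handling beyond
  lon/lat is attempted.
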