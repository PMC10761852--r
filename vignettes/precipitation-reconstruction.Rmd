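---
title: "From ring widths to a seasonal precipitation reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From ring widths to a seasonal precipitation reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendrorecon)
```

`dendrorecon` reconstructs winter–spring (February–June) precipitation
from moisture-limited conifer ring widths. This vignette is the package's
account of its science: the statistical model at each stage, the
parameters that matter, the synthetic data the tests rely on, and the
choices made where the design was genuinely open.

## The dendroclimatic model

A measured ring width mixes three things: a biological age/geometry
trend, a common environmental (here: moisture) signal, and individual
noise. The pipeline separates them in the classical way.

**Detrending.** Each series is divided by a modified negative exponential
curve $f(t) = a e^{-bt} + k$ ($a>0$, $b>0$, $k \ge 0$) fitted over
cambial age $t = 1..n$ by constrained least squares
(`minpack.lm::nlsLM`). Ratio indices (width / fitted) rather than
differences are used because conifer ring-width variance scales with
level. When the constrained fit is unattainable — non-declining growth,
constant series, or a boundary solution with $a \approx 0$ or
$b \approx 0$ — the fit falls back to the horizontal mean, which is
conservative: it preserves all low-frequency variance rather than
inventing a trend. A declining-line fallback is available by option.
Cambial age is taken as the ring index within the core; pith offsets are
assumed zero because cores rarely record them. The fallback is recorded
on the returned object (`$fallback`, `$kind`).

**Prewhitening.** Ring-width indices carry biological persistence
(carry-over of reserves, needle mass). The residual index removes it by
fitting AR($p$), $p$ chosen by AIC over $0..10$ (Yule–Walker), keeping
the innovations, and re-centring them to mean 1 so residual and standard
indices live on the same scale. Re-centring to mean 1 rather than 0 is a
choice; it keeps the transfer function's intercept interpretable in mm.
The first $p$ years are dropped rather than back-filled.

**Averaging.** Per year, indices are combined with Tukey's biweight
(tuning constant $c = 9$, scale fixed at the median absolute deviation,
fixed point iterated to $10^{-8}$). With one or two values the plain
mean is used; with zero MAD the median. The biweight ignores a single
wild core (its influence is bounded as the outlier grows) while matching
the arithmetic mean on clean symmetric samples.

**Signal strength.** Over 50-yr windows advanced by 25 yr, Rbar is the
mean pairwise Pearson correlation among series with at least 30 common
years in the window, and
$\mathrm{EPS} = N\bar r / (N\bar r + 1 - \bar r)$ with $N$ the mean
sample depth. The reconstruction is truncated at the earliest year from
which *every* subsequent year (window EPS interpolated to years) stays at
or above 0.85 — the "all subsequent windows" rule avoids flickering
first crossings. The windowing constants are community defaults, not
estimates, and are exposed as arguments. EPS is computed on the standard
(not prewhitened) indices; for a composite, series from all sites are
pooled before averaging and Rbar uses all pairs, within- and
between-site alike.

## Growth–climate response

Correlation functions are computed per month of a 17-month window
(previous June through current October — wide enough to catch both
previous-year carry-over and current-season response) and for standard
seasons (DJF, MAM, MAMJ, FMAMJ, JJAS). Significance uses a classical
pairs bootstrap (1000 replicates by default) with 95 % percentile
intervals; a coefficient is significant when its interval excludes zero.
The classical rather than stationary-block bootstrap is the default:
the residual chronology is close to white, and the block variant is a
config option rather than a different answer. Monthly intervals are
*not* adjusted for multiplicity — with 22 coefficients, one spurious
flag per table is expected, and the tests treat it that way.

The seascorr-style analysis takes precipitation as the primary and
temperature as the secondary variable, over season lengths 1, 3, 5 and
12 months ending at each calendar month. The primary coefficient is a
simple correlation. The secondary coefficient is the **semipartial**
correlation — the chronology against the part of the secondary variable
orthogonal to the primary — so it measures what temperature adds beyond
the precipitation signal. (A full partial correlation, which also
removes the primary from the chronology, would report a perfect
secondary score for a chronology driven equally by both variables —
not the intended reading.) Significance comes from 1000 AR(1) surrogate
chronologies matching the observed lag-1 autocorrelation: empirical
non-exceedance probabilities of $|r|$, so the test respects the
persistence that a parametric t-test would ignore.

Moving correlations (30-yr window, 2-yr step) check the temporal
stability of the response; a collapsing correlation in one half of the
record (a "divergence" pattern) shows up as significance concentrated in
the other half.

## Transfer function and verification

The reconstruction model is simple linear regression of the seasonal
target on the residual composite chronology over the calibration window
(1965–2018 analogue, $n = 54$). Verification follows the standard
split-sample design (halves exchanged as calibration/verification, split
at the median year by default) plus leave-one-out cross-validation
(computed exactly via the hat matrix). Statistics, with their anchors:

- **RE** $= 1 - \mathrm{SSE}/\sum(\mathrm{obs}-\bar y_{cal})^2$ and
  **CE** $= 1 - \mathrm{SSE}/\sum(\mathrm{obs}-\bar y_{ver})^2$. Both are
  at most 1, positive values beat the respective mean-only predictor,
  and CE ≤ RE always. In-sample RE equals R² exactly for OLS — an
  identity the tests assert to $10^{-10}$. LOOCV RE uses the
  all-years calibration mean as its null predictor.
- Verification **R²** is reported as the squared Pearson correlation of
  observed and predicted values (it can exceed CE when the verification
  mean is poorly predicted).
- The **sign test** counts agreeing first-difference directions
  (zero differences dropped; two-tailed binomial p).
- The **product-mean test** (Fritts) splits the products of observed and
  predicted departures from the calibration mean into positives and
  absolute negatives and forms a Welch-type
  $t = (m_1 - m_2)/\sqrt{s_1^2/n_1 + s_2^2/n_2}$; an all-positive
  product set is reported as a degenerate pass, not a number.
- **Durbin–Watson** $= \sum(\Delta e)^2 / \sum e^2$ screens residual
  autocorrelation; **RMSE** is $\sqrt{\mathrm{SSE}/n}$ and doubles as
  the reconstruction's ±1 RMSE uncertainty band (±2 by option).
- **PRESS** is the sum of squared LOOCV residuals, in mm².

Negative predicted precipitation is possible under a linear model
applied to extreme index values; such years are flagged
(`$negative_years`) but not clipped.

## Characterizing the reconstruction

Extreme years are those beyond mean ± 1.5 SD of the *whole*
reconstructed span (using the calibration era instead would make the
catalogue depend on an arbitrary 54-yr window). Persistent wet/dry
periods are maximal runs of at least 2 consecutive years whose 10-yr
low-pass value exceeds mean ± 1 SD *of the low-pass series itself*.
The low-pass filter is a cubic smoothing spline whose amplitude response
is 0.5 at a 10-yr wavelength; its stiffness is found once per cutoff by
bisection against a measured sinusoid response (then cached), and the
tests verify the response empirically (0.5 ± 0.05 at 10 yr, > 0.9 at
50 yr, < 0.1 at 2 yr). Century bins run from the first reconstructed
year; a partial final bin is flagged and excluded from any
monotone-trend statement.

The multitaper spectrum uses Slepian tapers with time–bandwidth
NW = 2 and K = 3 tapers — the standard short-series compromise between
resolution (±2/n cycles/yr) and variance — computed from the symmetric
tridiagonal eigenproblem and cached per (n, NW, K). The null continuum
is the theoretical AR(1) spectrum at the series' lag-1 autocorrelation,
scaled to the series variance, with 95 %/99 % levels from
$\chi^2_{2K}$. Each significant peak is reported as the power-weighted
centroid of its contiguous significant run: a tapered line spreads over
the 2W bandwidth, so a raw arg-max bin can sit about two Rayleigh
resolutions off, while the centroid is sub-Rayleigh. The Morlet wavelet
($\omega_0 = 6$, $\delta j = 1/4$, full zero padding) follows the
Torrence–Compo formulation: Fourier period ≈ 1.03 × scale, cone of
influence at the $\sqrt 2 s$ e-folding distance, pointwise 95 %
significance against the same AR(1) background.

## The synthetic generator

The tests' ground truth comes from a two-layer generator.

*Climate* (`simulate_climate()`): monthly normals shaped so that
December–June carries ≈ 82 % of a 460 mm annual total with a 17 °C
annual mean temperature — typical station normals of a westerly-regime
Hindu Kush valley; an AR(1) interannual anomaly (φ = 0.3,
SD = 0.25 of the mean) common to all months; injected quasi-cycles at
2.7 and 8.2 yr (amplitude 0.4 interannual SD each), inside the 2–10-yr
band where ENSO-type variability lives; independent monthly noise
(SD 0.10); temperature anomalies correlated at −0.4 with precipitation
anomalies, so wet springs are cool. Negative monthly values are
truncated at zero (rarely binding at these settings).

*Forest* (`simulate_forest()`): cores follow
$w = (a e^{-b\,\mathrm{age}} + k) \cdot \max(0,\; 1 + \beta z_P +
\gamma z_T + \eta)$ with $z_P$ the standardized February–June
precipitation total and $z_T$ the standardized spring temperature.
The noise $\eta$ is AR(1) (φ_b = 0.5) with three components: a
stand-wide year effect (SD 0.25) shared by every tree — the non-climatic
common variance (disturbance, pests, snowpack quirks) that caps the
attainable chronology–climate correlation and is what keeps the
calibration r near 0.73 rather than 0.99; a tree effect (SD 0.12) shared
by the cores of one tree; and core noise (SD 0.15). Germination years
are staggered over the first three quarters of the span so sample depth
declines back in time, as in any real collection. Widths are rounded to
0.01 mm, the measurement resolution. The generator refuses couplings so
strong that the *expected* growth multiplier is non-positive in more
than 1 % of years.

`tune_coupling()` sets β to hit a target calibration correlation
(default 0.727 at n = 54): it solves the analytic correlation of the
generative model for β, then refines through the actual
detrend–prewhiten–average pipeline with a small Monte-Carlo loop
(6 replicate forests per step), because detrending and prewhitening
losses are invisible to the closed form.

What the generator does *not* emulate: spatially structured climate
(every site sees the same station), snow accumulation and melt timing,
age-dependent climate sensitivity, missing-ring clustering in drought
years, and disturbance pulses. Passing tests therefore demonstrate that
the *methods* recover known signals under realistic noise, persistence
and sample-depth structure — not that any particular real-world
collection meets the model's assumptions.

## Numerical choices and test scale

- Detrending starts `nlsLM` from three starting points and accepts the
  first constrained solution with positive fitted values; boundary
  solutions route to the mean fallback.
- `biweight_mean` iterates to $10^{-8}$; the test oracle is an
  independent fixed-point iteration run to $10^{-12}$.
- AR fitting everywhere is Yule–Walker with AIC selection; the same
  machinery serves prewhitening, crossdating, and surrogate generation,
  for internal consistency.
- COFECHA-style defaults: 50-yr segments lagged 25 yr, lags ±10,
  one-tailed critical r at α = 0.01. Positive best lag means the series
  is dated too old. These are conventions, exposed as arguments.
- Degenerate inputs fail loudly (all-zero series, zero-variance
  predictor or residuals, constant spectra) except where a defined
  answer exists (singleton biweight, zero-MAD median, constant
  prewhitening input returned unchanged).
- Test problem sizes: recovery experiments use 50 replicate forests of
  2–3 sites × 4–6 trees × 2 cores over 219–679 yr, 200-seed null
  calibrations for the spectral false-positive rate and slope-CI
  coverage, and 635-yr series for spectral recovery — large enough for
  the stated tolerances, small enough that the whole suite runs in a
  few minutes on one core.

## Known limitations

- Only negative-exponential/mean/line detrending is provided; RCS,
  splines and signal-free iteration are out of scope, so very
  low-frequency (multi-century) variance is not interpretable.
- Reconstruction from the residual chronology deliberately sacrifices
  decadal-plus periodicity for calibration fidelity; spectra of the
  output are dominated by the 2–10-yr band.
- Uncertainty is a constant ±RMSE band; it ignores sample-depth changes
  through time (no nested calibration).
- The sign convention and critical values of the crossdating module
  assume annual rings; it will not diagnose double/false rings as such,
  only flag the segments they corrupt.
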