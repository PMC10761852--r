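# dendrorecon

Tree-ring chronology building and seasonal precipitation reconstruction
for moisture-limited conifer sites.

In the westerly-dominated mountain climates of High Asia (and in many
other semi-arid forests), conifer radial growth is limited by moisture:
wet, cool springs leave wide rings, dry springs narrow ones. That makes
dated ring-width series a proxy for winter–spring precipitation on
multi-century time scales where station records cover only a few decades.
`dendrorecon` implements the full analysis chain from raw measurement
files to a validated reconstruction:

1. **I/O** — Tucson/RWL decadal ring-width files and monthly station
   climate CSVs (`read_rwl()`, `write_rwl()`, `read_climate_table()`).
2. **Cross-dating checks** — Gleichläufigkeit and COFECHA-style segment
   correlations against a leave-one-out master (`glk()`, `crossdate()`).
3. **Chronology building** — modified negative exponential detrending
   (`a·e^{-bt} + k`, ratio indices), AIC-selected AR prewhitening, Tukey
   biweight mean, running Rbar and expressed population signal
   EPS = N·r̄ / (N·r̄ + 1 − r̄), and EPS-based truncation
   (`build_chronology()`, `truncate_by_eps()`, `pca_sites()`).
4. **Growth–climate response** — bootstrapped monthly/seasonal correlation
   functions over a 17-month dendroclimatic window, seascorr-style
   semipartial correlations with AR(1) surrogate significance, and
   moving-window correlations (`bootstrap_corrfun()`, `seascorr()`,
   `moving_corr()`, `index_corr()`).
5. **Reconstruction** — a linear transfer function
   `P = slope · RC + intercept` fitted by OLS on the calibration window,
   validated by leave-one-out cross-validation and split-sample
   calibration/verification with the standard statistic set (r, R², R²adj,
   RMSE, F, Durbin–Watson, sign test, product-mean test, RE, CE, PRESS),
   then applied back in time with a ±RMSE uncertainty band
   (`fit_transfer()`, `loocv()`, `split_sample()`, `reconstruct()`).
6. **Variability** — extreme years (mean ± 1.5 SD), persistent wet/dry
   periods on a 10-yr low-pass spline (mean ± 1 SD of the smoothed
   series), per-century extreme counts, multitaper spectra with AR(1)
   red-noise significance, and Morlet wavelet power (`find_extremes()`,
   `find_periods()`, `mtm_spectrum()`, `morlet_wavelet()`).

A seeded synthetic generator (`simulate_climate()`, `simulate_forest()`)
produces monthly climate and climate-driven multi-site ring-width
collections with known ground truth — an AR(1) interannual anomaly with
injected quasi-cycles, ~80 % of precipitation in December–June, and
moisture-limited growth (positive precipitation, negative temperature
coupling) — so every stage is testable end to end without field data.
`tune_coupling()` calibrates the precipitation coupling to a target
calibration correlation.

## Worked example

The whole workflow runs from one config-driven call. With no inputs it
simulates a study-like scenario (climate 1340–2018, three sites, 36
cores, 54-yr calibration 1965–2018 split at 1991, February–June
precipitation target):

```r
library(dendrorecon)
report <- run_pipeline(list(seed = 42))
print(report)
#> == dendrorecon run report ==
#> chronology 1340-2018 (36 series), truncated at EPS >= 0.85: 1349
#> calibration 1965-2018: P = 162.2224 * RC +97.3917
#>   r=0.751 R2=0.564 R2adj=0.556 RMSE=50.62 F=67.4 DW=0.92
#>   LOOCV: R2=0.534 RE=0.533; split RE=0.636/0.478 CE=0.634/0.476
#> reconstruction 1349-2018: mean 259.8 mm, SD 61.0 mm; 40 wet / 49 dry extremes
#> significant spectral peaks (yr): 2.0, 2.2, 2.3, 2.7, 3.2, ..., 8.2, 32.5, 34.1
#> truth recovery: calibration r=0.751, pre-calibration r(recon, truth)=0.719
```

Reading the report: the pooled composite chronology is reliable (EPS ≥
0.85) from 1349; the transfer function converts the residual ring-width
index RC into February–June precipitation in mm; the calibration model
explains 56 % of the observed variance, holds up in cross-validation
(RE > 0, CE > 0 in both split directions), and the reconstruction
recovers the injected 2.7-yr and 8.2-yr precipitation cycles among its
significant spectral peaks. Because this run is synthetic, the report
also states how well the reconstruction tracks the true (generated)
pre-calibration precipitation.

On real data, point `run_pipeline()` at files instead:

```r
report <- run_pipeline(list(
  inputs = list(rwl = list("site1.rwl", "site2.rwl"),
                climate = list(prec = "station_prec.csv",
                               tmean = "station_tmean.csv")),
  calibration = list(start = 1965, end = 2018, split_year = 1991)))
```

Each stage is also an ordinary function (`build_chronology()`,
`fit_transfer()`, ...) for interactive use; a thin command-line wrapper
lives at `inst/cli/dendrorecon.R`.

## Vignette

`vignettes/precipitation-reconstruction.Rmd` documents the statistical
model, every tunable parameter with its default and rationale, the
design of the synthetic generator (and what passing tests do and do not
imply about real data), and the package's numerical choices and known
limitations.
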