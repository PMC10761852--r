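Package: dendrorecon
Title: Tree-Ring Chronology Building and Seasonal Precipitation Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A dendroclimatology toolkit covering the full workflow from raw
    ring-width collections to a validated climate reconstruction: Tucson/RWL
    decadal input and output, cross-dating quality checks (Gleichlaeufigkeit and
    COFECHA-style segment correlations), modified negative exponential
    detrending, autoregressive prewhitening, robust biweight-mean chronologies
    with running Rbar and expressed population signal (EPS), bootstrapped and
    partial (seascorr-style) growth-climate correlation functions, a linear
    transfer-function reconstruction with leave-one-out and split-sample
    RE/CE validation, extreme-year and wet/dry-period catalogues, multitaper
    spectra with red-noise significance, and Morlet wavelet analysis. Includes
    a seeded synthetic climate and forest generator with known ground truth so
    the whole pipeline is testable end to end without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    lmtest,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
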