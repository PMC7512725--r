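Package: dispentropy
Title: Amplitude- and Fluctuation-Based Dispersion Entropy for Time Series
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Irregularity analysis of univariate time series via dispersion
    entropy (DispEn) with linear, sorting, log-sigmoid, tan-sigmoid and
    normal-CDF signal-to-class mappings, fluctuation-based dispersion entropy
    (FDispEn), and forbidden dispersion-pattern censuses for discriminating
    deterministic from stochastic dynamics. Includes reference estimators
    (permutation entropy with emergence-order tie ranking, sample entropy,
    Lempel-Ziv complexity), Hedges' g effect sizes, seeded synthetic-signal
    generators (colored noise, logistic map, MIX process), and drivers for
    noise-sensitivity, stability and sliding-window experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
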