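# dispentropy

Irregularity analysis of univariate time series via **dispersion entropy
(DispEn)** and **fluctuation-based dispersion entropy (FDispEn)**, with
forbidden dispersion-pattern censuses for telling deterministic dynamics from
stochastic ones, the standard comparator estimators (permutation entropy,
sample entropy, Lempel–Ziv complexity, Hedges' g), and seeded synthetic-signal
generators for benchmarking.

## Who this is for

Analysts of biomedical and other real-world recordings (heart rate, blood
pressure, EEG, gait) who need an entropy estimate that is fast (`O(N)`),
defined on short epochs, robust to small-amplitude noise, and sensitive to
amplitude — the regime where permutation entropy saturates and sample entropy
becomes undefined.

## The statistic

Given a signal `x` of length `N`, each sample is mapped to an integer class
`u_j ∈ {1..c}` (linear, rank-based *sorting*, or sigmoid-family *logsig* /
*tansig* / *NCDF* mapping of the standardized signal). Windows of `m` classes
at delay `d` form dispersion patterns `π`, and

    DispEn(x; m, c, d) = − Σ_π p(π) ln p(π),
    p(π) = #{windows of type π} / (N − (m−1)d),

normalized by `ln(c^m)`. FDispEn applies the same construction to the
adjacent differences of each pattern (entries `−(c−1)..(c−1)`, space
`(2c−1)^(m−1)`), so patterns equal up to a constant offset coincide and only
local fluctuations count. Patterns that never occur are *forbidden*; their
persistent fraction as `N` grows is a signature of determinism.

## Worked example

The ten-sample series shipped with the package, three linear classes,
embedding dimension 2:

```r
library(dispentropy)
x <- read_signal(system.file("extdata", "worked_example.csv",
                             package = "dispentropy"))
e <- dispen(x, m = 2, c = 3, mapping = "linear")
summary(e)
#> dispersion entropy (DispEn)
#>   parameters: m = 2, c = 3, d = 1, mapping = linear
#>   raw: 1.73513 nats
#>   normalized: 0.78969
#>   embedded vectors: 9
#>   pattern space: 9; observed: 6; forbidden: 3 (0.333)
#>   most frequent patterns:
#>     (1,1)  count 2  p = 0.2222
#>     (1,2)  count 2  p = 0.2222
#>     (2,1)  count 2  p = 0.2222
#>     (2,2)  count 1  p = 0.1111
#>     (2,3)  count 1  p = 0.1111
```

The raw value 1.7351 nats is the Shannon entropy of the nine windows (three
patterns seen twice, three seen once); 0.790 is that value relative to the
maximum `ln 9` attainable with nine potential patterns. On a deterministic
chaotic signal the forbidden fraction stays high at any length:

```r
y <- logistic_map(10000, alpha = 4, x0 = 0.23)
forbidden_census(y, m = 3, c = 6, mapping = "logsig",
                 flavor = "dispersion")$normalized_forbidden
#> [1] 0.8981481
```

whereas for white noise of the same length it is near zero.

A command-line wrapper over the same functions is installed at
`inst/cli/dispen` (subcommands `entropy`, `simulate`, `sweep`, `forbidden`,
`compare`):

```sh
Rscript inst/cli/dispen entropy --estimator dispen --mapping linear \
        -m 2 -c 3 -d 1 --input inst/extdata/worked_example.csv
# raw 1.7351
# normalized 0.7897
```

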