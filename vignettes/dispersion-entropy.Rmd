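---
title: "Dispersion entropy: methods, parameters and design choices"
author: "dispentropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dispersion entropy: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dispentropy)
```

## The model

Dispersion entropy (DispEn) quantifies the irregularity of a univariate
series `x = (x_1, ..., x_N)` through the distribution of coarse-grained
ordinal-amplitude patterns:

1. **Mapping.** Each sample is assigned an integer class `u_j` in `1..c`.
2. **Embedding.** Windows `(u_i, u_{i+d}, ..., u_{i+(m-1)d})` of `m` classes
   at delay `d` form *dispersion patterns*; there are `c^m` potential
   patterns and `N - (m-1)d` windows.
3. **Counting.** The relative frequency `p(pi)` of each observed pattern is
   its count over the number of windows.
4. **Entropy.** `DispEn = -sum p(pi) log p(pi)` in nats; the normalized value
   divides by `log(c^m)`, the entropy of a uniform pattern distribution.

A maximally regular series concentrates all windows on one pattern
(entropy 0); an unconstrained stochastic source at large `N` spreads them
uniformly (normalized entropy near 1, up to the mapping-induced class
occupancies discussed below).

**Fluctuation-based DispEn (FDispEn)** replaces each pattern by its adjacent
differences, an `(m-1)`-tuple with entries in `-(c-1)..(c-1)`. Patterns equal
up to a constant class offset — e.g. `(1,3,4)` and `(2,4,5)` — collapse to
one fluctuation pattern, so only local movement matters and slow trends drop
out. The pattern space is `(2c-1)^(m-1)` and normalization uses its log.

Unlike permutation entropy (PerEn), which sees only order relations,
dispersion patterns retain amplitude information through the class labels,
handle repeated values naturally (equal samples share a class), and are
robust to small perturbations (a small amplitude change rarely crosses a
class boundary). `sample_entropy()`, `permutation_entropy()` and
`lempel_ziv_complexity()` are provided as the standard comparators, and
`hedges_g()` for effect-size summaries of group contrasts.

## Mappings

`map_to_classes()` supports five signal-to-class schemes:

* **linear** — affine rescaling of the empirical `[min, max]`. Fast, but a
  single outlier compresses most samples into few classes.
* **sorting** — rank-based, equal-occupancy classes; invariant under any
  strictly increasing transform, hence blind to amplitude (like PerEn).
* **logsig / tansig / ncdf** — sigmoid-family transfer of the standardized
  signal `(x - mu)/sigma`, classified over the *theoretical* output range
  ((0,1) for logsig and the normal CDF, (-1,1) for tansig). The fixed range
  is what gives these maps their outlier compression: extremes saturate
  instead of stretching the class grid. An `range = "empirical"` option in
  `mapping_spec()` is provided for comparison.

Classification rounds `z = 0.5 + c (y - a)/(b - a)` half-up and clamps into
`[1, c]`, so both range endpoints receive a valid class; this rule reproduces
the reference class series `{1,1,2,2,1,1,1,2,2,2}` of the worked
two-class example including its boundary samples.

Numerical conventions worth stating explicitly:

* `mu` and `sigma` are the mean and **population** SD (divide by `N`) of the
  analysed signal itself, the symmetric convention for a per-signal
  standardization. SampEn's tolerance `r * SD` and the CV / Hedges-g
  statistics use the sample SD (n-1), as is standard for those statistics.
* A **constant signal** cannot be standardized or ranged; all samples are
  assigned the middle class `floor((c+1)/2)` with a warning, so a flat epoch
  yields entropy 0 ("completely certain") rather than an error.
* Sorting ties are broken by order of emergence (stable ranking), making the
  equal-occupancy split deterministic.
* All logarithms are natural; normalized values divide by the log of the
  pattern-space size.

## Parameter defaults

* `c = 6` classes for DispEn and `c = 5` for FDispEn: small `c` discards
  amplitude detail, large `c` lets noise flip classes; these values balance
  the two and give stable noise-sensitivity profiles on the noisy logistic
  map.
* `m = 2` (DispEn) / `m = 3` (FDispEn): FDispEn patterns have length `m - 1`,
  so it needs one more embedding step for a comparable pattern length.
  Reliable estimates need `N` well above `c^m` (or `(2c-1)^(m-1)`) windows.
* `d = 1`: larger delays subsample the dynamics and are exposed but rarely
  needed.
* PerEn `m = 3` or 4; SampEn `m = 2`, `r = 0.2 * SD` (recomputed per epoch in
  `epoch_group_comparison()`).

## Forbidden patterns and determinism

`forbidden_census()` counts patterns that never occur. For a stochastic
full-support source the missing ("false forbidden") patterns vanish as `N`
grows; deterministic one-dimensional maps retain true forbidden patterns at
any length. Because classes are monotone in the signal, a class window with
strict inequalities realizes the same ordinal pattern as the underlying
samples, so a missing permutation implies that **every** dispersion pattern
realizing it strictly is missing too; `forbidden_implications()` enumerates
that set (20 patterns for a missing length-3 permutation at `c = 6`) and its
fluctuation images. Tuples with tied classes carry no implication, since a
class tie does not constrain the underlying order.

One design choice was genuinely open: the embedding length for the
*permutation* flavor of `forbidden_fraction_curve()`. At `m = 3` the fully
chaotic logistic map (`alpha = 4`) admits five of the six ordinal patterns,
so the forbidden fraction plateaus at 1/6 — detectable but far below the
plateaus of the dispersion (`0.90` of `6^3`) and fluctuation (`0.83` of
`11^2`) flavors at `m = 3, c = 6`. Forbidden ordinals dominate their pattern
space only for longer patterns, so the permutation flavor defaults to
`m_perm = 5` (fraction about `0.74`), the shortest length at which the
determinism signature exceeds half the space. Both are arguments, not
constants.

## Synthetic benchmark signals

All generators are pure functions of their arguments and seed.

* `colored_noise()` — white (i.i.d. Gaussian), pink and brown noise, the
  latter two via Fourier-amplitude shaping (`f^{-1/2}`, `f^{-1}`) of white
  noise, which hits the target spectral slope exactly in expectation and
  stays seedable.
* `logistic_map()` / `logistic_sweep()` — `x_{t+1} = a x_t (1 - x_t)`;
  period-4 at `a = 3.5`, chaotic with embedded periodic windows up to
  `a = 4`. The initial state must avoid the points that collapse onto fixed
  points at `a = 4`.
* `mix_process()` — the MIX mixture: a period-12 sinusoid whose samples are
  replaced by uniform noise with probability `p`, sweeping from periodic
  (`p = 0`) to i.i.d. (`p = 1`). The default constants are the classic
  unit-variance ones (amplitude `sqrt(2)`, noise on `(-sqrt(3), sqrt(3))`);
  `constants = "literal"` selects amplitude 2 and bounds `(-3, 3)`. The
  choice does not affect any qualitative ordering but does shift stability
  (CV) levels; see the caveat below.
* `add_noise_at_snr()` — additive white Gaussian noise rescaled so the
  realized variance ratio matches the requested SNR (dB) exactly, the only
  SNR definition that is well defined against a deterministic signal.
* `noisy_sinusoid()` — `sin(i/20) + 0.3 U(0,1)`: noise small enough to leave
  amplitudes (and classes) nearly unchanged while scrambling local order
  relations, the canonical case where PerEn saturates and DispEn does not.

These generators emulate spectral slope, determinism, regularity mixing and
additive noise. They do **not** emulate nonstationarity, heavy-tailed
amplitude distributions, oscillatory morphology (ECG/EEG waveforms) or
measurement quantization, so passing benchmarks here demonstrates estimator
behavior on controlled dynamics, not clinical validity on physiological
recordings.

## What the estimators converge to

A subtlety the test suite encodes: the normalized DispEn of white noise
converges to 1 only when the class occupancies are uniform. That holds for
the `ncdf` mapping (probability integral transform). For `logsig` on Gaussian
input the limiting class probabilities are
`pnorm(qlogis(k/c)) - pnorm(qlogis((k-1)/c))`, giving an asymptote of about
`0.917` at `c = 6, m = 2`; the saturation tests assert against these
mapping-specific limits, not against 1.

## Stability benchmark caveat

The MIX stability comparison (`mix_cv_comparison()`: CV of each estimator
over 20 seeded `MIX(p = 0.5)` realizations of 1000 samples) reproduces the
qualitative pattern that SampEn at small tolerance is by far the least
stable estimator, and the reported SampEn CV level itself. The dispersion
CV *levels* depend strongly on details of the generating pipeline (mixture
constants, windowing, averaging across windows); across every variant we
examined they come out between one and a few times `10^-2` at these problem
sizes, and at the smallest-tolerance end SampEn remains several-fold less
stable than DispEn/FDispEn at matched settings. Comparisons of CVs across
publications should therefore fix the full generation pipeline, not just
`(p, N)`.

## Problem sizes

The test suite uses the sizes the estimators are designed around: worked
examples of 10 samples, invariance and oracle checks on series of 20–300
samples, saturation and noise-color experiments at `N` up to 1000 with 20–40
seeded realizations, forbidden-pattern censuses on a 10,000-sample logistic
trajectory, and a 15,000-sample parameter sweep for the sliding-window
profile. Brute-force oracles (naive pattern recount, exhaustive SampEn pair
count, closed-form entropies) back every fast path at small `N`.

## Known limitations

* Univariate, single-scale analysis only: no multiscale, refined-composite,
  or multivariate variants, and no weighted pattern counts.
* Entropy values are sample-index based; the optional sampling rate is
  metadata only.
* SampEn is `O(N^2)` in time and memory (pairwise distance matrix); it is
  intended here as a comparator, not for very long records.
* The Lempel-Ziv comparator fixes one variant (median binarization, LZ76
  exhaustive parsing, `c(n) log2(n) / n` normalization); other binarizations
  change its absolute level.
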