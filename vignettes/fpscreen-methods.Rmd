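---
title: "Methods: interferogram simulation, feature mapping and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interferogram simulation, feature mapping and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpscreen)
```

## The physical model

A two-beam Fabry–Perot cavity of geometric length $l$ filled with a medium
of refractive index $n$ reflects a broadband source into the fringe pattern

$$T(\lambda) = 1 + \cos\!\left(\frac{4\pi n l}{\lambda}\right),$$

the phase being $\varphi = 4\pi n l/\lambda$. Maxima sit at
$\lambda_m = 2nl/m$ for integer fringe order $m$; near a wavelength
$\lambda_0$ the fringe spacing (free spectral range) is approximately
$\lambda_0^2/2nl$, so at $l = 280\ \mu m$ and $\lambda_0 = 1550$ nm it
shrinks from 3.30 nm at $n = 1.30$ to 2.86 nm at $n = 1.50$. That
dependence of spacing, fringe count and fringe position on $n$ is the
physical signal the classifier exploits; the cavity length is held fixed so
$n$ is the only varying quantity.

`theoretical_interferogram()` implements $T$ literally as the two-beam
cosine model. Multi-beam (Airy) corrections, mirror tilt, polarization and
cavity-length drift are deliberately out of scope: the reference signal is
a comparison template, not an instrument model. All lengths are handled in
nm internally; the cavity length is entered in µm and converted once at the
model boundary.

## The synthetic acquisition model

`synthetic_interferogram()` emulates one optical-spectrum-analyzer trace:

$$P(\lambda) = E(\lambda)\,[1 + V\cos\varphi] + \varepsilon(\lambda).$$

Design choices, each configurable through `cavity_model()`:

* **Envelope** $E$: the source line shape is not dictated by anything we
  can reproduce, so a Gaussian centred at 1550 nm with FWHM equal to the
  35 nm spectral width is used — the conventional first-order model of a
  superluminescent diode.
* **Visibility** $V = 0.9956$ by default, the fringe contrast of a
  well-aligned 280 µm cavity. A test verifies that the counted contrast
  $(I_{max}-I_{min})/(I_{max}+I_{min})$ over the central fringe reproduces
  the configured value.
* **Noise**: additive zero-mean Gaussian with standard deviation
  `noise_sd` *relative to the peak power*, default 1%. A relative additive
  model is the simplest mechanism consistent with a single published
  contrast figure; detector shot/read noise structure is not modelled.
* **Wavelength grid**: 2001 uniform points over 1530–1570 nm (0.02 nm
  step). OSA resolution is a free parameter; tests that compare fringe
  positions against the closed form at the 0.1% level use an 8001-point
  grid so grid quantisation (half a step per detected peak) stays an order
  of magnitude below the tolerance.
* **Dispersion**: certified liquids are labeled at 589.3 nm but operate at
  1550 nm. Datasheet values at 1550 nm are not portable, so the operating
  index defaults to the label index (identity mapping) with a per-liquid
  override available. Class labels always use the label-scale index.

`generate_study_design()` reproduces the calibration campaign: 21 liquids
spanning 1.30–1.50 in 0.01 steps, 10 replicates each, 210 spectra. One
master seed is expanded into per-spectrum noise seeds, so the whole design
is reproducible from a single integer.

## Feature mapping

Each spectrum is mapped to one 18-column row (`extract_features()`):

| slot | meaning | default / unit |
|------|---------|----------------|
| F1 | number of local maxima after thresholding | count |
| F2 | global maximum power | power units |
| F3 | threshold fraction | 0.05 |
| F4 | amplitude factor $f = ssmax/\mathrm{global\ max}$ | – |
| F5–F8 | mean/max/min/median spacing of consecutive maxima | nm |
| F9 | distortion $D = \lvert(1 - area_{exp} f)/area_{sym}\rvert$ | – |
| F10 | axial shift of global maxima | nm, signed |
| F11 | RMSE of $f\cdot$experimental vs theoretical | power units |
| F12 | cavity length | µm |
| F13, F14 | window bounds | nm |
| F15 | power amplitude (max − min) | power units |
| F16, F17 | wavelength of maximum power, measured / theoretical | nm |
| F18 | target (1 = cancer, 0 = healthy) | – |

Numerical conventions, chosen once and tested:

* **Thresholding** flags samples below `threshold × global max` as
  excluded from maxima analysis; power values are retained and the global
  maximum is unchanged. A spectrum without positive power is a degenerate
  input and is rejected.
* **Peak detection** accepts interior points strictly greater than both
  neighbours among the retained samples; plateaus count once, at their
  leftmost point. No prominence or smoothing filter is applied — at 1%
  noise F1 therefore counts noise-induced micro-peaks on top of the true
  fringes, and F7 collapses towards the grid step. This is intentional:
  the feature set as defined is the input contract of the classifiers,
  which absorb the noise. An exhaustive neighbour-scan oracle pins the
  implementation on random short signals.
* **Fewer than two maxima** make F5–F8 a sentinel 0 rather than `NA`, so
  degenerate spectra still produce complete rows (a row is complete or
  rejected, never partial).
* **Areas** (F9) use composite Simpson on a shared uniform grid with an odd
  point count; spectra on unequal or even-length grids are linearly
  resampled first. The distortion formula is applied exactly in its printed
  asymmetric form — for a self-compared signal of area $A$ it yields
  $\lvert 1-A\rvert/A$, not 0; no dimensional "correction" is invented.
* **RMSE** (F11) scales the experimental signal by $f$ *before*
  differencing, so F11 is expressed in simulation units and is invariant
  under rescaling of the measured power. This also makes F4–F11 satisfy
  clean scale-invariance laws (tested): multiplying the measured power by
  $c$ scales F2, F15 by $c$, F4 by $1/c$, and leaves the rest unchanged.
* **Ties** for a global maximum are broken towards the lowest wavelength,
  deterministically. Under the Gaussian envelope adjacent fringe peaks can
  tie within noise, so F10 is occasionally a whole free spectral range —
  a known ambiguity of peak-based alignment that is left visible to the
  classifier rather than hidden by unwrapping.

## Labels, splits and folds

`assign_label()` maps label indices ≤ 1.38 to healthy (0) and ≥ 1.39 to
cancer (1), with an $\varepsilon = 10^{-6}$ guard for the floating-point
0.01 grid; the default design therefore splits 90/120 (43%/57%).

`split_validation()` reserves a stratified 20% of rows
(`round(0.2 n_c)` per class: 18 healthy + 24 sick of 210) before any
training. Row-level stratified sampling is the default because it keeps
exact class proportions at the stated fraction; since replicates of one
liquid are nearly identical, a `group_by_liquid = TRUE` mode moves whole
liquids instead for a leakage-free (and harder) protocol in which
validation indices are entirely unseen. Both modes are deterministic given
a seed.

`stratified_kfold()` deals each class round-robin after shuffling, so
per-fold class counts deviate from exact proportionality by less than one
row for any admissible $k$; $k = 3$ is the default (small enough that each
fold keeps 30 healthy + 40 sick of the full design), and the partition
property is tested for $k \in \{3,5,7,9\}$.

## Classifiers

Four families, instantiated with the study's settings via
`classifier_spec()`:

* **Random forest** (`randomForest`): 100 Gini trees, minimum leaf size 1.
* **Gradient-boosted trees** (`xgboost`): gbtree booster, learning rate
  0.3, minimum split loss 0, depth 6, uniform sampling, 100 rounds,
  single-threaded for determinism.
* **Gaussian naive Bayes** (`e1071::naiveBayes`): empirical priors;
  variance smoothing adds $10^{-9} \times$ the largest feature variance to
  every class-conditional variance (a one-row class contributes variance 0
  before smoothing).
* **Neural net**: a dense 32/16/1 network with ReLU, ReLU and sigmoid
  activations trained full-batch for 200 epochs with Adam; implemented
  in-package as a compact MLP since no installed R package provides a
  multi-hidden-layer dense net. Features are standardised inside this
  family only; tree and Bayes families see raw features. The neural family
  is tolerance-tested, not bit-tested.

Trees and Bayes are exactly seed-deterministic; no feature scaling or
hyperparameter search is performed anywhere.

`run_experiment()` is the fitting entry point: per classifier it trains
$k$ fold models (each scored on its held-out fold *and* on its own training
rows — the literature reports both conventions, so both are always stored;
`fold_score` selects which one summaries display, holdout by default) plus
a final model on all training rows scored on the validation set. Metrics
follow the defining formulas, with zero-denominator cases reported as `NA`
with a warning, never silently 0. Wall-clock training/prediction times are
logged for information and never asserted.

## Problem sizes and what the tests show

The test suite and the acceptance script run the full 210-spectrum design
on the 2001-point grid (seconds per pipeline run); the noise-robustness
property uses 10 master seeds per noise level over
$\sigma \in \{0, 0.01, 0.05, 0.2\}$, and unit tests use a reduced design
(5 liquids × 4 replicates, 401-point grid) chosen to exercise every code
path quickly. With `noise_sd = 0` every classical classifier separates the
classes perfectly — replicates are then identical, so this validates the
plumbing, not generalisation. The group-aware split and the noise sweep are
the informative stress tests.

Passing on synthetic data shows the pipeline reproduces the *designed*
relationship between refractive index and fringe geometry under additive
noise. It does not show robustness to what the generator omits: real
dispersion (label vs 1550 nm index offsets), source ripple and background
slope, cavity-length drift between acquisitions, correlated detector noise,
or biological variability of actual tissue — measured spectra remain the
only test of those.
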