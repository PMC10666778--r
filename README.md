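# vpcsp

Spatial filtering for two-class motor-imagery EEG decoding, built around a
**variance-characteristic-preserving common spatial pattern (VPCSP)**
estimator: classical CSP augmented with a graph-Laplacian smoothness penalty
on the spatially projected time series.

## The problem and the model

Motor imagery modulates the power of sensorimotor rhythms (ERD/ERS in the
mu/beta bands).  CSP finds spatial filters `w` that maximize the projected
band-power ratio between the two classes,

    J(w) = (w' Γ₁ w) / (w' Γ₂ w),      Γₙ = class-mean of Xᵢ Xᵢ',

solved as the generalized eigenproblem `Γ₁ w = λ Γ₂ w`.  Because Γ is a
second-moment estimate, transient artifacts and outliers leak into the
filters.  VPCSP views each projected series `z = w'X` as a graph whose nodes
are time points and whose edges join samples exactly `l` apart.  The penalty

    R(z) = Σᵢⱼ (zᵢ − zⱼ)² Aᵢⱼ = 2 z' L z,     L = D − A,

is small for series that vary slowly at lag `l` while leaving shorter-range
(local variance) structure untouched.  Folding it into the denominator
yields a single penalized eigenproblem,

    M = (1 − β) Γ₂ + β (X₁ L X₁' + X₂ L X₂'),      Γ₁ w = λ M w,

with `β ∈ [0, 1)` the penalty weight (`β = 0` is exactly CSP).  Multiple
spacings can be constrained at once via `L = L₁ + … + L_q`.  The package
also provides delay embedding (stacking a lagged copy of the signal so
spatial filters act spectrally), a three-band filter bank
(4–20 / 8–24 / 12–28 Hz) whose per-band classifier probabilities are fused
by averaging, log-variance features `f_k = log(var Z_k / Σ var Zᵢ)`, RBF-SVM
and LDA classifiers, stratified 64/16/20 five-fold cross-validation, and
Gaussian-process expected-improvement optimization of `(l, β, q)`.

A calibrated synthetic generator (`generate_mi_eeg()`) produces two-class
EEG with known mixing, class-dependent source power, sensor noise, and
transient artifact bursts, so every stage is testable without external
recordings.  EDF recordings (with an event-table sidecar) and a native
binary epoch container are supported for real data.

## Worked example

```r
library(vpcsp)

# 120 trials, 16 channels, 250 Hz; 10% of trials carry a 20x-RMS burst
sim <- generate_mi_eeg(synth_config(artifact_rate = 0.1, noise_sigma = 4, seed = 1))
sim$epochs
#> <eeg_epochs> 120 trials x 16 channels x 750 samples @ 250 Hz
#>   window: [0.000, 3.000] s; classes: 60 / 60 trials

x <- bandpass(sim$epochs, band_spec(8, 32))
model <- vpcsp(x, beta = 0.5, l = 1, K = 3)
model
#> <vpcsp> 6 filters on 16 channels
#>   beta = 0.5, single (l = 1), K = 3, delay_embed = FALSE
#>   eigenvalues:  1.479, 1.113, 1.054, 0.885, 0.8692, 0.8656

report <- cross_validate(x, config = vpcsp_config(beta = 0.5, l = 1), seed = 1)
report
#> <eval_report> 5 folds, svm-rbf classifier (seed 1)
#>  fold accuracy precision recall   mode l beta q n_test
#>     1    95.83     92.31 100.00 single 1  0.5 1     24
#>     2    91.67     85.71 100.00 single 1  0.5 1     24
#>     3    95.83    100.00  91.67 single 1  0.5 1     24
#>     4    91.67    100.00  83.33 single 1  0.5 1     24
#>     5    87.50     90.91  83.33 single 1  0.5 1     24
#> mean: accuracy 92.50%  precision 93.79%  recall 91.67%
```

The eigenvalues are the per-filter class-power ratios against the penalized
denominator: values above 1 favor class 1, below 1 favor class 2.  On the
same noisy artifact-bearing data the `beta = 0` (classical CSP) pipeline
scores 91.67% under identical splits — the penalty buys a modest but
consistent margin.  `predict(model, x)` returns the 6 log-variance features
per trial; `plot(model)` draws the spatial patterns; the `vpcsp_fb()` /
`predict()` pair runs the full filter-bank decoder, and `bayes_optimize()`
tunes `(l, β, q)` against a validation split.

A command-line wrapper (`inst/cli/vpcsp-cli.R`) exposes
`simulate` / `fit` / `evaluate` subcommands driven by a YAML run
configuration.

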