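---
title: "Variance-preserving spatial filtering for motor-imagery EEG: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance-preserving spatial filtering for motor-imagery EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vpcsp)
```

## The estimator

Two-class motor-imagery decoding rests on a simple physiological fact:
imagining a movement modulates the band power of sensorimotor rhythms
(mu, ~8–13 Hz; beta, ~13–30 Hz) with a lateralized topography.  Common
spatial patterns (CSP) exploits this by finding a spatial filter $w$ that
maximizes the ratio of projected power between the classes,
$J(w) = w^\top\Gamma_1 w / w^\top\Gamma_2 w$, where $\Gamma_n$ is the
class-mean of the trial second-moment matrices $X_i X_i^\top$
($X_i \in \mathbb{R}^{C\times T}$, microvolts, band-filtered, epoched).
The maximizers are generalized eigenvectors of $(\Gamma_1, \Gamma_2)$; the
$K$ largest- and $K$ smallest-eigenvalue vectors form $2K$ filters whose
normalized log band powers feed a classifier.

Because $\Gamma$ is a raw second moment, a single high-amplitude transient
(electrode pop, EMG burst) in a handful of trials can dominate the
eigenstructure.  The penalized variant implemented here treats each
projected series $z = w^\top X$ as a signal on a graph whose nodes are the
$T$ time points and whose edges join samples exactly $l$ apart
($A_{ij} = 1 \iff |i-j| = l$).  The quadratic form

$$R(z) \;=\; \sum_{i,j} (z_i - z_j)^2 A_{ij} \;=\; 2\, z^\top L z,
  \qquad L = D - A,$$

is zero for constants, grows quadratically with amplitude, and — because
pairs closer than $l$ are *not* connected — leaves the short-range variance
structure that carries the ERD/ERS contrast untouched while punishing
point-to-point abnormalities.  Averaging the per-trial quadratic-form
matrices $X_i L X_i^\top$ within each class and folding them into the
denominator gives a single symmetric-definite eigenproblem

$$M \;=\; (1-\beta)\,\Gamma_2 \;+\; \beta\,(P_1 + P_2), \qquad
  \Gamma_1 w = \lambda M w,$$

solved by Cholesky whitening of $M$; columns are normalized to
$w^\top M w = 1$.  At $\beta = 0$ this *is* CSP, which the test suite
asserts exactly (eigenvalues to $10^{-6}$ relative, principal angles of the
selected subspaces below $10^{-4}$ rad).  Several lags can be constrained
at once through $L = L_1 + \dots + L_q$ (`spacing_mode = "cumulative"`),
and a delayed copy of the signal can be stacked onto the channel dimension
(`delay_embed`, default lag one sample) so that spatial weights act
spectrally.

## Parameters that matter

* `beta` ∈ [0, 1): penalty weight; 0 disables the penalty.  Default 0.5 —
  the midpoint of the admissible range, a neutral prior for a quantity that
  is meant to be tuned per subject.
* `l` (samples): edge spacing of the graph.  Small `l` (1–3 at 100–250 Hz)
  penalizes sample-to-sample jumps, which transients produce and narrowband
  rhythms do not; large `l` approaches a long-lag difference penalty.
* `q`: largest spacing in cumulative mode; spacings 1..q are summed.
* `K`: filter pairs, default 3 (6 features) — the common choice for
  CSP-family methods; must satisfy $2K \le C$.
* `trace_normalize` (default on): per-trial unit-trace covariance
  normalization *and* scale balancing inside $M$ (below).
* Preprocessing: 4th-order Butterworth, zero-phase (forward–backward)
  filtering by default — offline epoched analysis tolerates the doubled
  effective order and gains zero group delay, so ERD timing is not shifted.
  The broadband default is 8–32 Hz; the filter-bank variant uses
  4–20 / 8–24 / 12–28 Hz applied to the *raw* epochs (the lowest band
  extends below the broadband edge, so chaining the two filters would
  defeat its purpose).
* Classifier: RBF-kernel SVM, cost 1, kernel width
  $1/(d\cdot\overline{\mathrm{var}\,f})$ on the $d$ log-variance features,
  with probabilities from a logistic (Platt-style) calibration of decision
  values — calibration on decision values keeps predictions deterministic
  under a seed.  LDA is available as the usual lighter alternative and
  behaves comparably on these features (the acceptance script logs the
  paired signed-rank comparison).

## Numerical choices

**Scale balancing in $M$.**  $\Gamma_2$ and the penalty matrices live on
different scales: the penalty grows with graph degree and with $T$.  With
`trace_normalize` on, $\Gamma_2$ and $P_1 + P_2$ are each scaled to unit
trace before the $(1-\beta)/\beta$ combination, so $\beta$ is comparable
across datasets and sampling rates.  The combination is then rescaled by
$\mathrm{tr}(\Gamma_2)$ — not to a fixed trace — so that at $\beta = 0$ the
matrix $M$ equals $\Gamma_2$ *exactly* and the CSP reduction holds to
machine precision rather than up to a data-dependent factor.  Raw-scale
mode (`trace_normalize = FALSE`) preserves the literal convex combination
for users who want it.

**Ridge loading.**  $10^{-8}\cdot\mathrm{tr}(M)/C$ is added to the
diagonal of every matrix that gets inverted; high-density montages
estimated from a few hundred trials are otherwise near-singular.

**Determinism.**  Eigenvector signs are canonicalized (largest-magnitude
entry positive); all stochastic components (splits, optimizer proposals,
classifier internals) draw from one seeded generator and restore the
caller's RNG state.  Variances in the features are population variances
(divide by $T$), matching the power interpretation; the normalization
ratio cancels the convention anyway.  Zero variances are floored at
$10^{-12}$ of the largest variance; an all-constant projection is an
error, not a silent feature.

**Conventions.**  Epoch cropping uses half-open $[t_0, t_1)$ windows with
0-based sample indexing, so a 3-second window at 100 Hz is exactly 300
samples.  A spacing $l \ge T$ would give an empty graph and silently turn
the penalty off; it is rejected.  Fusion ties go to class 1.

## Open design points and how they were resolved

* **Trial aggregation in the penalty** is not dictated by the quadratic
  form itself; the per-trial matrices are *averaged* within each class,
  mirroring covariance averaging.  Concatenating trials would create
  spurious cross-trial edges.
* **One eigenproblem or two.**  The $2K$ filters come from the single
  spectrum of $M^{-1}\Gamma_1$ (largest and smallest eigenvalues), exactly
  parallel to classical CSP.  A two-problem mode (class roles swapped for
  the second $K$) exists behind `two_problem = FALSE`.
* **How `l` and `q` interact** when both are tunable: the search space
  carries an explicit mode switch — single-spacing (`l` free, `q` pinned
  to 1) versus cumulative (`q` free) — and the optimizer explores both.
* **Refit after tuning** uses the training set only; the validation set
  stays held out (a `refit = "train+val"` flag exists).
* **Fusion** is the unweighted mean of branch probabilities — the simplest
  rule consistent with "probabilistic fusion", and convexity makes the
  fused outputs valid probabilities by construction.
* **Hyperparameter bounds**: $l \in [1, \min(40, T'-1)]$,
  $\beta \in [0, 0.99]$, $q \in [1, 20]$, 50 evaluations with a
  Gaussian-process surrogate and expected improvement (10 space-filling
  starts, 256-candidate acquisition maximization).  A space collapsed to a
  point short-circuits after one evaluation.

## What the synthetic generator does and does not emulate

`generate_mi_eeg()` draws band-limited (9–13 Hz) unit-RMS noise sources,
mixes them through random orthonormal columns into $C$ sensors, scales the
first source's amplitude by $\sqrt{\text{erd\_ratio}}$ in class 1 (a
stationary within-trial power modulation), adds spatially white Gaussian
noise, and optionally injects half-cosine single-channel bursts of
amplitude `artifact_amp` × background RMS into a fraction of trials.  The
mixing matrix, source index, amplitudes and artifact trials are returned
as ground truth, which is what lets the tests assert pattern recovery
(cosine similarity of the top spatial pattern to the true mixing column)
rather than only accuracy.

It does **not** emulate 1/f background spectra, time-locked ERD ramps,
volume-conduction head geometry, eye/muscle artifact topographies, or
non-stationarity across a session.  Passing tests therefore demonstrate
the estimator's correctness and its robustness mechanism under controlled
violations, not state-of-the-art performance on competition recordings.

## Problem sizes and the robustness protocol

Unit and property tests run at small sizes (6–8 channels, 100 Hz, 1–1.5 s
epochs, 24–60 trials) so the suite stays fast; the calibration checks run
the full default configuration (16 channels, 250 Hz, 3 s, 120 trials),
where the clean five-fold CSP pipeline decodes essentially at ceiling.

That ceiling is the reason the robustness benchmark
(`robustness_benchmark()`) runs at `noise_sigma = 4` instead of the
generator default of 1: with 10% artifact trials at the default noise
level every decoder — penalized or not — scores 100%, and a comparison has
no headroom.  At the noisier operating point the clean task sits near
87–92% and the artifact comparison becomes informative; the benchmark
fixes a small $(l, \beta)$ grid ($l \in \{1, 2\}$,
$\beta \in \{0.25, 0.5, 0.75\}$) selected per fold on the validation set,
against a $\beta = 0$ baseline on identical splits, averaged over ten
generator seeds.  The acceptance script recomputes this end to end.

## Known limitations

* Two classes only; no multiclass extension.
* The graph is fixed and unweighted over time points; no data-adaptive or
  channel-domain graphs.
* Covariance regularization is plain ridge loading; no shrinkage
  estimators.
* The EDF reader handles continuous equal-rate recordings with an event
  sidecar; EDF+ annotations are not parsed.
* Band-limited-noise sources make the synthetic task easier than real EEG;
  absolute accuracies on it should not be compared to published
  competition numbers.
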