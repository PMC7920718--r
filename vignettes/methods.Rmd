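---
title: "Methods: synthetic fNIRS walking-imagery decoding with cdSRC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic fNIRS walking-imagery decoding with cdSRC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its models and the design
choices behind them: what is computed, under which assumptions, which
knobs matter, and what a green test does and does not establish.

## 1. The decoding problem

A dual-wavelength (760/850 nm) continuous-wave fNIRS system samples 16
channels over bilateral motor cortex at 20 Hz while a subject alternates
between two mental states: kinesthetic walking imagery and a relaxed
idle state. Decoding is binary classification of single 10 s task
blocks from the oxyhemoglobin (HbO) response. The package implements
the full offline stack and, because no public recordings exist for this
paradigm, a synthetic generator that stands in for the data with a known
ground truth.

## 2. Paradigm schedule

One session is 60 s baseline, then n trials of (2 s cue + 10 s task +
30 s rest), then 180 s eyes-closed rest; classes are exactly balanced
over all sessions and their order is a seeded uniform permutation.
Defaults: 2 sessions × 40 trials.

A note on the session length: this paradigm is commonly summarized with
a 1860 s total for a 40-trial session, but the stated segments sum to
60 + 42·40 + 180 = 1920 s. The segment durations are what every
downstream computation depends on (task windows, trial counts, epoch
indexing), so the schedule follows them and a 40-trial session is
1920 s. The discrepancy is carried as a deliberately failing acceptance
assertion rather than papered over.

Sample counts use one convention everywhere: a segment of duration `T`
at rate `fs` spans `floor(T·fs)` samples, and a window starting `s`
seconds after an onset begins at sample `round(s·fs)` (half-open
interval on the right).

## 3. Synthetic data generator

**What it emulates.** Each walk trial adds to every channel an
amplitude-scaled, unit-peak double-gamma hemodynamic response starting
at task onset; idle trials add nothing. The HRF has a 2 s
neural-to-hemodynamic lag and a 5 s rise to peak (so the response peaks
~7 s after task onset), a late undershoot (mode 15 s, ratio 1/6), and
HbR is −1/3 × HbO. Per-trial amplitudes are N(0.06, 0.01²) µmol/L
truncated at zero ("easy" preset) — chosen once so that simulated HbO
excursions stay within the ~−0.01 to 0.08 µmol/L range reported for
this kind of recording, with trial-to-trial variability typical of
block-design studies; per-channel gains are drawn once per subject from
U(0.6, 1). The "null" preset sets the amplitude to exactly zero and is
the negative control: any decoder claiming above-chance accuracy on it
is leaking information.

A design note on the response shape: convolving a canonical double-gamma
HRF with the full 10 s task boxcar places the response peak ~12 s after
onset — outside the task window and inconsistent with the ~2 s lag +
~5 s rise timing that motivates the 2–8 s feature window. Each trial
therefore contributes the event response itself (unit-peak HRF), which
honors both the timing and the within-window peak.

**Noise.** Per channel: sinusoids with channel-specific random frequency
and phase in the cardiac (1.2–1.6 Hz, 0.02 µmol/L), respiration
(0.15–0.3 Hz, 0.015 µmol/L) and Mayer (0.08–0.12 Hz, 0.02 µmol/L)
bands; linear drift (slope U(−2, 2)·10⁻⁵ µmol/L/s) plus a random-walk
drift (step sd 2·10⁻⁴ µmol/L); white noise (sd 0.005 µmol/L); and
sparse motion spikes (0.5/min, ~0.1 µmol/L, 1.5 s exponential decay)
added with the *same* sign to HbO and HbR — the positively-correlated
signature that CBSI is designed to remove, whereas the true hemodynamic
response is anti-correlated. Noise amplitudes were chosen once as
plausible magnitudes relative to the ~0.06 µmol/L response and were not
revisited.

The noisy concentrations are mapped to optical density by the exact
Beer-Lambert forward model, so conversion back is lossless and the
round trip is testable to machine precision.

**What it does not emulate.** No photon transport or head anatomy, no
short-separation channels, no channel-to-channel noise correlation, no
serially-dependent artifacts (e.g. slow posture changes), no
non-stationary vigilance effects, and the per-class amplitude
distribution is an invention — no public data constrains it. A green
test on this world shows the *pipeline* is correct and that the
classifier ordering holds under the stated assumptions; it is not
evidence about real subjects.

## 4. Beer-Lambert conversion

The MBLL is definitionally the 2×2 linear system
`ΔOD_λ = d·(ε_λ,HbO ΔHbO + ε_λ,HbR ΔHbR)`; conversion implements its
cofactor solution and is test-asserted equal to a generic linear solver
at 1e-12 on random inputs. (Printed closed forms of these equations in
the literature sometimes carry transcription slips in the numerator
coefficients; the linear system is what is implemented.) Units: ΔOD is dimensionless, concentrations are
µmol/L via a fixed 10⁶ scaling of mol/L, d = 18 cm combines DPF 6 with
a 3 cm optode separation. Inputs with NaNs are rejected with the
offending channel/timepoint; a singular extinction table is rejected at
construction.

## 5. Preprocessing

Order is fixed: band-pass → CBSI → baseline correction.

**Band-pass.** First-order Butterworth, 0.02–0.1 Hz, designed from the
analog prototype by the band transform and bilinear transform with
frequency prewarping (coefficients agree with standard DSP references).
Zero-phase forward-backward application is the default so features stay
time-locked to onsets; it squares the magnitude response, which the
attenuation tests account for. Edge handling is odd-reflect padding of
`3·fs/low` samples (~150 s at the defaults) — the 0.02 Hz edge has a
long transient and the default padding of common implementations is far
too short for it. Causal single-pass mode is a flag. Only order 1 is
supported; the band already rejects all three stated physiological
bands, with attenuation verified against the closed-form analog
magnitude response.

**CBSI.** Per channel, α = σ(HbO)/σ(HbR), HbO′ = (HbO − α·HbR)/2,
HbR′ = −HbO′/α; the output pair is exactly anti-correlated, and any
artifact entering HbO and HbR with equal amplitude and sign cancels
when α = 1. Zero-variance HbR channels pass through with a warning
rather than dividing by zero.

**Baseline correction.** No formula is fixed by the source; the
realization here subtracts the whole-recording least-squares line, then
the mean of the baseline segment(s), so the baseline period averages
zero. Per-trial local baselining was rejected because, with task blocks
this close together, it subtracts task signal into neighboring trials.

## 6. Features

M, P, R per channel over the window, HbO only; P is the signed maximum
(the "maximum activation degree"), not |max|. The window origin is task
onset (cue excluded). Column order is all channels for M, then P, then
R. The algebraic identity R² = M² + population variance and P ≥ M are
property-tested. The task-relative presets 0–10, 2–8, 3–9 and 4–10 s
exist because the first ~2 s of the task precede the hemodynamic
response; 2–8 s brackets the response peak.

## 7. cdSRC

Per class, a dictionary of ℓ2-normalized training feature vectors.
Scoring a test vector combines:

* **cdOMP** — greedy OMP against the class dictionary: select the
  unselected atom with the largest |inner product| with the current
  residual (ties → lowest column index, for determinism), re-project on
  the selected span, repeat until the support reaches the sparsity
  level (10), the residual norm falls below 1e-10 (prevents projector
  degeneracy on exact matches), or all inner products vanish.
  Rank-deficient supports fall back to the pseudoinverse. The residual
  path is non-increasing and the final residual is orthogonal to every
  selected atom; both are tested against an independent
  normal-equations OMP.
* **cdKNN** — mean of the K = 5 smallest Euclidean distances to the
  class's (unnormalized) training vectors; K mirrors the KNN baseline
  since no separate value is stated, clipped to the class size.

The per-class residual-norm vector and distance vector are each
normalized to unit sum (all-zero vectors, including residuals below
1e-8·‖x‖ which mean exact reconstruction, normalize to uniform); the
fused score is s_c = r̃_c + λ·d̃_c with λ = 0.05 and the argmin wins,
ties to the first class in sorted order. λ is read as the weight on the
distance term — a small distance-based correction to a residual-led
decision; only the two ingredients and λ's value are fixed a priori, so
λ's role is documented here as a config semantic.

**Standardization.** cdSRC input columns are divided by the training
fold's standard deviation but *not* centered. This is deliberate: on a
balanced two-class problem, centering places the class means at ±µ, the
two normalized dictionaries become mirror images, and OMP residuals —
which are invariant to atom sign — lose the class information entirely
(measured on the easy preset: mean-feature LOOCV drops from ~0.94 to
chance). Classic sparse-representation classifiers likewise operate on
uncentered, norm-scaled data.

## 8. Baseline classifiers

One `fit_predict` contract; all deterministic.

* **SVM**: RBF kernel, γ = 1, C = 2, class weight 1.05 on the walk
  class (which class carries the weight is not fixed a priori; walk,
  the positive class, is the flagged choice). The dual is solved by a
  maximal-violating-pair SMO loop (deterministic working-set selection,
  KKT gap 1e-6), validated against a reference implementation on a
  frozen fixture. The SVM consumes features on their native µmol/L
  scale: with γ fixed at 1, z-scored 16–48-dimensional features give
  squared distances of ~2× dimension, the Gram matrix collapses to the
  identity, and the classifier degenerates to majority voting. γ = 1
  is only meaningful on the scale the features are born at.
* **KNN**: k = 5, Euclidean, majority vote (stable order on distance
  ties), z-scored features.
* **LDA**: pooled covariance, empirical priors, pseudoinverse fallback
  for singular covariance, z-scored features.
* **LR**: batch gradient descent on the mean logistic loss, zero
  initialization, no regularization, α = 0.01, 300 iterations — the
  minimal reading of the stated fitting loop; its trajectory is tested
  against a hand-rolled recursion at 1e-10.

## 9. Evaluation and statistics

LOOCV is trial-level (80 folds per subject at the default schedule) —
the only unit compatible with per-subject accuracy; both sessions are
pooled, flagged in config. Standardization is refitted inside every
fold on the training portion only. Folds whose training set degenerates
to a single class are skipped and reported, never silently dropped.
Summaries are mean ± sample sd (denominator n−1) across subjects.

Classifier comparison: Shapiro–Wilk per classifier (reported NA when a
column is nearly constant), Friedman across classifiers (an all-tied
matrix reports statistic 0 / p 1 instead of NaN), and two-sided
Wilcoxon signed-rank tests of cdSRC against each baseline with zero
differences dropped, exact null where R's implementation permits and
the normal approximation under ties. Raw pairwise p values are
reported; a Holm-correction flag exists but defaults off.

## 10. Orchestration and reproducibility

One flat JSON config drives synth → convert → preprocess → features →
classify → evaluate. A single master seed fans out to per-subject and
per-stage seeds through a fixed linear map (all below 2³¹); every
random draw goes through a state-restoring seeded evaluator, so the
same config + seed give byte-identical report files (outputs carry a
config hash and package version, never timestamps). The config format
is JSON because no YAML/TOML reader is part of the supported dependency
set. The smoke scale lowers the cdOMP sparsity to 5 because a 20-trial
subject leaves only 9 same-class trials in a LOOCV training fold,
below the full-scale dictionary minimum max(sparsity, K) = 10.

## 11. Known limitations

* The synthetic amplitude/noise levels are plausible but unconstrained
  by data; absolute accuracies on the easy preset say nothing about
  real-subject accuracy.
* Only two wavelengths, one global path length, first-order filtering;
  no wavelet/spline artifact removal or PCA denoising.
* cdSRC is implemented for the binary case (the per-class loop is
  generic, but nothing beyond two classes is tested).
* Offline only; no online/streaming decoding.
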