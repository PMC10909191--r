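---
title: "Methods: EEG-based anxiety detection with wavelet and spectral features"
author: "anxeeg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG-based anxiety detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anxeeg)
```

## The detection problem

Anxious states modulate the scalp EEG, most prominently over frontal cortex:
beta-band (13–30 Hz) power rises and alpha-band (8–13 Hz) power falls relative
to calm states. `anxeeg` frames anxiety detection as binary classification of
1-second EEG epochs recorded with a consumer 14-channel headset (Emotiv EPOC
montage, 128 Hz), labeled either by the subject's own affect ratings (SAM
valence/arousal) or by a clinician-style anxiety score (HAM-A). The package
covers the whole chain — signal synthesis, preprocessing, labeling, feature
extraction, class balancing, classification and evaluation — so that every
stage is unit-testable and the end-to-end behaviour is reproducible from a
single seed.

## The synthetic cohort model

Real anxiety EEG datasets are small and access-controlled, so the package
ships a generator that emulates their structure: `n_subjects` subjects, 6
trials of 60 s each by default, 14 named EPOC channels at 128 Hz.

Each trial is a sum of four fixed-frequency oscillations at the band centres
θ = 6, α = 10, β = 20, γ = 35 Hz, with an independent uniform random phase per
channel and trial, plus white Gaussian noise (`noise_sd`, default 2, in the
same arbitrary µV-scale units as the base amplitudes 4/8/4/2 for θ/α/β/γ —
alpha dominance reflecting an awake resting spectrum). Anxiety is a
subject-level state: for an anxious subject the β amplitude is multiplied by
`1 + effect_size` and the α amplitude divided by `1 + effect_size` on the
eight frontal channels (AF3, AF4, F3, F4, F7, F8, FC5, FC6) — the same
channel set the affect equations read. `effect_size` is dimensionless
(default 1); at 0 the two classes are bit-identical by construction, which
gives the null calibration below its teeth.

Three deliberate simplifications matter for interpreting results:

* **Fixed amplitudes, random phases.** Band amplitudes carry no
  subject-specific signature, so with the effect switched off no feature can
  identify a subject and downstream accuracy must sit at chance. Phases *are*
  trial-specific, and phase structure does reach the time-domain wavelet
  coefficients — this is why the null-calibration check uses the phase-blind
  spectral features. With an epoch-level holdout split, epochs of one trial
  appear on both sides of the split, so a nearest-neighbour classifier can
  exploit trial phase fingerprints in wavelet features; that leakage is a
  property of epoch-level splitting (which the evaluation deliberately
  mirrors), not a generator artifact.
* **Oscillation frequencies are integers**, so a 1-s window captures whole
  cycles and epoch boundaries do not introduce spectral leakage that varies
  across epochs.
* **No artifacts or 1/f background.** Blinks, EMG, volume conduction and the
  aperiodic spectral slope are out of scope; passing tests demonstrate the
  pipeline's correctness and sensitivity, not clinical performance.

Annotations are drawn consistently with the class flags: anxious subjects get
a HAM-A total uniform on 21–56 and per-trial SAM ratings uniform over the
anxious region of the 9 × 9 grid; non-anxious subjects get HAM-A 0–20 and
ratings from the complement. Relabeling the generated annotations therefore
recovers the generating flags exactly — a round-trip the tests enforce.

Each subject derives its own RNG stream from the master seed (a fixed affine
map into the 32-bit range), so cohorts are reproducible regardless of the
order in which subjects are simulated.

## Preprocessing

Recordings are band-pass filtered to 4–45 Hz with a 4th-order Butterworth
filter applied forward-backward (`signal::filtfilt`), which doubles the
effective order and cancels phase shift; the tests pin the cross-correlation
peak at lag 0. The filter family is a package choice — only the band is
dictated by the detection problem. Ten channels correlated with anxiety
(AF3, F7, F3, F4, F8, AF4, FC6, FC5, P7, P8) are retained, and the signal is
cut into non-overlapping 1-s epochs, dropping any trailing partial window.
Sampling rates other than 128 Hz are accepted with a warning, because the
wavelet band map below is only aligned with the canonical EEG bands at
128 Hz.

CSV (one row per channel, first column the channel name) is the primary
on-disk format; a minimal 16-bit EDF writer/reader is included for
interoperability, with round-trip error bounded by the per-channel
quantization step.

## Labeling rules

* **SAM**: anxious iff valence ≤ 5 and arousal ≥ 5, *except* the carve-out
  {valence 4–5} × {arousal 5–6}, which is non-anxious — low-intensity mild
  displeasure is not an anxious state. Enumerated over the 9 × 9 grid this
  yields exactly 21 anxious cells (25 − 4). The carve-out overlaps the
  threshold rule; the carve-out wins. Because the corner cells (e.g. 5/5)
  are the ambiguous ones, `carve_out_wins = FALSE` exposes the plain
  threshold rule for sensitivity analyses.
* **HAM-A**: non-anxious for totals 0–20, anxious above 20. The clinical
  literature already calls ≥ 18 severe; 20 is the detection threshold used
  here, and the monotonicity of the rule (raising a score never flips
  anxious → non-anxious) is property-tested.

Trial-level SAM labels and subject-level HAM-A labels are broadcast to every
epoch of the trial/subject.

## Wavelet features

Each channel of a 128-sample epoch is decomposed with a 4-level Daubechies-4
(db4) filter bank. At 128 Hz the dyadic bands align with the canonical EEG
bands: D1 ↔ 32–64 Hz (γ), D2 ↔ 16–32 (β), D3 ↔ 8–16 (α), D4 ↔ 4–8 (θ),
A4 ↔ 0–4 (δ). Two boundary modes are implemented:

* `symmetric` (default): half-sample symmetric extension, coefficient array
  lengths ⌊(n + 7)/2⌋ per level (67/37/22/14/14 from 128 samples) — the
  convention of the common wavelet toolboxes, and the mode used for feature
  extraction;
* `periodization`: circular wrap, length n/2 per level. Only this mode is an
  orthonormal transform, so coefficient energy equals signal energy to
  machine precision; the energy-conservation test runs here. Symmetric
  extension is redundant at the boundaries and cannot satisfy Parseval —
  the perfect-reconstruction test (relative error < 1e−8) runs in both
  modes.

Signal complexity is measured by Shannon entropy of the epoch's value
histogram: 16 equal-width bins spanning the per-channel range (a power of
two, stable at 128 samples; configurable), S = −Σ pᵢ log₂ pᵢ in bits.
Because the attributes below need a *series* and the entropy of one epoch is
a scalar, the sixth component series is the per-bin information profile
{−pᵢ log₂ pᵢ}, whose sum is exactly S. This convention keeps the feature
arithmetic exact (six series per channel) and is isolated in
`entropy_profile()` so alternatives can be swapped; data-relative bin edges
make the entropy features invariant under constant offsets.

Ten statistical attributes summarize each of the six series: mean, median,
25th/75th percentiles (linear interpolation), population variance (divide by
n), standard deviation, RMS, zero- and mean-crossing rates (strict sign
changes per consecutive pair, normalized by n − 1; an exact zero breaks a
crossing), and the mean first difference. Total:
10 channels × 6 series × 10 attributes = **600 features**, named
`<channel>_<component>_<attribute>` in fixed channel-major order.

## Spectral features

A single-segment Hann periodogram is computed per channel and epoch — at 128
samples, multi-segment Welch averaging would leave too little frequency
resolution, so the single full-epoch window is the right estimator at this
scale. Density scaling is chosen so the rectangle-rule integral of the
one-sided spectrum estimates the signal's variance (Parseval; verified within
±10 % over 50 white-noise draws). Band powers integrate the density over
half-open bands [low, high): θ 4–8, α 8–13, β 13–30, γ 30–40 Hz — γ capped at
40 Hz, not Nyquist — so adjacent bands never double-count an edge bin.
`average_power` is the mean of the four band powers (the named-but-undefined
"average" is pinned to this definition) and `total_power` the integral over
the whole spectrum; with the four bands that is 6 values × 10 channels =
**60 features**, plus an optional raw per-bin stacking for high-dimensional
experiments.

## Affect features

Eight valence/arousal quantities are appended to every feature vector,
computed from frontal α and β band powers with `a(...)`/`b(...)` denoting
sums over the named channels:

* V1 = b(AF3,F3)/a(AF3,F3) − b(AF4,F4)/a(AF4,F4)
* V2 = ln a(Fz,AF3,F3) − ln a(Fz,AF4,F4)
* V3 = a(F4) − b(F3)
* V4 = a(F4)/b(F4) − a(F3)/b(F3)
* A1 = a(AF3+AF4+F3+F4) / b(AF3+AF4+F3+F4)
* A2 = 1/A1
* A3 = log₂ [ b(Fz,AF4,F4,AF3,F3) / a(Fz,AF4,F4,AF3,F3) ]
* A4 = −( ln a(Fz,AF4,F4) + ln a(Fz,AF3,F3) )

The EPOC montage has no midline Fz electrode, yet three equations reference
it. The default surrogate interpolates Fz as the mean of F3 and F4 — the
nearest lateral frontal electrodes straddling the midline; `af3_af4` and
`drop_term` are available as alternatives, and the choice is an explicit
argument rather than a silent assumption. Identities the tests enforce:
A1·A2 = 1 to 1e−12; V1/V2 change sign and A1–A3 are invariant under a
left–right hemisphere swap; equal powers force the symmetry zeros.

In wavelet mode the band powers feeding these equations are the mean squares
of the band's coefficient arrays (D3 → α, D2 → β); in spectral mode they are
the integrated band powers — so both extractors produce the same eight affect
columns (608 = 600 + 8 and 68 = 60 + 8 features respectively).

## Balancing and evaluation

SMOTE raises the minority class exactly to the majority count: each synthetic
row is x + u·(x_nn − x) with u ~ U(0,1) and x_nn one of the k = 5 nearest
minority neighbours (k shrinks automatically for tiny minorities); original
rows are preserved verbatim and synthetic rows are flagged. Balancing is
applied to the *training split only* by default — balancing before splitting
leaks interpolated copies of training points into the test set; a
`smote_before_split` flag reproduces that leakier variant for comparison.

Evaluation uses a single stratified 80/20 holdout (a `seed` argument makes
repeated holdout trivial to script). Features are z-scored with parameters
fitted on the training split only. The six classifiers and their defaults:
k-NN with k = 1, LDA (binary, one discriminant; features that are constant
within every class are dropped first, since LDA is undefined for them),
RBF-kernel SVM, random forest with 500 trees, AdaBoost.M1 with 100 depth-1
stump rounds, and gradient boosting with 100 rounds, depth 3, learning rate
0.1 (canonical gradient-boosting defaults). AdaBoost and gradient boosting
are boosting algorithms proper; bagged-tree variants can be emulated via the
hyperparameter overrides if wanted. Reported metrics: accuracy; micro-
averaged recall, which for a forced-choice binary classifier is *identical*
to accuracy; support-weighted precision (micro precision would also collapse
to accuracy, which is why weighting is used); the 2 × 2 confusion matrix
(rows = actual); AUC as the Mann–Whitney rank statistic of the model's
continuous score (mid-ranks for ties; undefined and reported `NA` with a
warning for a single-class test set); and Cohen's κ = (p₀ − pₑ)/(1 − pₑ),
returning 1 by convention (with a warning) in the degenerate all-agree
single-class case.

`run_comparison()` crosses 6 classifiers × 2 feature sets × 2 labelings ×
{with, without} SMOTE into 48 reports; `run_pipeline()` wires the whole chain
to one config object and optionally writes feature tables (CSV), the metric
grid (CSV), reports (JSON) and a manifest with the config and seeds. The
exported functions are the interface; there is no shell wrapper.

## Numerical choices and degenerate inputs

* Wavelet filters are the standard db4 analysis/synthesis taps to 17
  significant digits; single-level decompositions are pinned against values
  computed once with an independent wavelet toolbox and frozen into the
  tests.
* Constant signals: entropy 0 (all mass in one bin), variance 0, crossing
  rates 0; quantiles fall back to the constant.
* Non-finite samples are rejected at the I/O boundary, not silently filtered.
* Zero-variance feature columns get their scale parameter forced to 1 during
  z-scoring (the column stays constant instead of becoming NaN).
* Ties in the k-NN vote and AUC ranks are handled by the seeded tie-break of
  `class::knn` and mid-ranks respectively.
* All simulation, split, SMOTE and ensemble seeds derive from user-supplied
  integers; identical seed + config ⇒ bit-identical outputs, enforced by
  tests.

## Problem sizes used by the test-suite and calibration checks

Unit tests run on single epochs and cohorts of 4–10 subjects with 2–6 trials
of 1–8 s. The calibration checks use 6 subjects × 4 trials × 8 s (192
epochs): with `effect_size = 0`, mean random-forest test accuracy over 20
seeds must lie in [0.40, 0.60] (chance); with `effect_size = 2`, a single
seed must exceed 0.85 accuracy and 0.9 AUC. The SMOTE arithmetic check uses
the 1,440/2,700 class split so the balanced result (2,700/2,700) is verified
at the realistic cohort scale. These sizes are the package's choices for a
desk-scale, fully reproducible demonstration; nothing prevents running the
same pipeline at 23 subjects × 6 × 60 s.

## Known limitations

* Synthetic EEG is stationary sinusoid-plus-noise; no artifacts, no 1/f
  slope, no inter-channel correlation beyond shared class effects. Passing
  tests show pipeline correctness and sensitivity, not clinical validity.
* Epoch-level holdout leaks trial context (see above); subject-level splits
  would be the stricter protocol and can be built from the provenance
  columns.
* The four-level anxiety grading (normal/light/moderate/severe) is out of
  scope; only the binary problem is implemented.
* The spectral feature stack is the 68-feature band-power form; no
  multitaper or autoregressive estimators.
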