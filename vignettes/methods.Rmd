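---
title: "Methods: physiological emotion recognition with affectpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: physiological emotion recognition with affectpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

`affectpipe` implements a complete analysis chain for recognizing the two
principal dimensions of emotion — arousal (intensity) and valence
(pleasantness) — from peripheral and central physiological signals: a
single-lead ECG and nine EEG channels (Fz, F3, F4, Cz, C3, C4, POz, P3,
P4) recorded at 256 Hz while a subject experiences a ~90 s stimulus.
Self-assessment scores on a −4..+4 scale are bipolarized (`score > 0` is
the high/positive class) and a sigmoid-kernel C-SVM is trained to predict
those labels from the physiological features under leave-one-subject-out
(LOSO) cross-validation.

Because no recorded human dataset ships with the package, a synthetic
signal generator with fully known ground truth stands in for it. The
generator is first-class, tested code: it is what makes every estimator
in the chain falsifiable.

# The synthetic generator

**RR series.** The instantaneous inter-beat interval follows

RR(t) = RR₀ + A_LF sin(2π·0.1·t) + A_HF sin(2π·0.25·t) + ε,
ε ~ N(0, σ²)

with defaults RR₀ = 800 ms, A_LF = A_HF = 30 ms, σ = 10 ms — a resting
adult with balanced sympatho-vagal modulation. The two tones sit at the
canonical centers of the LF (0.04–0.15 Hz) and HF (0.15–0.4 Hz) bands.
For a high-arousal window A_LF is multiplied by √e and A_HF divided by
it (e = `arousal_effect`), so the LF/HF power ratio scales by e² while
total modulation power is unchanged. Every modulation parameter is
returned as ground truth.

**ECG.** A fixed 80 ms Mexican-hat template (amplitude 1 mV) is placed
at each beat time, plus 0.2 Hz baseline wander and white noise. This has
no P/T waves by design (a stated non-goal): it is exactly the morphology
needed to exercise the Pan-Tompkins filter/derivative/square/integrate
chain, no more.

**EEG.** Each channel is a sum over bands (θ 4–8, α 8–12, β 13–25, γ
25–40 Hz) of one oscillator per band plus 1/f pink noise. Phase coupling
between channels is planted by mixing, with weight κ, a band-wide shared
oscillator into every channel:

x_ch,b(t) = A_b [√(1−κ)·cos φ_priv(t) + √κ·cos φ_shared(t)]

Private oscillators get a channel-specific frequency drawn from the
inner half of the band plus a Wiener phase drift (default 0.15
rad/sample), which is what makes uncoupled channels genuinely
asynchronous; the shared oscillator sits at the band center. Because the
two components are uncorrelated, expected band power is A_b²/2
independent of κ. High arousal multiplies A_β by `arousal_effect`;
positive valence multiplies κ by `valence_effect` (clipped to 1).

**Artifacts.** `inject_artifacts()` corrupts a chosen fraction of 1 s
epochs with blink-like transients (150 µV, four anterior channels) or
electrode-pop steps (400 µV boxcar on three channels, contained in the
middle of the epoch so its ground-truth span is well defined). The step
amplitude is deliberately large: a step must survive the 0.5–40 Hz
band-pass to be detectable at all, and real pops are of this scale.
Channel flattening (a disconnected electrode) is a whole-channel
phenomenon and lives in `flatten_channel()`.

**What the generator does not emulate.** Volume conduction, realistic
scalp topographies, non-stationary autonomic tone, respiration–cardiac
coupling, movement artifacts. Passing tests therefore demonstrate that
the estimators recover what they claim from signals with the assumed
statistical structure — not that the pipeline's accuracy on real
recordings would match.

# HRV features

`hrv_feature_vector()` runs detection → correction → detrending → the 26
named features of the canonical HRV battery (time domain, frequency
domain, Poincaré, entropies, DFA, correlation dimension).

- **Pan-Tompkins detection**: zero-phase 5–15 Hz band-pass, five-point
  derivative, squaring, 150 ms moving-window integration, adaptive dual
  thresholds with search-back after 1.66× the running RR mean, peak
  refinement on the band-passed waveform. A flat signal returns an
  explicit "undetectable" result.
- **Artifact correction**: intervals deviating more than 250 ms (default)
  from an 11-beat running median are replaced by cubic-spline
  interpolation; more than 20% flagged rejects the window.
- **Detrending**: the smoothness-priors smoother
  trend = (I + λ²D₂ᵀD₂)⁻¹ z with λ = 500 (cutoff ≈ 0.035 Hz at usual
  beat rates). Time-domain and nonlinear features are computed on the
  corrected series with the trend removed but the mean restored;
  spectral features on the zero-mean residual.
- **Spectral features**: cubic-spline tachogram at 4 Hz, Welch PSD (60 s
  Hann segments, 50% overlap), bands VLF < 0.04, LF 0.04–0.15, HF
  0.15–0.4 Hz. The HF band follows the universal convention; normalized
  units divide by total minus VLF power. A 90 s window cannot resolve
  VLF trustworthily, so VLF values carry a `vlf_reliable = FALSE` flag
  rather than being suppressed.
- **pNN50** counts successive differences strictly *greater* than 50 ms
  (the universal definition of NN50).
- **Entropies**: ApEn and SampEn with m = 2, r = 0.2·SD (the common
  toolbox defaults), Chebyshev distance; SampEn excludes self-matches
  and signals an explicit error when no templates match. Both are tested
  for exact equality against an independent O(N²) double-loop oracle.
- **DFA**: α1 over boxes 4–16, α2 over 16–64; α2 needs ≥ 130 beats.
- **D2**: Grassberger–Procaccia at embedding 10, unit delay, Theiler
  window 10, slope over the region 0.5% < C(r) < 30%, with a saturation
  flag comparing against a lower embedding dimension; needs ≥ 200 beats.

A ~90 s window at 800 ms beats holds ~112 intervals, so α2 and D2 do not
meet their preconditions there and are returned `NA`; the block-PCA
stage drops such columns (with a warning) before fitting. On longer
records both features activate automatically.

# EEG preprocessing

The chain is: channel QC → optional single-channel interpolation →
baseline removal and zero-phase 4th-order Butterworth 0.5–40 Hz →
1 s epoching with rule-based rejection → optional infomax-ICA cleanup.

- **Channel QC**: a channel is corrupted when its excess kurtosis is an
  outlier among the nine channels or it is flat for more than 10% of the
  recording ("flat" = runs ≥ 0.1 s of successive differences < 0.01 µV).
  With only nine channels the plain z-score is bounded by
  (n−1)/√n ≈ 2.67, so a z > 5 rule could never fire; the package
  therefore uses a robust z (median/1.4826·MAD), keeping the threshold
  at 5. One corrupted channel is interpolated by inverse-distance
  weighting over the schematic 10-20 montage (spherical splines would be
  overkill at 9 electrodes); two or more reject the subject.
- **Epoch rejection**: an epoch goes when any channel's within-epoch
  kurtosis is a robust-z outlier (> 5) across that channel's epochs, or
  when strictly more than 2 channels contain a sample over 100 µV or an
  inter-sample step over 70 µV. Reason codes are kept per epoch.
- **ICA hook**: natural-gradient infomax (logistic nonlinearity, suited
  to super-Gaussian artifact sources) on the concatenated retained
  epochs, with learning-rate annealing after 100 iterations. Components
  are flagged either by an explicit mask (the expert-input path) or by
  an automatic heuristic: activation-kurtosis robust z > 5, or jointly
  low-frequency dominated (> 25% of power below 4 Hz — oscillatory
  components sit near 2% after the 0.5 Hz high-pass, blinks far above)
  and frontally dominated (> 50% of scalp-map energy on Fz/F3/F4).
  Subjects with more than a third of epochs artifact-affected are
  rejected outright. Non-convergence downgrades gracefully: the record
  passes through unchanged with a logged warning.

# EEG features

**Band power.** Each retained epoch contributes a Hann-tapered
periodogram of the full 1 s epoch (1 Hz resolution); band integrals are
averaged over epochs, making the per-stimulus value a Welch estimate
with 1 s segments. Sub-epoch segmentation is available via `nperseg`,
but 0.5 s segments give 2 Hz resolution, which demonstrably cannot
separate the 4-Hz-wide θ and α bands (tone-recovery error ~40%); the
full-epoch default recovers planted band powers within a few percent.

**Mean phase coherence.** Per band and epoch each channel is reduced to
its band-limited analytic signal — frequency-domain band selection with
a raised-cosine edge taper on positive frequencies, i.e. the band-pass
and Hilbert transform in one step — and the first/last 10% of phase
samples are trimmed against edge effects. For each channel pair,

R² = E[cos Δφ]² + E[sin Δφ]²

with the expectation pooled over all retained phase samples of the
stimulus (per-epoch complex mean phasors averaged across epochs, modulus
taken last). Taking the modulus per epoch and averaging moduli instead
would floor the independence baseline at ~0.5 in θ for 1 s epochs — a
time-bandwidth limit, since one second spans too few phase decorrelation
times at 4–8 Hz. With pooled expectation the independence baseline is
~0.05 in every band, identical or constant-lag channels give exactly 1,
and the statistic is monotone in the planted coupling.

The assembled vector is 26 HRV + 36 band-power (9 channels × 4 bands) +
144 MPC (36 pairs × 4 bands) = 206 features, with block boundaries
recorded for the reduction stage.

# Feature reduction and classification

- **Bipolarization**: label = score > 0; 0 belongs to the low/negative
  class.
- **Split**: by subject, `floor(0.15 · n)` test subjects (38 → 5).
- **Block-wise PCA**, fitted on training subjects only, on standardized
  columns (the blocks mix ms², µV² and ratios; correlation-scale PCA is
  the only defensible choice across such units). Per block the smallest
  component count reaching 95% cumulative variance is kept. Fitting on
  the training side only is the leakage-free reading of an ambiguous
  protocol description; the alternative (fitting on all data) is
  unsupervised and label-blind, and is used only inside the
  self-contained calibration experiments where no test set exists.
- **Normalization**: median / raw MAD (no consistency constant), fitted
  per LOSO fold on the training side and applied to the held-out
  subject. Zero-MAD dimensions fall back to a unit divisor and are
  logged.
- **Grid search**: sigmoid C-SVM (LIBSVM via `e1071`), 15 values of cost
  and gamma log-spaced in [0.1, 1000], maximizing LOSO accuracy; ties
  break toward smaller cost then smaller gamma, making the search
  deterministic.
- **SVM-RFE with correlation bias reduction**, per LOSO fold on its
  training rows: features are scored by the kernel-space margin
  criterion |W² − W²₍₋j₎|; features correlated above |r| = 0.85 (graph
  components) share the group-mean criterion, so a redundant group rises
  or falls together instead of diluting each member's score; one feature
  is eliminated per iteration (the reduced space is ~19-dimensional, so
  this is cheap). Fold rankings are aggregated by median rank (ties:
  mean rank, then name), the LOSO accuracy is traced as a function of
  the top-k features, and the best k is used for the final model and the
  held-out test evaluation.
- **Evaluation**: 2×2 confusion matrix in row percentages (rows sum to
  100), total accuracy, and the F-score of the positive/high class (the
  averaging convention is otherwise unspecified).

# Calibration and sensitivity experiments

`loso_calibration_run()` packages the full generator → features → PCA →
LOSO chain into one call. Two standing experiments validate it:

- **Null calibration**: with effect multipliers 1 the generator carries
  no label information; LOSO accuracy, pooled over 20 seeds of 8
  subjects × 4 stimuli, must stay inside the 95% binomial band around
  50%. This check uses a *fixed* SVM specification (C = 1,
  γ = 1/dim): a grid-search maximum is a selection statistic and sits
  above chance even on label-free data.
- **Sensitivity**: with `arousal_effect = valence_effect = 3` and 20
  subjects, grid-searched LOSO accuracy must exceed the one-sided
  binomial significance threshold for 80 trials (≈ 61%) in at least 90%
  of 20 seeds.

These experiments use a 5×5 parameter grid and skip the ICA hook (no
artifacts are injected, so the hook is an identity on clean data); both
are configuration knobs whose pipeline defaults remain 15 points and
ICA on. Problem sizes (8 or 20 subjects, 90 s windows, 20 seeds) are the
package's chosen replication conditions.

# Numerical choices and edge cases

- Welch PSDs are one-sided densities; a sinusoid of amplitude A
  integrates to A²/2, which the tests assert directly.
- All rejections are classed conditions (`affectpipe_rejection` and
  subclasses), never silent NAs: undetectable ECG, unusable windows,
  subject rejections, undefined SampEn, and degenerate configurations
  each carry their own class.
- Determinism: every stochastic step is seed-controlled; identical
  configuration and seed give byte-identical datasets, splits and
  reports. The subject split draws from an isolated RNG stream so it
  does not disturb the caller's.
- EDF export quantizes to 16 bits over each signal's physical range;
  round-trip error is bounded by 1 quantization step.
- The feature count is 26 + 36 + 144 = 206. Protocol descriptions of
  this design sometimes quote 29 HRV / 209 total features; the canonical
  battery enumerates 26, and the three-feature difference is not
  identifiable from any published enumeration, so 26 is what the package
  computes.

# Known limitations

- The sigmoid kernel is not positive semi-definite; with strongly
  saturating gammas the SVM can behave erratically, which is precisely
  why the grid search spans four decades.
- MPC on 9 scalp channels measures signal synchrony, not source
  connectivity; volume conduction (absent in the generator, present in
  real data) inflates it.
- VLF-band HRV metrics over 90 s windows are reported but flagged
  unreliable; interpret them only on longer recordings.
- The automatic ICA policy is a stand-in for expert component review;
  an explicit component mask reproduces the expert path.
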