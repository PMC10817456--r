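---
title: "Models and methods behind tmseegdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tmseegdx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`tmseegdx` implements a complete analysis chain for discriminating major
depressive disorder (MDD) from healthy controls (HC) using two EEG
modalities recorded in one session: eyes-closed resting-state EEG and
EEG evoked by single-pulse transcranial magnetic stimulation (TMS) of the
left dorsolateral prefrontal cortex (DLPFC). Because no patient data ship
with the package, a first-class synthetic cohort generator produces
two-group cohorts with known, controllable group differences, so that every
stage of the chain — preprocessing, feature extraction, feature screening,
nested cross-validated classification, and permutation importance — can be
tested against ground truth. This vignette describes the models, the
estimators, the generator, and the design decisions taken where the
procedure admitted more than one reasonable reading.

## The analysis chain

The pipeline mirrors a fixed preprocessing order:

1. **Epoching.** Resting EEG is cut into non-overlapping 6 s epochs
   (`epochResting()`); TMS-EEG into one 4 s epoch per pulse, from 2 s
   before to 2 s after the stimulus, mean-baseline-corrected per channel
   over −1550…−50 ms (`epochTMS()`).
2. **Amplitude-based rejection** (`rejectBad()`): channels that are flat or
   exceed ±150 µV in more than 25 % of epochs are dropped, then epochs with
   any remaining excursion beyond ±150 µV are dropped.
3. **ICA #1 (TMS only)**: components whose trial-averaged 10–500 ms
   post-stimulus time course correlates with an exponential decay template
   (time constants 50/100/200 ms) are removed (`icaClean()`).
4. **Filtering** (`filterEpochs()`): zero-phase Butterworth band-pass
   0.5–100 Hz (order 4) and band-stop 48–52 Hz (order 2).
5. **Downsampling** to 1 kHz (`downsampleEpochs()`), anti-aliased.
6. **ICA #2 / resting ICA**: blink-like components (frontal-dominant
   topography with dominant < 4 Hz power) and line-noise components
   (spectral peak inside the notch band) are removed.

Removals are capped at `floor(0.20 × n_components)` combined across the two
TMS stages (12 components for a 64-channel montage) and
`floor(0.08 × n_components)` for resting data. Every operation returns a
new `EpochSet` carrying an append-only provenance trail; inputs are never
mutated.

The analysis windows are half-open intervals `[start, end)` converted to
samples by rounding: pre-stimulus −1550…−50 ms (1500 ms) and post-stimulus
50…550 ms (500 ms). The ±50 ms around the pulse is excluded everywhere to
avoid residual stimulation artifacts. The 500 ms window is the shortest
that still contains two cycles of the 4 Hz theta edge, which is also why
the Welch segment length is 500 ms.

### Zero-phase filtering

All band filtering applies the squared magnitude response of a Butterworth
design in the frequency domain, which is exactly the transfer function of a
forward–backward (zero-phase) pass of that filter. Inputs are extended by
odd reflection (250 ms for band extraction, 1 s for the wide preprocessing
band-pass) so edge transients land on padding that is discarded. The
frequency responses are cached per design and FFT length.

## Features

Per modality the package computes 614 features over a 17-channel frontal
montage (`frontalMontage()`): 68 band powers (17 channels × θ 4–7, α 8–13,
β 14–30, γ 30–45 Hz), 544 weighted phase lag index values (136 channel
pairs × 4 bands), and 2 phase–amplitude coupling indices (θ–γ and α–γ,
averaged over the left-DLPFC electrodes F3, F5, AF3). Names follow
`<SET>_<KIND>_<LOC>_<BAND>`, with channel pairs ordered by montage position.

- **Band power** is the integrated one-sided Welch PSD over the band
  (500 ms Hann segments, 50 % overlap), in µV². Integration rather than a
  band mean was chosen so that a flat spectrum yields power proportional to
  bandwidth; the two differ only by a per-band constant and are equivalent
  for every rank- or z-score-based step downstream.
- **wPLI** weights the sign of the imaginary part of the analytic
  cross-spectrum by its magnitude:
  \( \mathrm{wPLI} = |\sum_t |\Im X_t|\,\mathrm{sgn}\,\Im X_t| / \sum_t |\Im X_t| \),
  with \(X_t = \tilde x_t \overline{\tilde y_t}\) from band-filtered Hilbert
  analytic signals. Zero-lag (volume-conducted) coupling contributes
  nothing; a zero denominator returns 0 by convention. Because the analytic
  signal is band-limited below 45 Hz, the sample distribution is evaluated
  on a ~100 Hz-decimated grid, which changes nothing in expectation and
  little in variance while cutting cost fourfold.
- **PAC–MI** bins the γ amplitude envelope by the θ (or α) instantaneous
  phase into 18 bins and reports the Kullback–Leibler divergence of the
  mean-amplitude distribution from uniform, normalized by \( \log 18 \) to
  lie in [0, 1]. Empty bins are merged into their neighbours.

The four feature sets are: **RST**, features computed on each resting epoch
and averaged across epochs; **PRE** and **PST**, features of the
stimulus-locked data within the pre- and post-stimulus windows; and
**DIF = PST − PRE**, an arithmetic difference for every feature.

### Window wPLI: pooled over trials, not on the averaged trace

Power and PAC for PRE/PST are computed on the trial-averaged (evoked)
trace. For wPLI the averaged trace was rejected after measurement: a 500 ms
narrow-band window carries only two or three independent phase samples, so
the single-trace estimator's null sits near 0.7 with a standard deviation
around 0.3 — it is degenerate and cannot express any real coupling
difference. The window wPLI is therefore estimated over the analytic
cross-term samples *pooled across trials*: phase relations that are
consistent over trials accumulate in the numerator, incoherent ones cancel.
This is also how trial-resolved connectivity toolboxes estimate wPLI. The
choice matters for anyone comparing numbers across implementations and is
the package's resolution of a genuine ambiguity in how "features of the
additively averaged signal" should be read for a phase-lag statistic.

## Screening and classification

Features are screened with a two-sided Mann–Whitney U test at p < 0.01,
deliberately without multiple-testing correction: the screen is
dimensionality reduction, not inference, and its null behaviour is itself
under test (see below). Tie-free columns use the exact U null distribution
(cached CDF); ties fall back to the tie- and continuity-corrected normal
approximation. The default *placement* is `per_fold`: the screen runs
inside each outer training fold and never sees held-out subjects. A
`global` placement (whole-sample screening) is provided for comparison; it
is optimistic by construction and the leakage canary in the acceptance
battery demonstrates the difference.

Nine classifiers are registered (`modelRegistry()`): ridge-penalized
logistic regression (LR), linear discriminant analysis with a tunable
shrinkage of the pooled covariance toward a scaled identity (LDA —
classical LDA is singular on combined feature sets because every DIF
column is an exact PST − PRE combination), RBF-kernel SVM, k-nearest
neighbours (KNN), Gaussian naive Bayes (NB), a decision tree (DT), random
forest (RF), extremely randomized trees (ET), and gradient-boosted trees
(LG, backed by xgboost). Evaluation uses nested
double cross-validation: a stratified 5-fold outer loop estimates
generalization; inside each outer training fold, screening, z-scoring
(means/SDs fit on training subjects only) and a random grid search over the
model's hyperparameter grid — scored by stratified 10-fold inner CV — are
performed, the tuned model is refit on the whole training fold and scored
on the held-out fold with continuous decision scores (positive class MDD).
Fold ROC curves are averaged *vertically*: each fold's curve is linearly
interpolated onto a common 101-point FPR grid (upper envelope at duplicated
FPR, TPR(0) = 0 by convention) and averaged; the reported mean AUC is the
arithmetic mean of fold AUCs, with the sample SD across folds as its
spread. Threshold averaging was rejected because fold-specific thresholds
are not comparable across models. All 15 non-empty subsets of
{RST, PRE, PST, DIF} can be crossed with all nine models
(`rankModels()` assembles the 15 × 9 grid).

Permutation importance is computed on the outer **test** folds — the drop
in test AUC when one feature column is permuted, averaged over 10 repeats
and the 5 folds — so it measures generalizable reliance rather than
training-set fit. The per-model top-20 lists for LDA, LR and SVM are
intersected to find features that every strong model relies on. Post hoc,
each such feature gets an age-adjusted ANCOVA (`value ~ age + group`, F on
1 and n−3 df) and per-group Spearman correlations against MADRS, STAI and
MMSE, at an exploratory α = 0.05 without correction.

## The synthetic cohort generator

`generateCohort()` draws `2 × nPerGroup` subjects (default 60/60), each
with clinical covariates, a resting recording and a TMS-EEG recording. The
defaults reproduce the study protocol: 3 kHz sampling over the 17-channel
frontal montage, 5 min of resting EEG, 80 single pulses at a mean 5 s
inter-pulse interval jittered ±10 % (the protocol does not fix the
interval; 4 s epochs require at least 4 s spacing).

Signals are 1/f-shaped Gaussian background (spectral exponent 1, 10 µV)
plus 2 µV white sensor noise. Oscillatory sources are band-filtered
Gaussian noise rather than pure tones, because pure tones make phase-lag
statistics degenerate. Clinical scores are drawn from per-group Gaussians
matched to the cohort description (e.g. MADRS 31.8 ± 7.8 in MDD vs
1.1 ± 2.0 in HC; age 45.8 ± 12.2 vs 40.5 ± 12.2) and clipped to instrument
ranges.

Five group effects are planted by default, at standardized effect size
d = 1.2 each, mirroring the reported group differences: resting AFz β
power and F4–F6 γ wPLI are higher in MDD; the pre-to-post change of
F5–AF3 α, AFz–F5 α and AF3–F8 θ wPLI is lower in MDD.

- **Band power** (`power_scale`): a β-band source at AFz whose amplitude is
  log-normal across subjects with a group shift.
- **Resting wPLI** (`shared_source_lag`): a shared band-limited source
  added to both channels at fixed SNR, whose copy on the second channel is
  delayed by a subject-specific lag angle \( \theta = 90^\circ
  \mathrm{plogis}(\eta) \). Zero lag is invisible to wPLI and larger lags
  raise it monotonically, while the added band power is identical in both
  groups — so the coupling effect cannot leak into power features. This
  power-neutrality is asserted by a test.
- **TMS wPLI change** (`dif_coupling`): each trial draws a *fresh* shared
  source for the pre- and post-stimulus windows (induced, not evoked
  activity), added to the pair at fixed SNR with a consistent within-pair
  lag — common in the pre window, subject-specific in the post window, with
  MDD showing the smaller pre-to-post lag change. Redrawing per trial makes
  the source cancel from the evoked average (power-neutral) and prevents
  deterministic interference with the evoked response or with other
  effects sharing a channel; pooled-trial wPLI still accumulates the
  consistent lag.
- **PAC** (`pac_depth`, available though not in the default table):
  multiplies the γ component by \( 1 + d\cos\phi_\theta \).

Within the MDD group the AFz-β amplitude shares a latent severity variable
with the MADRS and STAI draws, tuned so the recovered within-group Spearman
correlation with MADRS is near 0.28 (and near 0.36 for STAI). The mixing
coefficients include a fixed attenuation factor (0.9) calibrated once by
simulation for the noise the feature estimate adds.

The mapping from a requested effect size `d` to signal-domain parameters
(source SNRs, lag-angle shifts, log-amplitude shifts) uses constants
calibrated once by simulation at the package's reduced evaluation profile
and then frozen (`.effectCalib`). At larger recording sizes the estimator
noise shrinks, so realized effects are at or slightly above the requested
`d`; recovery is validated across seeds in the acceptance battery.

Artifact injection is off by default — effect-recovery studies use clean
signals — and can be enabled per recording type: blink-like 120 µV
raised-cosine transients with a frontal topography (resting), and
exponential TMS decay artifacts (τ ≈ 100 ms, ~120 µV peak,
frontal-weighted, fixed per channel across pulses so they form a single
spatial component for ICA). The decay amplitude is deliberately below the
±150 µV rejection preset so the artifact reaches the ICA stage built to
remove it.

What the generator does **not** emulate: biophysical forward modelling,
realistic head geometry or volume conduction (channels are independent
except for planted couplings), the full artifact taxonomy of real EEG
(muscle, electrode drift, sweat), non-stationarity across a session, and
between-subject spectral diversity beyond the planted parameters. Tests
passing on these cohorts therefore validate the *pipeline* — estimator
correctness, leakage safety, calibration, recovery of effects of known
size — not clinical performance on real recordings.

## Problem sizes used by the test and acceptance battery

The package's own test battery runs the full chain at a reduced evaluation
profile chosen once: 320 Hz sampling (the γ band at 45 Hz is still
resolved with a wide margin and all filters keep their shape), 12 s of
resting EEG (two 6 s epochs) and 20 pulses, with 60 subjects per group for
effect-recovery checks and 30 per group for null calibration. The effect
calibration is referenced to this profile; at the full protocol scale
estimates only get tighter. ICA stages are exercised on dedicated
artifact-injection cohorts and skipped in cohorts where no artifacts are
injected (the heuristic scores have nothing to find there; a test asserts
exactly that on clean data).

## Numerical choices and degenerate inputs

- Half-open windows with round-to-nearest-sample conversion give exact
  sample counts (1500/500 at 1 kHz) and put the boundary samples where the
  definitions say.
- wPLI returns 0 on a zero denominator; MI returns 0 for a uniform or
  empty amplitude distribution; values are clamped to [0, 1] against
  floating-point epsilon only.
- The Welch estimator falls back to a single-segment periodogram (with a
  warning) when the segment exceeds the signal.
- FastICA (logcosh contrast, symmetric orthogonalization, eigenvalue
  whitening) is seeded and deterministic; stages are skipped with a warning
  when fewer than `20 × channels²` samples are available.
- Stratified folds require at least `k` members per class; a fold with one
  class is an error, not a silent NA.
- If fewer than two features survive a fold's screen, the two smallest-p
  features are used and the fold is flagged in the result.

## Known limitations

- The evoked-average wPLI ambiguity discussed above means numbers for PRE/
  PST/DIF wPLI are not directly comparable to a single-trace
  implementation.
- The LG registry slot is gradient-boosted trees via xgboost; results for
  tree-boosting hyperparameters map closely but not identically to other
  boosting libraries.
- EDF support is read-only and assumes a uniform sampling rate across
  signal channels; BrainVision support covers multiplexed float32/int16.
- Real-data headline numbers (e.g. a specific mean AUC) depend on the real
  cohort and cannot be reproduced from synthetic data; the battery instead
  checks structure: counts, calibration, monotone gains from combining
  feature sets, and recovery of the planted effect pattern.
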