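# tmseegdx

EEG and TMS-EEG biomarkers for discriminating major depressive disorder
(MDD) from healthy controls (HC), as a fully tested R pipeline with a
synthetic-cohort generator for ground-truth validation.

## The problem

Depression has no established objective diagnostic marker. One candidate
readout combines two EEG modalities from a single session: eyes-closed
resting-state EEG, and EEG responses to single-pulse transcranial magnetic
stimulation (TMS) of the left dorsolateral prefrontal cortex. From a
17-channel frontal montage, three families of neurophysiological features
are extracted per modality:

- **band power** per channel and band (θ 4–7, α 8–13, β 14–30, γ 30–45 Hz):
  integrated Welch PSD, µV²;
- **weighted phase lag index** (wPLI) per channel pair and band,

  wPLI = |Σₜ |Im Xₜ| sgn(Im Xₜ)| / Σₜ |Im Xₜ|,  Xₜ = x̃ₜ · conj(ỹₜ),

  where x̃, ỹ are band-filtered Hilbert analytic signals — a
  phase-synchronization measure blind to zero-lag (volume-conducted)
  coupling;
- **phase–amplitude coupling** via the modulation index
  MI = (log N + Σ pⱼ log pⱼ) / log N, the normalized KL divergence of the
  θ- (or α-) phase-binned γ-amplitude distribution from uniform (N = 18
  bins), averaged over the left-DLPFC electrodes.

Each subject yields four feature sets of 614 features each: resting (RST),
pre-stimulus (−1550…−50 ms, PRE), post-stimulus (50…550 ms, PST), and
their difference (DIF = PST − PRE); 2456 features in total. Features are
screened by a two-sided Mann–Whitney U test at p < 0.01 and fed to nine
classifiers (LR, LDA, SVM, KNN, NB, DT, RF, ET, LG) evaluated by nested
double cross-validation — a stratified 5-fold outer loop with 10-fold
inner tuning via random grid search — with vertically averaged ROC curves
and mean AUC ± SD per (feature-set combination × model) cell, and mean
permutation importance on the held-out folds, intersected across the top
models. Post hoc, candidate markers get age-adjusted ANCOVA and per-group
Spearman correlations against MADRS / STAI / MMSE scores.

Because no patient recordings can ship with the package, a first-class
generator (`generateCohort()`) simulates two-group cohorts — 1/f
background plus band-limited oscillatory sources, TMS pulse trains with
evoked responses, optional blink and TMS-decay artifacts, and clinical
covariates — with five planted group effects of controllable standardized
size mirroring the reported pattern (resting AFz β power and F4–F6 γ wPLI
higher in MDD; pre-to-post changes of F5–AF3 α, AFz–F5 α and AF3–F8 θ
wPLI lower in MDD). The planting mechanisms are power-neutral (the
coupling effects live in a phase-lag angle, invisible to band power), so
recovered effects are attributable to the intended features. See
`vignettes/methods.Rmd` for the model, the estimator choices and their
rationale.

## Worked example

A reduced-scale cohort (60 subjects, 320 Hz, 12 s resting, 20 pulses) takes
a couple of minutes end to end:

```r
library(tmseegdx)

spec   <- fastCohortSpec(nPerGroup = 30, seed = 42, fs = 320,
                         restDuration = 12, nPulses = 20)
cohort <- generateCohort(spec)
cohort[[1]]
#> SubjectRecord 'S001' (MDD): MADRS 28.0, age 65.0

ft <- buildFeatureTable(cohort, preprocConfig(run_ica = FALSE,
                                              target_fs = 320))
dim(featureValues(ft))
#> [1]   60 2456

sel <- selectFeatures(ft, alpha = 0.01)
head(sel[order(sel$p), ], 5)
#>                    feature   U            p selected
#> 2187 DIF_wPLI_AF3-F8_theta 147 2.445710e-06     TRUE
#> 2160 DIF_wPLI_AF3-F5_alpha 163 9.415847e-06     TRUE
#> 1546 PST_wPLI_AF3-F5_alpha 164 1.020585e-05     TRUE
#> 23      RST_power_AFz_beta 735 1.105753e-05     TRUE
#> 1573 PST_wPLI_AF3-F8_theta 199 1.339670e-04     TRUE
```

The screen puts the planted markers on top: the reduced pre-to-post wPLI
changes (θ at AF3–F8, α at AF3–F5, with their post-stimulus shadows) and
the elevated resting AFz β power. `U` is the Mann–Whitney statistic (MDD
vs HC; large U = higher in MDD, small U = lower in MDD) and rows with
`p < 0.01` enter the classifiers. Model evaluation on one cell of the
grid:

```r
res <- nestedCvEvaluate(ft, featureSets(), "LDA",
                        cvConfig(outer_k = 5, inner_k = 5, budget = 5,
                                 seed = 1))
res
#> EvaluationResult DIF+PRE+PST+RST | LDA: mean AUC 0.767 +- 0.137
#>   (folds: 0.722, 0.750, 0.639, 1.000, 0.722)
```

returns an `EvaluationResult` whose show method prints the fold AUCs and
their mean ± SD; `rankModels()` assembles the full 15-combination × 9-model
grid and `importanceReport()` computes the held-out permutation importance
and the cross-model top-20 intersection. `runExperiment()` chains the whole
study, and `runFromConfig("run.yaml")` drives it from a plain-text
configuration file (validated fail-fast before any compute). At this reduced scale the
discrimination signal is intentionally modest; `cohortSpec()` defaults
reproduce the full protocol (60/60 subjects, 3 kHz, 5 min rest, 80
pulses).

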