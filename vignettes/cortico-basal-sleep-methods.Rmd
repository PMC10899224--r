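---
title: "Methods: cortico-basal sleep analysis on synthetic nights"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cortico-basal sleep analysis on synthetic nights}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(sleepdbs)
```

## The problem this package addresses

Sensing-enabled deep-brain-stimulation (DBS) implants can stream cortical
electrocorticography (ECoG) and subcortical (STN/GPi) field potentials
overnight while a portable polysomnography (PSG) headband scores sleep
stages. Three scientific questions drive the pipeline:

1. How do cortico-basal spectral power and cortico-subcortical coherence
   differ between consolidated N2/N3 NREM sleep and wakefulness, and how
   does stimulation modulate them?
2. Within N2/N3 NREM, is subcortical beta (13--31 Hz) inversely coupled to
   cortical slow-wave delta (1--4 Hz) activity at a 5 s timescale, and which
   rhythm leads?
3. Does subcortical beta rise in the seconds before spontaneous awakenings,
   and can NREM vs. wake be classified from band powers rapidly enough
   (5 s epochs) to drive sleep-aware adaptive stimulation?

Real overnight intracranial recordings of this kind are privacy-protected,
so the package ships a synthetic-night generator with queryable ground
truth: every stage of the pipeline is validated by parameter recovery on
simulated nights rather than by reproducing clinical values.

## Pipeline overview

A night enters as a four-channel recording (cortex/subcortex x left/right),
a 30 s hypnogram, optionally a 5 s re-scored fine track near awakenings,
and two tri-axial accelerometer streams (implant and headband).

1. **Synchronization** (`estimate_lag`): both accelerometer streams are
   resampled to a common rate (50 Hz), collapsed to their Euclidean norm
   across axes, and the clock lag is the argmax of the normalized
   cross-correlation within a search window. A peak below 0.5 flags the
   estimate as low-confidence; real deployments validated alignment with
   five deliberate taps on both sensors, which the generator reproduces.
2. **Conditioning** (`condition_signal`): anti-aliased resampling to
   250 Hz, then a zero-phase elliptic bandpass 0.8--100 Hz with 1 dB
   passband ripple and 100 dB stopband attenuation, implemented as a
   high-pass/low-pass cascade. Orders are chosen by probing the designed
   response (3--7): the smallest order meeting the attenuation at the
   stopband edge with poles strictly inside the unit circle. Transfer-
   function IIR filters above order 7 at a 0.8 Hz corner on a 125 Hz
   Nyquist are numerically unreliable, which the probe excludes by
   construction.
3. **Spike excision** (`detect_and_excise_spikes`): the squared subcortical
   signal is smoothed with a Gaussian kernel of 1 s total support
   (sigma = 1/6 s, the standard window-to-sigma convention); periods above
   5x the whole-night median are masked with +/-0.5 s guard padding and
   zeroed in both the subcortical channel and its same-hemisphere cortical
   partner. Downstream epoching skips epochs with more than 20% masked
   samples.
4. **ECG removal** (`build_seed_template`, `remove_ecg`): a per-night seed
   template is built from sharp QRS-like deflections detected per 10 min
   window (peaks above 3.5 robust SDs of a 5--45 Hz detection signal, with
   a plausibility check that the peak train looks cardiac: at least
   ~24 bpm and inter-beat intervals concentrated near their median). Each
   10 min window then runs a Woody adaptive loop seeded with the same
   per-night template: correlate, pick events (NCC >= 0.6, 0.4 s
   refractory), re-average, iterate (max 10 iterations or RMS change
   < 1e-3). The refined template is accepted only if its maximum NCC
   against the seed reaches 0.9 -- the guard against the template drifting
   onto rhythmic neural activity; otherwise detection is redone with the
   fixed seed at the forced-search threshold (0.4). Accepted windows also
   get a forced search inside gaps of the beat train. Events are removed by
   subtracting the least-squares-scaled template, so samples away from
   events are bit-identical to the input, and a window without a credible
   beat train is left untouched.

## Spectral features

Per 5 s (or 30 s) epoch on a midpoint-labelled grid (the 0--5 s epoch is
labelled 2.5 s), Welch spectra use 1 s Hamming segments, 50% overlap and a
512-point zero-padded transform -- nine averaged segments per 5 s epoch at
250 Hz. Normalization operates on linear power: either by the total over
0--50 Hz (the default; the normalized spectrum then bin-sums to one), or by
the total excluding 13--31 Hz (used for cortical delta in the coupling
analysis, so beta cannot leak into its own normalizer), or not at all (the
cortical-cortical control). Band powers are half-open bin sums in dB; the
analysis scheme keeps the printed overlap of sigma (13--15 Hz) inside beta
(13--31 Hz). Coherence uses the same segmentation: Welch-averaged
magnitude-squared coherence. The description of the coherence estimator we
follow pairs a stated 1 s Hamming window and 512-point transform with a
multitaper reference; we implement the Welch/Hamming reading, which the
stated parameters pin down, and reuse the 50% overlap stated for power
spectra.

Stage contrasts average log-transformed spectra within each stage group per
night (hemispheres pooled by concatenating epochs) and subtract wake from
N2/N3 NREM.

## Beta--delta coupling and lag

For each night, subcortical beta and cortical delta dB series over all
N2/N3 5 s epochs (hemispheres concatenated) give a Spearman rank
correlation -- invariant to monotone transforms, so the dB scale choice is
immaterial. For the lead--lag estimate both series are smoothed with a
20-point Gaussian kernel (support 20 epochs = 100 s, sigma = 20/6 epochs),
mean-subtracted, and the normalized cross-correlation is searched over
+/-24 epochs (+/-120 s); the lag at the trough (minimum, reflecting the
negative relationship) is reported. Sign convention, fixed and tested
against a constructed oracle: with cortical delta as the reference,
negative lag means subcortical beta leads. Single-night troughs are noisy
at a 5 s quantization, so multi-night summaries pool the cross-correlation
curves across nights (`pool_lag_curves`) before taking the trough.

## Transition-locked dynamics

Maximal N2/N3 runs immediately followed by wake are events; events need at
least 85 s of NREM and 25 s of wake to count. Band power around events is
the squared magnitude of the analytic signal (zero-phase elliptic bandpass,
then Hilbert transform via the frequency-domain construction) in dB,
averaged into 5 s bins anchored at wake onset (bins [-5,0) -> -2.5 s,
[0,5) -> +2.5 s). Two windows summarize each event: deep NREM (whole
epochs from 40 s after NREM onset to 40 s before awakening -- at the 85 s
validity boundary exactly one epoch survives) and awake (from 25 s after
wake onset to wake end). The named contrasts are the -7.5 s bin minus deep
NREM (pre-awakening rise) and the +12.5 s bin minus deep NREM
(post-awakening change). All relative-time bins are retained for
event-level modelling; bins between -40 s and -7.5 s are not folded into
the deep-NREM summary.

## Mixed-effects inference

`fit_lme` wraps maximum-likelihood `lmer` fits (ML, not REML, so
log-likelihoods are comparable across fixed-effect structures) with
unstructured random-effect covariance and Wald 95% intervals; p-values use
a residual degrees-of-freedom t approximation (a `normal` option exists).
`compare_lme_bootstrap` implements the parametric-bootstrap likelihood-
ratio test: simulate from the null fit, refit both models, and report
`p = (1 + #[LR* >= LR]) / (n_reps + 1)`. Nesting of the fixed effects is
checked syntactically. `lme_preset` ships the formulas for the standard
analyses (stage contrast, disease-group contrast, ON/OFF stimulation,
epoch-level beta-to-delta with hemisphere and night random intercepts, and
the night-quadrant interaction probing medication wear-off); where the
random structure wording was ambiguous we encode participant, night-within-
participant and hemisphere-within-participant intercepts for the pooled
beta--delta model, and hemisphere-only for the within-participant variant.

## Classification

Six band powers (delta 0--4, theta 4--8, alpha 8--13, sigma 13--15, high
beta 15--31, low gamma 31--50 Hz) per epoch feed a Gaussian-kernel SVM with
kernel width 2.6 (`gamma = 1/2.6^2`), features standardized on training
folds only, uniform prior, and a fixed 0.5 threshold on the Platt
probability score -- a raw margin has no natural 0.5, so a calibrated score
is the default. Class balance randomly downsamples NREM epochs (without
replacement) to the wake count; the printed rule only ever reduces NREM.
For 5 s models an asymmetric class weight (2:1 on wake) makes missed
awakenings costlier; the exact cost scheme in the source analysis is
unspecified, so the ratio is a config-exposed default. Cross-validation is
stratified by label (5-fold default, 2-fold option); fold metrics
(accuracy, AUC, sensitivity, specificity, PPV, NPV, as percent) are
reported mean +/- SEM. Feature ranking uses plug-in mutual information on
16 equal-frequency bins with the Miller--Madow correction. Grouping folds
by night is available to probe temporal leakage, but the default matches
label-stratification only. For time-resolved wake detection around
awakenings, peri-event epochs (60 s before to 30 s after each awakening)
are excluded from the training pool, and the fraction of fold models voting
wake is binned on the wake-anchored grid.

## The synthetic-night generator

`synth_config` fixes the study conditions; `generate_night` is bit-level
deterministic given the seed.

- **Stage dynamics**: a continuous semi-Markov trajectory (pre-sleep wake
  -> N1 -> N2 cycling with N3, REM and spontaneous awakenings; exponential
  dwells, N1 truncated below three 30 s epochs to match the scoring
  convention) scored twice -- 30 s epochs by midpoint (the automated-scorer
  view) and a 5 s fine track (the re-scored ground truth, which places
  awakening onsets on the 5 s grid). Default dwell means (pre-sleep wake
  420 s; N1 90 s; N2 210 s; N3 270 s; REM 540 s; awakening 120 s) yield
  roughly 165/100/120 min of N2/N3/REM, ~45 min of wake after sleep onset
  and on the order of ten valid N2/N3-to-wake transitions per 8 h night,
  the regime reported for multi-night at-home recordings. This is a
  statistical emulation, not a model of sleep architecture.
- **Oscillations**: each channel is 1/f background (5 uV) plus band-limited
  Gaussian-noise carriers (delta/theta/alpha/beta) gated by stage-dependent
  amplitudes, so Welch and Hilbert estimators face realistic estimator
  variance rather than sinusoidal idealizations. Deep NREM is delta-
  dominant, wake is beta/alpha-dominant in both regions. Two deliberate
  flatnesses keep recovery tests interpretable: subcortical amplitudes do
  not differ between N2 and N3 (any asymmetry there would leak through the
  0--50 Hz normalizer into the beta series and fake a coupling at zero
  gain), and cortical delta is moderate relative to the other cortical
  bands (a delta-dominated exclude-beta normalizer would compress the very
  delta dynamics being measured). All other band envelopes carry slow
  log-normal amplitude fluctuations (sd 0.35 in log, ~1 min timescale;
  0.15 for subcortical delta, which dominates the beta normalizer), the
  within-stage variability that keeps classifier margins realistic.
- **Coupling**: a smoothed Gaussian driver `z` (sd 0.5, ~60 s timescale)
  modulates the subcortical beta envelope as `(1 + z)`; the cortical delta
  envelope is modulated as `(1 + gain * z(t - lag))`. Defaults
  `gain = -0.5`, `lag = 5 s` (beta leads). The driver depth makes the
  injected coupling the dominant within-NREM delta modulator, matching the
  overnight rank correlations of roughly -0.3 to -0.6 the method is meant
  to detect.
- **Pre-awakening ramp**: subcortical beta amplitude ramps linearly to
  `(1 + gain)`x baseline over the 10 s before each fine-track awakening
  (default gain 1), so the -7.5 s and -2.5 s bins are affected but
  -12.5 s is not.
- **Artifacts**: QRS-shaped transients (three triangular lobes, 0.08 s,
  60 uV, 70 bpm with 10% jitter) and sparse raised-cosine spikes
  (20/h, ~200 uV, 0.15--0.4 s) on subcortical channels only, with exact
  injected times returned as truth. The 60 uV default makes the artifact
  prominent relative to the ~10 uV background -- the regime in which
  dedicated removal is warranted at all.
- **Accelerometers**: implant (64 Hz) and headband (50 Hz) observe the
  same movement process (wake-gated noise bursts plus five synchronization
  taps); the headband copy is delayed by the configured clock lag and
  carries independent sensor noise.

What the generator does **not** emulate: spindle/K-complex morphology, REM
phenomenology, 1/f slope changes across states, stimulation artifacts,
inter-participant heterogeneity, or non-stationary heart rate. Passing
recovery tests therefore demonstrates correctness of the estimators under
the stated signal model, not clinical performance on real recordings.

## Numerical choices and degenerate inputs

- Welch PSD is one-sided density (power/Hz); normalized modes are
  scale-free so the density convention never reaches downstream values.
- Zero in-band power floors at -300 dB instead of -Inf.
- An all-zero signal yields an empty spike mask (the 5x-median rule with a
  zero median detects nothing).
- Flat band-power series make the lag undefined and raise an error rather
  than returning a spurious trough.
- Tie-breaks in event picking keep the higher-NCC peak inside a 0.4 s
  refractory window.
- `coupling_correlation` flags results from fewer than 10 epochs invalid.
- Grouping factors with a single level are dropped from random-effect
  structures with a warning rather than producing a singular fit.

## Problem sizes used in the shipped checks

The acceptance-style checks run on reduced desk-scale simulations chosen to
keep the full suite in the tens of minutes: half-hour to 45-minute nights
with a compressed pre-sleep wake, 10--20 nights for artifact and
synchronization recovery, 21 nights across the coupling-gain grid, 500
null fits for mixed-model calibration, and 15--20 label permutations for
classifier nulls.

The pre-awakening ramp study deserves a note on design. Per-event
(-7.5 s bin minus deep NREM) contrasts carry ~4--5 dB of noise, dominated
by the coupling driver's beta fluctuations, against a ~1--2 dB ramp
effect; a one-arm sign test at that effect size would need several hundred
events (the full multi-night regime). At desk scale the study instead
pairs nights: the same seed is generated with and without the ramp, which
makes the hypnogram, carriers, coupling driver and background bit-
identical, so each event's paired contrast difference reflects the ramp
alone and is positive for essentially every event. The paired sign test
(25 seed pairs, ~30--40 events) detects the ramp; the ramp-free arm's own
contrast additionally verifies the null, and the post-awakening cortical
delta drop is tested one-armed (its effect, several dB, dwarfs the noise).
The acceptance script reports the same quantities at slightly smaller
sizes.

## Known limitations

- The ECG seed detector assumes the artifact is sharp and large relative
  to the robust background SD in the 5--45 Hz detection band; faint
  contamination (well under the background SD) is left in place by design,
  since template subtraction at that SNR removes more neural signal than
  artifact.
- The lag estimator quantizes to the 5 s epoch grid; leads shorter than
  one epoch are only resolvable through the pooled-curve trough.
- Wald intervals with a residual-df approximation are anti-conservative
  for very small group counts; the calibration checks run at group sizes
  where they are nominal.
- The EDF writer targets continuous 16-bit EDF with 1 s records and equal
  per-channel rates -- the subset the pipeline needs, not a general EDF
  implementation.
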