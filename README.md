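# sleepdbs

Analysis pipeline for multi-night intracranial field-potential recordings
from sensing-enabled deep-brain-stimulation (DBS) implants — cortical ECoG
plus subcortical (STN/GPi) leads — paired with portable polysomnography.
It is aimed at neural-engineering and movement-disorders groups studying
sleep physiology in Parkinson's disease and building sleep-aware adaptive
DBS.

Because raw overnight recordings of this kind are privacy-protected, the
package includes a synthetic-night generator with fully queryable ground
truth; every stage of the pipeline is validated by recovering what was
injected.

## What it computes

- **Stream synchronization** — the implant/headband clock lag from
  accelerometry, as the argmax of the normalized cross-correlation of the
  axis-norm traces, with a confidence flag.
- **Preprocessing** — anti-aliased resampling to 250 Hz; zero-phase
  elliptic bandpass 0.8–100 Hz (1 dB ripple, 100 dB attenuation);
  artifactual-spike excision (Gaussian-smoothed squared signal over 5× the
  night median, removed from subcortical and paired cortical channels);
  and hybrid ECG template subtraction: a per-night seed template from
  QRS-like deflections, refined per 10-min window by a Woody adaptive
  filter, gated at a 0.9 normalized cross-correlation against the seed
  (rejection falls back to forced searches with the fixed seed).
- **Spectral features** — per-epoch Welch spectra (1 s Hamming segments,
  50% overlap, 512-point FFT) normalized by total 0–50 Hz power (or
  excluding the beta range), band powers in dB, and Welch-averaged
  magnitude-squared coherence between cortex and subcortex.
- **Beta–delta coupling** — within N2/N3 NREM at 5 s resolution, the
  Spearman correlation between subcortical beta (13–31 Hz) and cortical
  delta (1–4 Hz) power, and their lead–lag from the trough of the
  normalized cross-correlation of the smoothed band-power series
  (negative lag ⇔ beta leads, cortical delta as reference).
- **Transition-locked dynamics** — N2/N3→wake events (≥ 85 s NREM, ≥ 25 s
  wake), Hilbert-envelope band power on a wake-anchored 5 s grid, and the
  pre-awakening (−7.5 s vs deep NREM) and post-awakening (+12.5 s vs deep
  NREM) contrasts.
- **Mixed-effects inference** — maximum-likelihood `lmer` fits with Wald
  intervals, named presets for the standard model structures, and a
  parametric-bootstrap likelihood-ratio comparison of nested models.
- **Rapid sleep staging** — NREM-vs-wake Gaussian-kernel SVMs (kernel
  width 2.6, training-fold standardization, 0.5 probability threshold) on
  six band powers at 30 s and 5 s epochs, with fold-wise
  accuracy/AUC/sensitivity/specificity/PPV/NPV, mutual-information feature
  ranking, and time-resolved wake detection around awakenings.

## Worked example

```r
library(sleepdbs)

cfg <- synth_config(seed = 7, night_dur_s = 3600,
                    stage_dwell_means_s = list(W_start = 120, N1 = 90,
                                               N2 = 210, N3 = 270,
                                               R = 540, W = 120))
night <- generate_night(cfg)
night$hypnogram
#> <hypnogram> 120 x 30 s epochs (1.0 h) + 5 s fine track
#>  W N1 N2 N3  R  U
#>  5 14 45 39 17  0

sync <- estimate_lag(night$accel_pair$implant, night$accel_pair$headband)
#> clock lag: 1.50 s (peak NCC 0.80, truth 1.50 s)

cp <- night_coupling(night$clean_recording, night$hypnogram)
#> N2/N3 beta-delta coupling: rho = -0.28 (p = 6.3e-20, 992 epochs)
```

The injected coupling (gain −0.5 on the shared slow driver) appears as a
significant negative overnight rank correlation. Single-night lag troughs
are noisy at the 5 s quantization; `pool_lag_curves()` over several nights
localizes the injected 5 s beta lead (see the methods vignette).

```r
bp <- epoch_band_powers(night$clean_recording, night$hypnogram,
                        epoch_len_s = 5, scheme = "ml")
ft <- build_features_balanced(bp, region = "cortex", seed = 1)
crossval_svm(ft, k = 5, cost_wake_miss = 2, seed = 2)
#> <cv_report>  5-fold  cross-validation
#>       metric   mean  sem
#>     accuracy  97.86 1.43
#>          auc 100.00 0.00
#>  sensitivity 100.00 0.00
#>  specificity  95.71 2.86
#>          ppv  96.17 2.52
#>          npv 100.00 0.00
```

Accuracy is the percent of held-out 5 s epochs correctly labelled
NREM/wake; sensitivity counts wake epochs caught (the quantity an
awakening-reactive stimulator cares about). On this one clean synthetic
hour the classes are nearly separable; across noisier nights accuracies
fall into the high-80s/low-90s.

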