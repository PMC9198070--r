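---
title: "Automated preprocessing and spectral validation of resting-state EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated preprocessing and spectral validation of resting-state EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope

`resteeg` implements an automated de-artifacting pipeline for clinical
resting-state EEG recorded on a 26-channel 10-10 cap with EOG/ECG/EMG
auxiliaries at 500 Hz, together with the two spectral analyses classically
used to check the neurophysiological quality of such data: the attenuation
of posterior alpha power from eyes-closed (EC) to eyes-open (EO), and the
lifespan maturation of the individual alpha peak frequency (iAPF). Because
clinical EEG archives are typically distributed under data-use agreements, a
synthetic lifespan-cohort generator with exact ground truth is a first-class
part of the package: every stage of the chain is validated against data
whose alpha peaks, condition effects and artifacts are known by
construction.

## The pipeline

The stage order is fixed and deliberate:

1. **Bipolar EOG.** `compute_bipolar_eog()` forms VEOG = VPVA − VNVB and
   HEOG = HOHL − HNHR from the four periocular electrodes.
2. **Ocular regression.** `gratton_correct()` estimates, per EEG channel,
   ordinary-least-squares propagation coefficients of the demeaned VEOG and
   HEOG and subtracts the fitted ocular contribution. This is the
   whole-recording variant of the classic regression correction: the
   original method estimates separate coefficients for blink and saccade
   segments, which requires an event segmentation this package does not
   perform. The simplification is recorded in every repair log header. With
   frequent blinks the blink response dominates the EOG covariance, so the
   whole-recording coefficients are close to the blink coefficients; the
   residual-blink detector (below) catches windows where correction was
   insufficient.
3. **Filtering.** `filter_recording()` demeans, band-passes 0.5–100 Hz and
   notches 50 Hz, all zero-phase (forward–backward Butterworth; order 4
   band-pass, order 2 stop-band of ±1 Hz). Zero-phase filtering avoids
   latency distortion of the waveforms at the cost of spreading sharp
   transients symmetrically. At a 500 Hz sampling rate the upper band edge
   is realized at 99 Hz: a Butterworth design with an edge at 0.4 of the
   sampling rate is comfortably stable, whereas 100 Hz offers no benefit
   because the recording hardware already low-passes at 100 Hz before
   digitization.
4. **Detection.** `detect_artifacts()` runs seven detectors on 1-second
   windows of the EEG channels (auxiliaries are never flagged):
   EMG, jumps, kurtosis, voltage swing, residual blinks, electrode bridging
   and extreme correlations. Each flags whole windows and records its
   provenance per region.
5. **Repair.** `repair_channels()` replaces any EEG channel flagged for
   strictly more than 66% of the samples by the inverse-distance weighted
   average of its 3–4 nearest EEG neighbours whose own flagged fraction is
   at most 0.66, using the built-in cap coordinates. The whole channel is
   replaced, mirroring the per-measurement reading of the repair rule; a
   channel with fewer than 3 eligible donors is unrepairable and excluded
   from epoch vetoing, and a recording whose Pz is unrepairable is failed
   outright, Pz being the validation channel.
6. **Segmentation.** `segment_epochs()` cuts consecutive non-overlapping
   5-second epochs (2500 samples) and retains only epochs without a single
   flagged EEG sample.

### Detector thresholds

The detector families are standard, but published descriptions of such
pipelines rarely print thresholds. All thresholds therefore live in
`detector_config()` with these defaults, chosen from the physics of each
artifact class and fixed before any validation was run:

| detector | default | rationale |
|---|---|---|
| EMG | 45–100 Hz window power > 4 × channel median | muscle bursts raise high-band power by an order of magnitude; the median is robust to the bursts themselves |
| JUMP | any adjacent-sample step > 100 µV | EEG slew between samples at 500 Hz is a few µV; electrode pops are hundreds |
| KURTOSIS | window kurtosis > 8 | Gaussian background has kurtosis 3; impulsive artifacts far exceed 8 |
| SWING | window peak-to-peak > 300 µV | clean scalp EEG rarely exceeds ~100 µV peak-to-peak |
| BLINK | |corr| with VEOG > 0.8 after correction | residual ocular windows remain strongly EOG-correlated |
| BRIDGE | pair difference variance < 0.5 µV² in ≥ 50% of windows | gel bridges short electrodes to within amplifier noise |
| CORR | |corr| > 0.975 with one single channel in ≥ 50% of windows | duplicates that are not electrical bridges (e.g. gain-scaled copies) |

A detail worth knowing: the jump detector operates on *filtered* data, and
zero-phase filtering attenuates the first difference of an instantaneous
step to roughly 0.4 of its raw size. A raw pop must therefore exceed about
260 µV to cross the 100 µV default — which genuine electrode pops do, and
the synthetic generator emulates (300–500 µV).

## The synthetic cohort generator

`cohort_config()` fixes the emulated study conditions: 2-minute EO and EC
recordings at 500 Hz per participant, ages uniform over 5–88 years. Each
recording is built from:

- **1/f background**: independent Gaussian noise per channel with power
  ∝ 1/f (exponent configurable), 10 µV RMS on EEG channels — the typical
  broadband amplitude of adult scalp EEG.
- **Alpha**: a sinusoid at the participant's true peak frequency with slow
  (< 0.25 Hz) random amplitude modulation, spatially weighted to be maximal
  at Pz. A narrow-band deterministic-frequency process was chosen over
  band-filtered noise because it gives an unambiguous spectral ground
  truth. EC amplitude at Pz defaults to 10 µV RMS; the EC/EO amplitude
  ratio has median 2 with log-normal between-subject spread (σ = 0.35,
  truncated at 1), and the amplitude itself has log-normal spread
  (σ = 0.4) — without between-subject variability the paired effect size
  would be implausibly large.
- **True iAPF**: the log-Gaussian maturation curve
  `c + a·exp(−(ln age − mu)²/(2σ²))` with defaults
  (a = 2.2, mu = ln 18, σ = 1, c = 8), plus N(0, 1 Hz) between-subject
  scatter, kept inside (7.2, 12.8) Hz so true peaks sit strictly inside the
  7–13 Hz search band. The 1 Hz scatter matches the residual spread
  reported for real lifespan cohorts.
- **Blinks**: 400 ms biphasic pulses, 100 µV on VPVA with a −20 µV
  counterpart on VNVB, propagated into scalp channels with factors decaying
  with distance from the frontopolar sites (0.5 at Fp1/Fp2, length constant
  90 in cap units). 18/min under EO, a tenth of that under EC.
- **Artifacts** at configurable rates: EMG bursts (45–99 Hz noise, 40 µV
  RMS, 0.5–1.5 s), jumps (300–500 µV steps lasting 0.2–0.8 s), swings
  (1–2 Hz, 900 µV peak-to-peak, 2–3 s), and electrode bridges (one channel
  replaced by its nearest neighbour plus 0.3 µV noise). Every injected
  event is recorded in an exact ground-truth event table; masks are what
  was injected, never re-detected.

Per-recording random substreams are derived from
`(cohort seed, participant index, condition)`, so any single recording can
be regenerated in isolation.

What the generator does **not** emulate: volume-conducted correlated
background between channels, non-stationary alpha frequency drift, ECG and
cardiac field artifacts, saccadic HEOG activity, task-evoked potentials,
and realistic head-model topographies. Passing validation on synthetic
cohorts therefore demonstrates the *mechanics* of the chain — detection,
repair arithmetic, spectral estimation, model fitting — not clinical-grade
performance on real recordings.

## Spectral conventions

`segment_log_spectrum()` multiplies each 2500-sample epoch by a periodic
Hann window (coherent gain exactly 0.5), takes `|X/N|²` on the 0.2 Hz FFT
grid, restricts to 2–45 Hz, and applies a natural log after adding a floor
of 1e-12 µV² (relevant only for pathological zero-power input). With this
scaling an on-grid sinusoid of amplitude A contributes (A/2)² per two-sided
bin, so `recover_sine_amplitude()` inverts peak power to amplitude — the
basis of the sine-injection recovery check.

Averaging is two-level and in the log domain: segments → session, then
sessions → condition, so every session counts equally regardless of how
many clean epochs it retained. The EO/EC contrast is computed on the
session-mean log power over 7–13 Hz (band edges inclusive): one value per
session-condition, paired within session, tested with a dependent-samples
t-test, with paired Cohen's d = mean(EC−EO)/sd(EC−EO). A frequency-wise
test across the band would be the main alternative reading; the band-mean
was chosen because it yields a single effect size of the kind usually
reported. The p-value is two-sided even though the hypothesis is
directional; the direction is read from the sign of d.

## iAPF and the maturation model

`find_iapf()` screens local maxima of raw power inside 7–13 Hz with two
criteria: the 1/f-corrected power (log power minus a log-log linear
baseline fitted over 2–45 Hz excluding 6–14 Hz, then exponentiated) must
reach 40% of the band's maximum corrected power, and the raw power must
exceed both adjacent 0.2 Hz grid points by 0.05 µV². "Taking the 1/f
signal into account" is read as detrend-then-ratio; applying the ratio to
raw power with a slope allowance would be the other defensible reading.
Among qualifying candidates the one with maximal corrected power wins; no
qualifying candidate yields a missing value, not an error. iAPFs are taken
from the EC spectra, where posterior alpha is maximal; sessions enter the
maturation fit individually, and sessions without a qualifying peak are
excluded but counted.

`fit_maturation()` fits the same log-Gaussian curve the generator uses by
trust-region nonlinear least squares. The objective is multi-modal in the
peak-age parameter, so three starts (`mu` at ln 10, ln 18, ln 30; `a` from
the observed range, `c` from the 5th percentile, σ = 0.7) are tried and the
smallest residual sum of squares wins. Degenerate flat data (zero iAPF
variance) returns `c = mean`, `a = 0`, `R² = 0` with a warning rather than
a spurious fit. Because the curve contains an additive offset, the residual
sum is exactly zero at the optimum, which makes `R²` coincide with
`1 − var(residuals)/var(iapf)`.

## Problem sizes and numerical checks

The validation suite and `scripts/acceptance.R` use cohorts sized to the
question being asked: 20 participants (40 two-minute recordings) for
detector recall and false positives, a dedicated 20-recording set with a
bridged pair in every recording for the bridge-identification rate (at the
default 5% bridge probability a 20-recording cohort would produce only ~2
bridged pairs — too few to estimate a rate), 200 participants for the EO/EC
effect with a 10,000-participant single-channel brute-force measurement of
the programmed effect as reference, and 500 participants for
maturation-curve recovery. Unit tests use shorter recordings (10–60 s)
wherever the property under test does not depend on duration.

Numerical conventions worth stating: band masks are inclusive of both
edges with a 1e-9 Hz tolerance; Parseval's identity holds exactly for the
unwindowed two-sided spectrum; the 66% repair rule is strict (`> 0.66`), so
a channel flagged at exactly 66% is not repaired; zero-variance EOG
regressors are skipped with a warning; a paired contrast with identically
zero differences returns (t = 0, p = 1, d = 0) and constant nonzero
differences return a flagged degenerate result.

## Known limitations

- The ocular correction is whole-recording OLS, not blink/saccade-resolved.
- Repair replaces entire channels; short artifact spans on otherwise good
  channels are handled by epoch rejection, not interpolation.
- No ICA-based artifact decomposition, no re-referencing, no time-frequency
  or topographic statistics, and no aperiodic/periodic decomposition beyond
  the log-log linear baseline.
- The published full-cohort validation statistics of the clinical archive
  this pipeline targets can only be recomputed with access to that gated
  archive; the synthetic cohorts validate the machinery, not the clinical
  numbers.
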