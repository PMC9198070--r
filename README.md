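# resteeg

Automated preprocessing, artifact detection and spectral quality validation
for clinical resting-state EEG.

## What this is for

Clinical EEG archives typically contain thousands of short resting-state
sessions — two minutes eyes-open (EO), two minutes eyes-closed (EC) — on a
26-channel 10-10 montage with EOG/ECG/EMG auxiliaries at 500 Hz. Before any
biomarker work, such data must be de-artifacted automatically and its
neurophysiological quality checked. `resteeg` provides that chain for R
users:

- **Preprocessing**: bipolar EOG computation, regression-based ocular
  artifact removal (per-channel OLS of each EEG channel on the demeaned
  VEOG/HEOG), demeaning, zero-phase 0.5–100 Hz band-pass and 50 Hz notch.
- **Seven artifact detectors** over 1-s windows: EMG (high-band power),
  sharp channel jumps, kurtosis, extreme voltage swing, residual eye
  blinks, electrode bridging, and extreme inter-channel correlations; all
  thresholds explicit in `detector_config()`.
- **Channel repair**: an EEG channel flagged on more than 66% of samples is
  replaced by the Euclidean inverse-distance weighted average of its ≥ 3
  nearest clean neighbours, using built-in cap coordinates.
- **Segmentation** into artifact-free 5-second epochs.
- **Spectral validation**: Hann-windowed FFT log-power spectra (2–45 Hz at
  0.2 Hz), two-level averaging (segments → session → condition), and the
  paired EO/EC alpha (7–13 Hz) contrast with dependent-samples t and paired
  Cohen's *d* = mean(EC−EO)/sd(EC−EO).
- **iAPF maturation**: individual alpha peak frequency detection in
  7–13 Hz (40%-of-corrected-maximum and 0.05 µV² neighbour-prominence
  criteria on 1/f-detrended spectra) and a log-Gaussian lifespan model
  `iAPF(age) = c + a·exp(−(ln age − µ)²/(2σ²))`, fitted by multi-start
  nonlinear least squares, with residual Shapiro–Wilk normality summary.
- **Synthetic lifespan cohorts**: `simulate_cohort()` generates EO/EC
  recordings (1/f background, posterior alpha with EC > EO amplitude,
  blinks, EMG bursts, jumps, swings, bridged electrode pairs) with exact
  ground-truth masks, so the whole chain is testable without
  access-controlled clinical data.
- **I/O**: BrainVision (`.vhdr`/`.vmrk`/`.eeg`, multiplexed INT_16 /
  IEEE_FLOAT_32) and CSV-derivative (+ JSON sidecar) readers/writers in a
  BIDS-like `sub-<id>/ses-<n>/eeg/` layout with `participants.tsv`.

## Worked example

Simulate a small cohort, preprocess it, and run both validation analyses:

```r
library(resteeg)

cfg <- cohort_config(n_participants = 12, duration_s = 60, seed = 7,
                     iapf_noise_sd = 0.5)
raw <- file.path(tempdir(), "raw")
simulate_cohort(cfg, dir = raw)

eoec <- validate_eoec(raw)          # preprocess + paired alpha contrast
eoec$contrast
iapf <- validate_iapf(raw)          # preprocess + iAPF maturation fit
iapf$fit
```

```
<eoec_contrast> 7-13 Hz, n = 12 pairs: t = 3.446, p = 0.00547, d = 0.995
<maturation_fit> n = 12: iAPF ~ 9.14 + 1.24 exp(-(ln age - 2.83)^2 / (2 * 0.63^2))
  peak age 16.9 y, R^2 = 0.601, residuals 0.000 +/- 0.382, Shapiro W = 0.959
```

Reading the output: the paired contrast says EC alpha log power at Pz
exceeded EO in these 12 sessions (positive *d*; the generator programs a
median EC/EO amplitude ratio of 2). The maturation fit recovers a curve
peaking near age 17 from only 12 noisy sessions; at realistic cohort sizes
(hundreds of sessions) the peak age lands within a couple of years of the
programmed 18 (see the acceptance script below). A small `d` with large `p`
would flag an archive whose conditions were mislabelled; a missing alpha
peak in many sessions would flag poor spectral quality.

The same stages are scriptable from a shell via the thin CLI in
`exec/resteeg`:

```sh
Rscript exec/resteeg simulate --out raw --n 12 --seed 7
Rscript exec/resteeg preprocess --in raw --out derivatives
Rscript exec/resteeg validate-eoec --in raw --out eoec.json
Rscript exec/resteeg validate-iapf --in raw --out iapf.json
```

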