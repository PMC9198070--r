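Package: resteeg
Title: Resting-State EEG Preprocessing, Artifact Detection and Spectral
    Quality Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An automated preprocessing and de-artifacting pipeline for
    multichannel resting-state EEG (26 scalp channels plus EOG/ECG/EMG
    auxiliaries at 500 Hz): regression-based ocular artifact removal,
    band-pass and notch filtering, seven artifact detectors (EMG, channel
    jumps, kurtosis, voltage swing, residual blinks, electrode bridging,
    extreme correlations), inverse-distance weighted repair of bad channels,
    and segmentation into 5-second epochs. Includes Hann-windowed FFT
    log-power spectra with an eyes-open/eyes-closed alpha attenuation
    contrast, individual alpha peak frequency (iAPF) detection with a
    log-Gaussian lifespan maturation model, readers and writers for
    BrainVision and CSV derivative formats in a BIDS-like layout, and a
    synthetic lifespan-cohort generator with ground-truth artifact masks so
    the whole chain can be validated without access-controlled clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
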