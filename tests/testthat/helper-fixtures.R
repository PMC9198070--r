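# Shared fixtures built in code.

# A small white-noise recording on a subset of montage channels.
tiny_recording <- function(channels = c("Fp1", "Fp2", "Pz", "Oz",
                                        "VPVA", "VNVB", "HOHL", "HNHR"),
                           duration_s = 12, srate = 500, seed = 11,
                           condition = "EO") {
  set.seed(seed)
  n <- duration_s * srate
  new_recording(matrix(rnorm(length(channels) * n, sd = 10),
                       nrow = length(channels)),
                channels = channels, srate = srate,
                participant_id = "20000001", session = 1L,
                condition = condition, age = 30)
}

# A toy montage with hand-chosen coordinates for repair-weight arithmetic.
toy_montage <- function(coords) {
  m <- data.frame(name = names(coords), role = "EEG",
                  x = vapply(coords, `[`, 0, 1),
                  y = vapply(coords, `[`, 0, 2),
                  z = vapply(coords, `[`, 0, 3),
                  stringsAsFactors = FALSE)
  class(m) <- c("eeg_montage", "data.frame")
  m
}

# Build an artifact_mask directly from a logical flag matrix.
manual_mask <- function(flags) {
  structure(list(flags = flags,
                 provenance = data.frame(kind = character(),
                                         channel = character(),
                                         start = integer(), end = integer(),
                                         stringsAsFactors = FALSE),
                 window_s = 1, n_windows = ncol(flags) %/% 500),
            class = "artifact_mask")
}

# Config with all artifact injection switched off.
clean_config <- function(...) {
  cohort_config(...,
                artifact_rates = list(blinks_per_min = 0, emg_per_min = 0,
                                      jumps_per_recording = 0,
                                      swings_per_recording = 0,
                                      bridge_prob = 0))
}
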