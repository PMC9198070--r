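#' Repair channels dominated by artifacts
#'
#' An EEG channel flagged for more than 66% of the measurement is replaced
#' entirely by the Euclidean inverse-distance weighted average of its nearest
#' clean EEG neighbours (at least 3, at most 4): weights
#' `w_i = (1/d_i) / sum(1/d_j)`. Only channels whose own flagged fraction is
#' at most 0.66 may donate. The repaired channel's mask rows are cleared
#' except at samples where a donor was itself flagged. A channel with fewer
#' than 3 eligible neighbours is left untouched and reported as unrepairable;
#' such channels are meant to be excluded from segmentation.
#'
#' @param rec an `eeg_recording`.
#' @param mask an `artifact_mask` for `rec`.
#' @param montage montage supplying electrode coordinates.
#' @return list with `recording` (repaired), `mask` (updated),
#'   `log` (data-frame-free list of repair records: channel, flagged
#'   fraction, donors, distances, weights) and `unrepairable` (character
#'   vector of channel names).
#' @export
repair_channels <- function(rec, mask, montage = load_builtin_montage()) {
  stopifnot(identical(dim(mask$flags), dim(rec$data)))
  eeg_idx <- eeg_channel_indices(rec, montage)
  eeg_names <- rec$channels[eeg_idx]
  frac <- rowMeans(mask$flags[eeg_idx, , drop = FALSE])
  names(frac) <- eeg_names
  bad <- names(frac)[frac > 0.66]  # strictly more than 66%
  dmat <- montage_distances(montage)

  original <- rec$data
  original_flags <- mask$flags
  log <- list()
  unrepairable <- character()

  for (ch in bad) {
    donors_pool <- setdiff(eeg_names[frac <= 0.66], ch)
    if (length(donors_pool) < 3) {
      unrepairable <- c(unrepairable, ch)
      next
    }
    d <- dmat[ch, donors_pool]
    ord <- order(d)
    k <- min(4, length(donors_pool))
    donors <- donors_pool[ord[seq_len(k)]]
    dd <- d[ord[seq_len(k)]]
    w <- (1 / dd) / sum(1 / dd)
    rec$data[ch, ] <- as.vector(w %*% original[donors, , drop = FALSE])
    donor_flagged <- colSums(original_flags[donors, , drop = FALSE]) > 0
    mask$flags[ch, ] <- donor_flagged
    log[[ch]] <- list(channel = ch, flagged_fraction = unname(frac[ch]),
                      donors = donors, distances = unname(dd),
                      weights = unname(w))
  }

  attr(log, "header") <- paste(
    "ocular correction: whole-recording two-regressor OLS",
    "(no blink/saccade event separation)")
  list(recording = rec, mask = mask, log = log, unrepairable = unrepairable)
}
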