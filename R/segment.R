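#' Segment a cleaned recording into artifact-free 5-second epochs
#'
#' Consecutive non-overlapping epochs of `epoch_s` seconds; an epoch is
#' retained only if none of its samples on any (non-excluded) EEG channel is
#' flagged. Auxiliary channels never veto an epoch. The trailing partial
#' epoch is dropped. Zero retained epochs is a valid (empty) result, with the
#' reason recorded.
#'
#' @param rec an `eeg_recording`.
#' @param mask optional `artifact_mask`; `NULL` treats the recording as clean.
#' @param exclude channel names whose flags are ignored (e.g. unrepairable
#'   channels).
#' @param epoch_s epoch length in seconds.
#' @return list of class `segmented_recording`: `epochs` (array
#'   `n_epochs x n_channels x samples`), `channels`, `epoch_indices` (which
#'   source epochs were retained), `n_total` epochs available, `srate`, and
#'   `reason` when empty.
#' @export
segment_epochs <- function(rec, mask = NULL, exclude = character(),
                           epoch_s = 5) {
  fs <- rec$srate
  len <- round(epoch_s * fs)
  n <- n_samples(rec)
  n_total <- n %/% len
  montage <- load_builtin_montage()
  eeg_idx <- eeg_channel_indices(rec, montage)
  veto_idx <- setdiff(eeg_idx, match(exclude, rec$channels))

  keep <- logical(n_total)
  for (k in seq_len(n_total)) {
    idx <- ((k - 1) * len + 1):(k * len)
    keep[k] <- is.null(mask) ||
      !any(mask$flags[veto_idx, idx, drop = FALSE])
  }
  kept <- which(keep)
  epochs <- array(NA_real_, dim = c(length(kept), nrow(rec$data), len),
                  dimnames = list(NULL, rec$channels, NULL))
  for (i in seq_along(kept)) {
    idx <- ((kept[i] - 1) * len + 1):(kept[i] * len)
    epochs[i, , ] <- rec$data[, idx]
  }
  reason <- if (n_total == 0) {
    sprintf("recording shorter than one %g s epoch", epoch_s)
  } else if (!length(kept)) {
    "all epochs contained flagged samples"
  }
  structure(list(epochs = epochs, channels = rec$channels,
                 epoch_indices = kept, n_total = n_total, srate = fs,
                 epoch_s = epoch_s, reason = reason),
            class = "segmented_recording")
}

#' @export
print.segmented_recording <- function(x, ...) {
  cat(sprintf("<segmented_recording> %d/%d epochs of %g s retained (%d channels)\n",
              length(x$epoch_indices), x$n_total, x$epoch_s,
              length(x$channels)))
  if (!is.null(x$reason)) cat("  note:", x$reason, "\n")
  invisible(x)
}

#' Extract one channel's retained epochs as a matrix
#'
#' @param seg a `segmented_recording`.
#' @param channel channel name.
#' @return numeric matrix `n_epochs x samples`.
#' @export
epoch_matrix <- function(seg, channel) {
  ch <- canonical_channel_names(channel)
  i <- match(ch, seg$channels)
  if (is.na(i)) stop("channel not present: ", channel)
  m <- seg$epochs[, i, , drop = FALSE]
  dim(m) <- dim(m)[c(1, 3)]
  m
}
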