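# Preprocessing stage 1: ocular correction and filtering. The pipeline order
# is fixed: bipolar EOG -> regression-based ocular correction -> demean +
# band-pass + notch -> artifact detection -> channel repair -> segmentation.

#' Compute the bipolar EOG channels
#'
#' Vertical EOG is the difference of the electrodes above and below the eye
#' (`VPVA - VNVB`), horizontal EOG the difference of the lateral pair
#' (`HOHL - HNHR`).
#'
#' @param rec an `eeg_recording` containing the four EOG electrodes.
#' @return list with numeric vectors `veog` and `heog`.
#' @export
compute_bipolar_eog <- function(rec) {
  need <- c("VPVA", "VNVB", "HOHL", "HNHR")
  missing <- setdiff(need, rec$channels)
  if (length(missing)) {
    stop("missing EOG channels: ", paste(missing, collapse = ", "))
  }
  list(veog = rec$data["VPVA", ] - rec$data["VNVB", ],
       heog = rec$data["HOHL", ] - rec$data["HNHR", ])
}

#' Regression-based ocular artifact removal
#'
#' For each EEG channel, propagation coefficients of the vertical and
#' horizontal bipolar EOG are estimated by ordinary least squares on the
#' demeaned series, and the fitted ocular contribution is subtracted
#' (whole-recording variant of the classic EOG regression correction).
#' Auxiliary channels pass through unchanged. A regressor with (near) zero
#' variance is skipped with a warning.
#'
#' @param rec an `eeg_recording`.
#' @param veog,heog bipolar EOG series from [compute_bipolar_eog()].
#' @return corrected `eeg_recording`; per-channel coefficients are attached
#'   as attribute `"eog_coefficients"`.
#' @export
gratton_correct <- function(rec, veog, heog) {
  n <- n_samples(rec)
  stopifnot(length(veog) == n, length(heog) == n)
  montage <- load_builtin_montage()
  eeg_idx <- eeg_channel_indices(rec, montage)

  regs <- list(veog = veog - mean(veog), heog = heog - mean(heog))
  keep <- vapply(regs, function(r) stats::var(r) > 1e-12, TRUE)
  if (!all(keep)) {
    warning("zero-variance EOG regressor skipped: ",
            paste(names(regs)[!keep], collapse = ", "))
  }
  regs <- regs[keep]
  coefs <- matrix(0, nrow = length(eeg_idx), ncol = 2,
                  dimnames = list(rec$channels[eeg_idx], c("veog", "heog")))
  if (length(regs)) {
    X <- do.call(cbind, regs)
    Y <- t(rec$data[eeg_idx, , drop = FALSE])
    Y <- sweep(Y, 2, colMeans(Y))
    B <- solve(crossprod(X), crossprod(X, Y))  # p x n_eeg
    rec$data[eeg_idx, ] <- rec$data[eeg_idx, , drop = FALSE] - t(X %*% B)
    coefs[, colnames(X)] <- t(B)
  }
  attr(rec, "eog_coefficients") <- coefs
  rec
}

#' Demean, band-pass and notch filter a recording
#'
#' Per channel: the mean is subtracted, a zero-phase (forward-backward)
#' Butterworth band-pass of order 4 between 0.5 and 99 Hz is applied, and a
#' zero-phase order-2 notch (band-stop 49-51 Hz) removes line noise. The
#' upper band edge sits at 99 Hz rather than 100 Hz to keep the design
#' stable at a 500 Hz sampling rate; the recording hardware low-passes at
#' 100 Hz before digitization anyway.
#'
#' @param rec an `eeg_recording` of at least 10 s.
#' @param band band-pass corner frequencies, Hz.
#' @param notch line frequency to remove, Hz (width +-1 Hz); `NULL` disables.
#' @return filtered `eeg_recording` of identical dimensions.
#' @export
filter_recording <- function(rec, band = c(0.5, 100), notch = 50) {
  fs <- rec$srate
  if (n_samples(rec) < 10 * fs) {
    stop("recording shorter than 10 s; too short for stable filtering")
  }
  hi <- min(band[2], 0.99 * fs / 2, 99)
  bp <- signal::butter(4, c(band[1], hi) / (fs / 2), type = "pass")
  bs <- if (!is.null(notch)) {
    signal::butter(2, c(notch - 1, notch + 1) / (fs / 2), type = "stop")
  }
  for (i in seq_len(nrow(rec$data))) {
    x <- rec$data[i, ] - mean(rec$data[i, ])
    x <- signal::filtfilt(bp, x)
    if (!is.null(bs)) x <- signal::filtfilt(bs, x)
    rec$data[i, ] <- x
  }
  rec
}
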