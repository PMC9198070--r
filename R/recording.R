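#' Construct a resting-state EEG recording
#'
#' The core container of the package: one participant-session-condition
#' multichannel time series in microvolts, with channel names matching the
#' montage and basic subject metadata.
#'
#' @param data numeric matrix, channels in rows, samples in columns, in uV.
#' @param channels character vector of channel names, one per row of `data`.
#' @param srate sampling rate in Hz.
#' @param participant_id 8-digit identifier string.
#' @param session positive integer session number.
#' @param condition `"EO"` (eyes open) or `"EC"` (eyes closed).
#' @param age age in years (optional).
#' @param gender free-form gender label (optional).
#' @return an object of class `eeg_recording`.
#' @export
new_recording <- function(data, channels, srate = 500,
                          participant_id = "00000000", session = 1L,
                          condition = c("EO", "EC"),
                          age = NA_real_, gender = NA_character_) {
  condition <- match.arg(condition)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  channels <- as.character(channels)
  if (nrow(data) != length(channels)) {
    stop(sprintf("data has %d rows but %d channel names given",
                 nrow(data), length(channels)))
  }
  if (anyDuplicated(channels)) stop("duplicate channel names")
  if (!is.numeric(srate) || length(srate) != 1 || srate <= 0) {
    stop("sampling_rate must be a single positive number")
  }
  if (any(!is.finite(data))) stop("recording contains non-finite values")
  if (!is.na(age) && age < 0) stop("age must be nonnegative")
  rownames(data) <- channels
  structure(
    list(participant_id = as.character(participant_id),
         session = as.integer(session),
         condition = condition,
         srate = as.numeric(srate),
         channels = channels,
         data = data,
         age = as.numeric(age),
         gender = as.character(gender)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %s-%d.%s: %d channels x %d samples @ %g Hz (%.1f s)%s\n",
    x$participant_id, x$session, x$condition,
    nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate,
    if (is.na(x$age)) "" else sprintf(", age %.1f", x$age)))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec an `eeg_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(rec) ncol(rec$data)

#' Extract one channel as a numeric vector
#' @param rec an `eeg_recording`.
#' @param channel channel name (canonicalized against the built-in montage).
#' @return numeric vector of samples in uV.
#' @export
channel_data <- function(rec, channel) {
  ch <- canonical_channel_names(channel)
  i <- match(ch, rec$channels)
  if (is.na(i)) stop("channel not present in recording: ", channel)
  rec$data[i, ]
}

# Index of EEG-role channels of a recording within the montage order.
eeg_channel_indices <- function(rec, montage = load_builtin_montage()) {
  which(rec$channels %in% montage$name[montage$role == "EEG"])
}
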