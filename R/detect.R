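# Stage 2: artifact detection. Seven detectors, each flagging whole analysis
# windows per channel: EMG (high-band power), JUMP (sharp steps), KURTOSIS
# (impulsive windows), SWING (extreme peak-to-peak), BLINK (residual ocular
# activity on frontal channels), BRIDGE (electrically shorted electrode
# pairs) and CORR (non-bridged near-duplicate channels).

#' Detector thresholds
#'
#' All thresholds are explicit configuration. Defaults are chosen so that the
#' false-positive rate on clean synthetic recordings stays below a few
#' percent (see the package vignette for the rationale per detector).
#'
#' @param window_s analysis window length, seconds.
#' @param emg_band muscle-activity band, Hz.
#' @param emg_factor flag windows whose high-band power exceeds this multiple
#'   of the channel's median window power.
#' @param jump_uv maximal allowed step between adjacent samples, uV.
#' @param kurtosis_max maximal window sample kurtosis (raw, Gaussian = 3).
#' @param swing_uv maximal window peak-to-peak amplitude, uV.
#' @param blink_corr maximal window correlation of a frontal channel with the
#'   bipolar vertical EOG (after ocular correction).
#' @param bridge_var_uv2 a channel pair whose difference has variance below
#'   this (uV^2) in at least half of the windows is considered bridged.
#' @param corr_max a channel correlating above this with one single other
#'   channel in at least half of the windows is a non-bridged duplicate.
#' @return list of class `detector_config`.
#' @export
detector_config <- function(window_s = 1, emg_band = c(45, 100),
                            emg_factor = 4, jump_uv = 100, kurtosis_max = 8,
                            swing_uv = 300, blink_corr = 0.8,
                            bridge_var_uv2 = 0.5, corr_max = 0.975) {
  stopifnot(window_s > 0, emg_factor > 0, jump_uv > 0, kurtosis_max > 0,
            swing_uv > 0, blink_corr > 0, bridge_var_uv2 > 0, corr_max > 0,
            length(emg_band) == 2, emg_band[1] > 0, emg_band[1] < emg_band[2])
  structure(as.list(environment()), class = "detector_config")
}

.artifact_kinds <- c("EMG", "JUMP", "KURTOSIS", "SWING", "BLINK", "BRIDGE", "CORR")

# window index boundaries: non-overlapping windows of w samples, the trailing
# remainder merged into the last window.
.window_bounds <- function(n, w) {
  n_win <- n %/% w
  if (n_win < 1) stop("analysis window longer than the recording")
  start <- (seq_len(n_win) - 1) * w + 1
  end <- start + w - 1
  end[n_win] <- n
  cbind(start = start, end = end)
}

# turn a per-window logical vector into sample regions
.windows_to_regions <- function(flagged, bounds) {
  r <- rle(flagged)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1
  on <- which(r$values)
  if (!length(on)) return(NULL)
  data.frame(start = bounds[starts[on], "start"],
             end = bounds[stops[on], "end"])
}

#' Detect artifacts in a filtered recording
#'
#' Runs the seven detectors on the EEG channels and returns the union of
#' their flags with per-region provenance. Auxiliary channels are never
#' flagged.
#'
#' @param rec a filtered `eeg_recording`.
#' @param veog bipolar vertical EOG series (for the residual-blink detector).
#' @param cfg a [detector_config()].
#' @return object of class `artifact_mask`: list with `flags` (logical
#'   channels x samples matrix), `provenance` (data frame `kind`, `channel`,
#'   `start`, `end`) and the window layout used.
#' @export
detect_artifacts <- function(rec, veog = NULL, cfg = detector_config()) {
  fs <- rec$srate
  n <- n_samples(rec)
  w <- round(cfg$window_s * fs)
  bounds <- .window_bounds(n, w)
  n_win <- nrow(bounds)
  montage <- load_builtin_montage()
  eeg_idx <- eeg_channel_indices(rec, montage)
  eeg_names <- rec$channels[eeg_idx]
  n_eeg <- length(eeg_idx)

  flags <- matrix(FALSE, nrow = nrow(rec$data), ncol = n,
                  dimnames = list(rec$channels, NULL))
  prov <- list()
  add_regions <- function(kind, channel, regions) {
    if (is.null(regions)) return()
    for (i in seq_len(nrow(regions))) {
      flags[channel, regions$start[i]:regions$end[i]] <<- TRUE
    }
    prov[[length(prov) + 1]] <<- data.frame(
      kind = kind, channel = channel, start = regions$start,
      end = regions$end, stringsAsFactors = FALSE)
  }

  X <- rec$data[eeg_idx, , drop = FALSE]

  # EMG: high-band power per window vs channel median
  hi <- min(cfg$emg_band[2], 0.99 * fs / 2)
  bp <- signal::butter(4, c(cfg$emg_band[1], hi) / (fs / 2), type = "pass")
  for (j in seq_len(n_eeg)) {
    xb <- signal::filtfilt(bp, X[j, ])
    pw <- vapply(seq_len(n_win), function(k)
      mean(xb[bounds[k, 1]:bounds[k, 2]]^2), 0)
    flagged <- pw > cfg$emg_factor * stats::median(pw)
    add_regions("EMG", eeg_names[j], .windows_to_regions(flagged, bounds))
  }

  # JUMP / KURTOSIS / SWING per window
  for (j in seq_len(n_eeg)) {
    x <- X[j, ]
    dif <- c(0, abs(diff(x)))  # step attributed to the later sample's window
    jump <- logical(n_win); kurt <- logical(n_win); swing <- logical(n_win)
    for (k in seq_len(n_win)) {
      idx <- bounds[k, 1]:bounds[k, 2]
      xi <- x[idx]
      jump[k] <- any(dif[idx] > cfg$jump_uv)
      m <- mean(xi)
      m2 <- mean((xi - m)^2)
      kurt[k] <- m2 > 0 && mean((xi - m)^4) / m2^2 > cfg$kurtosis_max
      swing[k] <- (max(xi) - min(xi)) > cfg$swing_uv
    }
    add_regions("JUMP", eeg_names[j], .windows_to_regions(jump, bounds))
    add_regions("KURTOSIS", eeg_names[j], .windows_to_regions(kurt, bounds))
    add_regions("SWING", eeg_names[j], .windows_to_regions(swing, bounds))
  }

  # BLINK: residual correlation of frontal channels with the vertical EOG
  if (!is.null(veog)) {
    stopifnot(length(veog) == n)
    frontal <- montage$name[montage$role == "EEG" & montage$y > 40]
    for (ch in intersect(frontal, eeg_names)) {
      x <- rec$data[ch, ]
      fl <- vapply(seq_len(n_win), function(k) {
        idx <- bounds[k, 1]:bounds[k, 2]
        if (stats::sd(x[idx]) < 1e-12 || stats::sd(veog[idx]) < 1e-12) {
          return(FALSE)
        }
        abs(stats::cor(x[idx], veog[idx])) > cfg$blink_corr
      }, TRUE)
      add_regions("BLINK", ch, .windows_to_regions(fl, bounds))
    }
  }

  # BRIDGE and CORR need per-window covariances between all EEG pairs
  if (n_eeg >= 2) {
    low_var <- matrix(0L, n_eeg, n_eeg)
    high_cor <- matrix(0L, n_eeg, n_eeg)
    for (k in seq_len(n_win)) {
      idx <- bounds[k, 1]:bounds[k, 2]
      M <- X[, idx, drop = FALSE]
      M <- M - rowMeans(M)
      C <- tcrossprod(M) / (length(idx) - 1)
      v <- diag(C)
      dvar <- outer(v, v, "+") - 2 * C
      low_var <- low_var + (dvar < cfg$bridge_var_uv2)
      s <- sqrt(pmax(v, 1e-300))
      corr <- C / outer(s, s)
      high_cor <- high_cor + (abs(corr) > cfg$corr_max)
    }
    diag(low_var) <- 0L
    diag(high_cor) <- 0L
    bridged <- which(low_var >= n_win / 2 & upper.tri(low_var), arr.ind = TRUE)
    bridged_ch <- unique(eeg_names[as.vector(bridged)])
    for (ch in bridged_ch) {
      add_regions("BRIDGE", ch, data.frame(start = 1L, end = n))
    }
    dup <- which(high_cor >= n_win / 2 & upper.tri(high_cor), arr.ind = TRUE)
    if (nrow(dup)) {
      keep <- !(eeg_names[dup[, 1]] %in% bridged_ch &
                  eeg_names[dup[, 2]] %in% bridged_ch)
      dup_ch <- unique(eeg_names[as.vector(dup[keep, , drop = FALSE])])
      for (ch in setdiff(dup_ch, bridged_ch)) {
        add_regions("CORR", ch, data.frame(start = 1L, end = n))
      }
    }
  }

  prov <- if (length(prov)) do.call(rbind, prov) else
    data.frame(kind = character(), channel = character(),
               start = integer(), end = integer(), stringsAsFactors = FALSE)
  structure(list(flags = flags, provenance = prov,
                 window_s = cfg$window_s, n_windows = n_win),
            class = "artifact_mask")
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf("<artifact_mask> %d x %d, %.2f%% flagged, %d regions\n",
              nrow(x$flags), ncol(x$flags), 100 * mean(x$flags),
              nrow(x$provenance)))
  if (nrow(x$provenance)) print(table(x$provenance$kind))
  invisible(x)
}

#' Rebuild the flag matrix for a subset of detector kinds
#'
#' @param mask an `artifact_mask`.
#' @param kinds detector kinds to include.
#' @return logical matrix of the same shape as `mask$flags`.
#' @export
mask_by_kind <- function(mask, kinds) {
  stopifnot(all(kinds %in% .artifact_kinds))
  m <- mask$flags & FALSE
  p <- mask$provenance[mask$provenance$kind %in% kinds, , drop = FALSE]
  for (i in seq_len(nrow(p))) {
    m[p$channel[i], p$start[i]:p$end[i]] <- TRUE
  }
  m
}
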