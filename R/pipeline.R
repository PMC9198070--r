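# End-to-end pipeline: preprocess one recording or a whole dataset, and the
# two neurophysiological validation analyses (EO/EC alpha attenuation,
# iAPF maturation).

#' Preprocess one recording
#'
#' Fixed stage order: bipolar EOG -> ocular regression correction -> demean /
#' band-pass / notch -> seven artifact detectors -> repair of channels
#' flagged > 66% -> segmentation into artifact-free 5-s epochs. A recording
#' whose Pz (the validation channel) cannot be repaired is reported as
#' failed.
#'
#' @param rec an `eeg_recording`.
#' @param det_cfg a [detector_config()].
#' @return list of class `preprocessed_recording`: `segments`
#'   (a `segmented_recording`), `recording` (cleaned), `mask`, `repair_log`,
#'   `unrepairable`, `qc` (per-detector flagged percentages and epoch
#'   counts), `status` (`"ok"` or `"failed"`), `reason`.
#' @export
preprocess_recording <- function(rec, det_cfg = detector_config()) {
  eog <- compute_bipolar_eog(rec)
  rec_c <- gratton_correct(rec, eog$veog, eog$heog)
  rec_f <- filter_recording(rec_c)
  veog_f <- compute_bipolar_eog(rec_f)$veog
  mask <- detect_artifacts(rec_f, veog_f, det_cfg)
  rep <- repair_channels(rec_f, mask)
  status <- "ok"
  reason <- NULL
  if ("Pz" %in% rep$unrepairable) {
    status <- "failed"
    reason <- "validation channel Pz unrepairable (fewer than 3 clean neighbours)"
  }
  seg <- segment_epochs(rep$recording, rep$mask, exclude = rep$unrepairable)

  montage <- load_builtin_montage()
  eeg_idx <- eeg_channel_indices(rec, montage)
  n_eeg_samp <- length(eeg_idx) * n_samples(rec)
  flag_pct <- vapply(.artifact_kinds, function(k) {
    p <- mask$provenance[mask$provenance$kind == k, , drop = FALSE]
    100 * sum(p$end - p$start + 1) / n_eeg_samp
  }, 0)
  qc <- list(entry = format_entry_name(rec$participant_id, rec$session,
                                       rec$condition),
             participant_id = rec$participant_id, session = rec$session,
             condition = rec$condition, status = status, reason = reason,
             flagged_pct_by_detector = as.list(flag_pct),
             flagged_pct_total = 100 * mean(mask$flags[eeg_idx, ]),
             repaired_channels = lapply(unname(rep$log), function(l)
               l[c("channel", "flagged_fraction", "donors", "weights")]),
             unrepairable_channels = rep$unrepairable,
             n_epochs_retained = length(seg$epoch_indices),
             n_epochs_total = seg$n_total)
  structure(list(segments = seg, recording = rep$recording, mask = rep$mask,
                 repair_log = rep$log, unrepairable = rep$unrepairable,
                 qc = qc, status = status, reason = reason),
            class = "preprocessed_recording")
}

#' Session-mean log-power spectrum of one channel
#'
#' @param seg a `segmented_recording`.
#' @param channel channel name (default the validation channel Pz).
#' @return a `power_spectrum` averaged over the retained epochs, or `NULL`
#'   when no epoch was retained.
#' @export
session_spectrum <- function(seg, channel = "Pz") {
  if (!length(seg$epoch_indices)) return(NULL)
  em <- epoch_matrix(seg, channel)
  spectra <- lapply(seq_len(nrow(em)), function(i)
    segment_log_spectrum(em[i, ], srate = seg$srate, epoch_s = seg$epoch_s))
  average_spectra(spectra)
}

#' Band-mean log power of one recording
#'
#' Convenience wrapper: preprocess (optional), segment, compute the
#' session-mean spectrum at `channel` and average its log power over `band`.
#'
#' @param rec an `eeg_recording`.
#' @param channel channel of interest.
#' @param band frequency band, Hz.
#' @param preprocess `"full"` runs the whole artifact pipeline, `"filter"`
#'   only demeans/filters and segments without artifact masking, `"none"`
#'   segments the raw data directly (for known-clean zero-mean simulations).
#' @param det_cfg detector configuration when `preprocess` is `"full"`.
#' @return scalar band-mean log power, or `NA` if no epochs survive.
#' @export
session_band_value <- function(rec, channel = "Pz", band = c(7, 13),
                               preprocess = c("full", "filter", "none"),
                               det_cfg = detector_config()) {
  preprocess <- match.arg(preprocess)
  seg <- switch(preprocess,
    full = {
      pp <- preprocess_recording(rec, det_cfg)
      if (pp$status != "ok") return(NA_real_)
      pp$segments
    },
    filter = segment_epochs(filter_recording(rec)),
    none = segment_epochs(rec))
  sp <- session_spectrum(seg, channel)
  if (is.null(sp)) return(NA_real_)
  band_logpower(sp, band)
}

#' Preprocess every recording of a dataset directory
#'
#' Reads all CSV derivatives under `in_dir`, runs [preprocess_recording()]
#' on each, writes cleaned derivatives and a per-recording QC JSON under
#' `out_dir` (same layout), plus a dataset-level `qc_summary.json`. Failures
#' are isolated: one bad recording does not stop the rest.
#'
#' @param in_dir dataset root with `sub-*/ses-*/eeg/*.csv`.
#' @param out_dir output root.
#' @param det_cfg a [detector_config()].
#' @return invisibly, a data frame with one row per recording: entry,
#'   status, epochs retained.
#' @export
preprocess_dataset <- function(in_dir, out_dir, det_cfg = detector_config()) {
  files <- list_condition_files(in_dir)
  if (!nrow(files)) stop("no condition files found under ", in_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (i in seq_len(nrow(files))) {
    f <- files[i, ]
    entry <- format_entry_name(f$participant_id, f$session, f$condition)
    res <- tryCatch({
      rec <- read_csv_derivative(f$path)
      pp <- preprocess_recording(rec, det_cfg)
      sub <- file.path(out_dir, paste0("sub-", f$participant_id),
                       paste0("ses-", f$session), "eeg")
      write_csv_derivative(pp$recording, sub, base = entry)
      jsonlite::write_json(pp$qc, file.path(sub, paste0(entry, ".qc.json")),
                           auto_unbox = TRUE, digits = NA, null = "null")
      message(sprintf("%s: %s, %d/%d epochs retained", entry, pp$status,
                      pp$qc$n_epochs_retained, pp$qc$n_epochs_total))
      data.frame(entry = entry, status = pp$status,
                 n_epochs = pp$qc$n_epochs_retained, stringsAsFactors = FALSE)
    }, error = function(e) {
      message(entry, ": failed (", conditionMessage(e), ")")
      data.frame(entry = entry, status = "error", n_epochs = 0L,
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  summary <- do.call(rbind, rows)
  jsonlite::write_json(summary, file.path(out_dir, "qc_summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(summary)
}

# Collect per-session preprocessed band values / spectra / iAPFs of a
# dataset directory of raw derivatives.
.session_results <- function(dir, channel, det_cfg, preprocess = TRUE) {
  files <- list_condition_files(dir)
  if (!nrow(files)) stop("no condition files found under ", dir)
  out <- list()
  for (i in seq_len(nrow(files))) {
    f <- files[i, ]
    rec <- read_csv_derivative(f$path)
    seg <- if (preprocess) {
      pp <- preprocess_recording(rec, det_cfg)
      if (pp$status != "ok") next
      pp$segments
    } else {
      segment_epochs(filter_recording(rec))
    }
    sp <- session_spectrum(seg, channel)
    if (is.null(sp)) next
    out[[length(out) + 1]] <- list(
      participant_id = f$participant_id, session = f$session,
      condition = f$condition, age = rec$age, spectrum = sp)
  }
  out
}

#' Eyes-open / eyes-closed validation analysis of a dataset
#'
#' Preprocesses every session, computes the session-mean Pz log-power
#' spectrum per condition, pairs EO with EC within each participant-session,
#' and tests the 7-13 Hz band contrast with a dependent-samples t-test and
#' paired Cohen's d.
#'
#' @param dir dataset root of raw CSV derivatives.
#' @param channel channel of interest.
#' @param band contrast band, Hz.
#' @param det_cfg a [detector_config()].
#' @param preprocess run the artifact pipeline (TRUE) or plain
#'   filter+segment (FALSE).
#' @return list with `contrast` (an `eoec_contrast`), `pairs` (data frame of
#'   per-session band values) and `mean_spectra` (condition-mean
#'   `power_spectrum` objects for plotting).
#' @export
validate_eoec <- function(dir, channel = "Pz", band = c(7, 13),
                          det_cfg = detector_config(), preprocess = TRUE) {
  sess <- .session_results(dir, channel, det_cfg, preprocess)
  key <- vapply(sess, function(s)
    paste0(s$participant_id, "-", s$session), "")
  cond <- vapply(sess, function(s) s$condition, "")
  pairs <- list()
  for (k in unique(key)) {
    i_eo <- which(key == k & cond == "EO")
    i_ec <- which(key == k & cond == "EC")
    if (length(i_eo) != 1 || length(i_ec) != 1) next
    pairs[[k]] <- data.frame(
      session = k,
      eo = band_logpower(sess[[i_eo]]$spectrum, band),
      ec = band_logpower(sess[[i_ec]]$spectrum, band),
      stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs)
  if (is.null(pairs) || nrow(pairs) < 3) {
    stop("fewer than 3 complete EO/EC session pairs")
  }
  mean_spectra <- lapply(c(EO = "EO", EC = "EC"), function(cc) {
    average_spectra(lapply(sess[cond == cc], function(s) s$spectrum),
                    condition = cc)
  })
  list(contrast = eo_ec_contrast(pairs$eo, pairs$ec, band),
       pairs = pairs, mean_spectra = mean_spectra)
}

#' iAPF maturation validation analysis of a dataset
#'
#' Preprocesses every eyes-closed session, detects the individual alpha peak
#' frequency at `channel` and fits the log-Gaussian maturation curve against
#' age. Sessions without a qualifying peak are excluded from the fit but
#' counted.
#'
#' @param dir dataset root of raw CSV derivatives.
#' @param channel channel of interest.
#' @param condition condition the spectra are taken from (alpha is maximal
#'   with eyes closed).
#' @param det_cfg a [detector_config()].
#' @param preprocess run the artifact pipeline (TRUE) or plain
#'   filter+segment (FALSE).
#' @return list with `fit` (a `maturation_fit`), `observations` (data frame
#'   of participant, session, age, iapf) and `n_missing` (sessions without a
#'   qualifying peak).
#' @export
validate_iapf <- function(dir, channel = "Pz", condition = "EC",
                          det_cfg = detector_config(), preprocess = TRUE) {
  sess <- .session_results(dir, channel, det_cfg, preprocess)
  sess <- sess[vapply(sess, function(s) s$condition == condition, TRUE)]
  obs <- do.call(rbind, lapply(sess, function(s) {
    r <- find_iapf(s$spectrum)
    data.frame(participant_id = s$participant_id, session = s$session,
               age = s$age, iapf = r$iapf, stringsAsFactors = FALSE)
  }))
  if (is.null(obs)) stop("no ", condition, " sessions found")
  fit <- fit_maturation(obs$age, obs$iapf)
  list(fit = fit, observations = obs, n_missing = sum(is.na(obs$iapf)))
}
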