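# Synthetic lifespan cohort generator. Emulates 2-minute eyes-open (EO) and
# eyes-closed (EC) resting-state recordings on the built-in 33-channel
# montage: 1/f Gaussian background, an age-dependent narrow-band alpha
# oscillation (posterior-dominant, stronger under EC), eye blinks written to
# the vertical EOG pair and propagated into frontal channels, and injectable
# EMG bursts, channel jumps, voltage swings and bridged electrode pairs, all
# with exact ground-truth masks.

#' Configuration of a synthetic cohort
#'
#' Defaults describe the recording protocol being emulated: 2-minute EO and
#' EC conditions at 500 Hz, a uniform lifespan age range, posterior alpha
#' with EC amplitude exceeding EO, and physiologically plausible artifact
#' rates.
#'
#' @param n_participants number of participants.
#' @param age_range (min, max) age in years; ages drawn uniformly.
#' @param seed integer seed driving all randomness.
#' @param duration_s recording length per condition, seconds.
#' @param srate sampling rate, Hz.
#' @param alpha_amp_uv alpha RMS amplitude at Pz under EC, uV.
#' @param alpha_ec_over_eo median EC/EO alpha amplitude ratio (> 1).
#' @param alpha_amp_sdlog between-subject log-SD of alpha amplitude.
#' @param ec_ratio_sdlog between-subject log-SD of the EC/EO ratio.
#' @param background_rms_uv RMS of the 1/f background on EEG channels, uV.
#' @param noise_exponent spectral exponent of the background (power ~ 1/f^x).
#' @param maturation_params named vector `(a, mu, sigma, c)` of the
#'   log-Gaussian iAPF-versus-age curve shared with [fit_maturation()].
#' @param iapf_noise_sd between-subject SD of the true alpha peak around the
#'   maturation curve, Hz.
#' @param artifact_rates list with elements `blinks_per_min` (EO rate; EC
#'   uses a tenth of it), `emg_per_min`, `jumps_per_recording`,
#'   `swings_per_recording`, `bridge_prob`.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 20,
                          age_range = c(5, 88),
                          seed = 1L,
                          duration_s = 120,
                          srate = 500,
                          alpha_amp_uv = 10,
                          alpha_ec_over_eo = 2,
                          alpha_amp_sdlog = 0.4,
                          ec_ratio_sdlog = 0.35,
                          background_rms_uv = 10,
                          noise_exponent = 1,
                          maturation_params = c(a = 2.2, mu = log(18),
                                                sigma = 1, c = 8),
                          iapf_noise_sd = 1,
                          artifact_rates = list(blinks_per_min = 18,
                                                emg_per_min = 2,
                                                jumps_per_recording = 2,
                                                swings_per_recording = 1,
                                                bridge_prob = 0.05)) {
  stopifnot(n_participants >= 1,
            length(age_range) == 2, age_range[1] > 0, age_range[2] < 120,
            age_range[1] < age_range[2],
            duration_s > 0, srate > 0,
            alpha_ec_over_eo > 1,
            maturation_params[["sigma"]] > 0,
            iapf_noise_sd >= 0)
  defaults <- list(blinks_per_min = 18, emg_per_min = 2,
                   jumps_per_recording = 2, swings_per_recording = 1,
                   bridge_prob = 0.05)
  artifact_rates <- utils::modifyList(defaults, artifact_rates)
  structure(list(n_participants = as.integer(n_participants),
                 age_range = as.numeric(age_range),
                 seed = as.integer(seed),
                 duration_s = duration_s, srate = srate,
                 alpha_amp_uv = alpha_amp_uv,
                 alpha_ec_over_eo = alpha_ec_over_eo,
                 alpha_amp_sdlog = alpha_amp_sdlog,
                 ec_ratio_sdlog = ec_ratio_sdlog,
                 background_rms_uv = background_rms_uv,
                 noise_exponent = noise_exponent,
                 maturation_params = maturation_params,
                 iapf_noise_sd = iapf_noise_sd,
                 artifact_rates = artifact_rates),
            class = "cohort_config")
}

#' Log-Gaussian maturation curve of the alpha peak frequency
#'
#' `iAPF(age) = c + a * exp(-(ln(age) - mu)^2 / (2 sigma^2))`. The curve
#' peaks at age `exp(mu)` with value `c + a` and flattens toward both ends of
#' the lifespan. Shared between the generator and [fit_maturation()].
#'
#' @param age age in years (> 0), vectorized.
#' @param params named vector or list with elements `a`, `mu`, `sigma`, `c`.
#' @return predicted alpha peak frequency in Hz.
#' @export
maturation_curve <- function(age, params) {
  p <- as.list(params)
  if (p$sigma <= 0) stop("sigma must be positive")
  if (any(age <= 0)) stop("age must be positive")
  p$c + p$a * exp(-(log(age) - p$mu)^2 / (2 * p$sigma^2))
}

# Gaussian noise with a 1/f^exponent power spectrum, unit RMS. The spectrum
# is drawn directly in the frequency domain (independent complex-Gaussian
# bins shaped by the target gain, Hermitian-symmetrized) so only one inverse
# FFT is needed per channel. Frequencies below f_floor share the f_floor
# gain so the variance stays finite.
.noise_one_over_f <- function(n, srate, exponent, f_floor = 0.5) {
  if (exponent == 0) {
    w <- stats::rnorm(n)
    return(w / stats::sd(w))
  }
  half <- n %/% 2  # n is even for all supported durations
  f <- (0:half) * srate / n
  gain <- pmax(f, f_floor)^(-exponent / 2)
  gain[1] <- 0
  X <- complex(real = stats::rnorm(half + 1),
               imaginary = stats::rnorm(half + 1)) * gain
  X[half + 1] <- Re(X[half + 1])  # Nyquist bin must be real
  full <- c(X, Conj(X[half:2]))
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  x / stats::sd(x)
}

# Slow positive amplitude-modulation envelope (around 1): Gaussian noise on
# a coarse 2-second grid, cubic-spline interpolated to the sample grid, so
# the modulation lives below ~0.25 Hz.
.slow_envelope <- function(n, srate, depth = 0.4) {
  step <- 2 * srate
  knots <- seq(1, n + step, by = step)
  s <- stats::spline(knots, stats::rnorm(length(knots)),
                     xout = seq_len(n))$y
  s <- s / max(stats::sd(s), 1e-12)
  pmax(1 + depth * s, 0.1)
}

# 400 ms biphasic blink template at a given sampling rate, unit peak.
.blink_template <- function(srate) {
  up <- seq(0, 0.3, by = 1 / srate)[-1]
  down <- seq(0, 0.1, by = 1 / srate)[-1]
  c(sin(pi * up / 0.3), -0.25 * sin(pi * down / 0.1))
}

# Draw the per-participant ground-truth parameters from the current RNG
# stream. True peaks are kept inside (7.2, 12.8) Hz so they sit strictly
# inside the 7-13 Hz search band.
.draw_participant_truth <- function(age, config) {
  iapf <- maturation_curve(age, config$maturation_params) +
    stats::rnorm(1, 0, config$iapf_noise_sd)
  list(true_iapf = min(max(iapf, 7.2), 12.8),
       alpha_rms_ec = config$alpha_amp_uv *
         exp(stats::rnorm(1, 0, config$alpha_amp_sdlog)),
       ec_ratio = max(1, config$alpha_ec_over_eo *
                        exp(stats::rnorm(1, 0, config$ec_ratio_sdlog))))
}

#' Simulate one resting-state recording with ground truth
#'
#' Deterministic given `(seed, age, condition, truth)`. The alpha component
#' is a slowly amplitude-modulated sinusoid at the participant's true peak
#' frequency, spatially weighted to be maximal at Pz; blinks are written to
#' the vertical EOG pair and propagated into frontal channels with
#' distance-decaying factors; EMG bursts, jumps, swings and bridged pairs are
#' injected at the configured rates and recorded in an exact ground-truth
#' event table.
#'
#' @param age participant age in years.
#' @param condition `"EO"` or `"EC"`.
#' @param config a [cohort_config()].
#' @param seed integer seed for this recording.
#' @param truth optional participant truth (as drawn internally); supply the
#'   same list to the EO and EC call so both conditions share the same alpha
#'   peak and amplitude.
#' @param channels optional subset of montage channel names to simulate
#'   (used for cheap single-channel oracle simulations).
#' @param participant_id,session identification stored in the recording.
#' @return list with elements `recording` (an `eeg_recording`) and `truth`
#'   (true iAPF, per-condition alpha RMS at Pz, event table with columns
#'   `kind`, `channel`, `start`, `end`, and `bridged_pair`).
#' @export
simulate_recording <- function(age, condition, config = cohort_config(),
                               seed = config$seed, truth = NULL,
                               channels = NULL,
                               participant_id = "20000001", session = 1L) {
  condition <- match.arg(condition, c("EO", "EC"))
  montage <- load_builtin_montage()
  if (is.null(channels)) channels <- montage$name
  channels <- canonical_channel_names(channels)
  stopifnot(all(channels %in% montage$name))
  srate <- config$srate
  n <- round(config$duration_s * srate)
  set.seed(seed)
  if (is.null(truth)) truth <- .draw_participant_truth(age, config)

  is_eeg <- montage$role[match(channels, montage$name)] == "EEG"
  dmat <- montage_distances(montage)

  # background
  data <- matrix(0, nrow = length(channels), ncol = n,
                 dimnames = list(channels, NULL))
  for (i in seq_along(channels)) {
    rms <- if (is_eeg[i]) config$background_rms_uv else 5
    data[i, ] <- rms * .noise_one_over_f(n, srate, config$noise_exponent)
  }

  # posterior alpha, maximal at Pz
  alpha_rms <- truth$alpha_rms_ec
  if (condition == "EO") alpha_rms <- alpha_rms / truth$ec_ratio
  if (alpha_rms > 0 && any(is_eeg)) {
    t <- (seq_len(n) - 1) / srate
    wave <- sin(2 * pi * truth$true_iapf * t + stats::runif(1, 0, 2 * pi)) *
      .slow_envelope(n, srate)
    wave <- wave / stats::sd(wave) * alpha_rms
    eeg_idx <- which(is_eeg)
    w <- exp(-dmat["Pz", channels[eeg_idx]] / 80)
    w[channels[eeg_idx] == "Pz"] <- 1
    data[eeg_idx, ] <- data[eeg_idx, ] + outer(w, wave)
  }

  ev_kind <- character(); ev_ch <- character()
  ev_start <- integer(); ev_end <- integer()
  add_event <- function(kind, channel, start, end) {
    i <- length(ev_kind) + 1L
    ev_kind[i] <<- kind; ev_ch[i] <<- channel
    ev_start[i] <<- as.integer(start); ev_end[i] <<- as.integer(end)
  }

  # blinks: 100 uV on VPVA, -20 uV counterpart on VNVB, frontal propagation
  blink_rate <- config$artifact_rates$blinks_per_min
  if (condition == "EC") blink_rate <- blink_rate / 10
  n_blinks <- stats::rpois(1, blink_rate * config$duration_s / 60)
  if (n_blinks > 0) {
    tmpl <- .blink_template(srate)
    front <- pmin(dmat["Fp1", ], dmat["Fp2", ])
    starts <- sort(round(stats::runif(n_blinks, srate,
                                      n - length(tmpl) - srate)))
    for (s0 in starts) {
      idx <- s0:(s0 + length(tmpl) - 1)
      veog_wave <- 120 * tmpl  # VPVA (+100) minus VNVB (-20)
      if ("VPVA" %in% channels) {
        data["VPVA", idx] <- data["VPVA", idx] + 100 * tmpl
        add_event("BLINK", "VPVA", s0, s0 + length(tmpl) - 1)
      }
      if ("VNVB" %in% channels) {
        data["VNVB", idx] <- data["VNVB", idx] - 20 * tmpl
        add_event("BLINK", "VNVB", s0, s0 + length(tmpl) - 1)
      }
      for (i in which(is_eeg)) {
        fac <- 0.5 * exp(-front[channels[i]] / 90)
        if (fac < 0.02) next
        data[i, idx] <- data[i, idx] + fac * veog_wave
        add_event("BLINK", channels[i], s0, s0 + length(tmpl) - 1)
      }
    }
  }

  eeg_names <- channels[is_eeg]

  # EMG bursts: band-limited (45-99 Hz) noise on one channel
  n_emg <- stats::rpois(1, config$artifact_rates$emg_per_min *
                          config$duration_s / 60)
  if (n_emg > 0 && length(eeg_names)) {
    bp <- signal::butter(4, c(45, 99) / (srate / 2), type = "pass")
    for (k in seq_len(n_emg)) {
      ch <- sample(eeg_names, 1)
      len <- round(stats::runif(1, 0.5, 1.5) * srate)
      s0 <- round(stats::runif(1, srate, n - len - srate))
      burst <- signal::filtfilt(bp, stats::rnorm(len + 200))[101:(100 + len)]
      burst <- burst / stats::sd(burst) * 40
      ramp <- round(0.02 * srate)
      env <- c(seq(0, 1, length.out = ramp),
               rep(1, len - 2 * ramp), seq(1, 0, length.out = ramp))
      idx <- s0:(s0 + len - 1)
      data[ch, idx] <- data[ch, idx] + burst * env
      add_event("EMG", ch, s0, s0 + len - 1)
    }
  }

  # sharp jumps: step up then back down after 0.2-0.8 s
  n_jump <- stats::rpois(1, config$artifact_rates$jumps_per_recording)
  if (n_jump > 0 && length(eeg_names)) {
    for (k in seq_len(n_jump)) {
      ch <- sample(eeg_names, 1)
      len <- round(stats::runif(1, 0.2, 0.8) * srate)
      s0 <- round(stats::runif(1, srate, n - len - srate))
      amp <- sample(c(-1, 1), 1) * stats::runif(1, 300, 500)
      idx <- s0:(s0 + len - 1)
      data[ch, idx] <- data[ch, idx] + amp
      add_event("JUMP", ch, s0, s0 + len - 1)
    }
  }

  # extreme voltage swings: large slow oscillation for 2-3 s
  n_swing <- stats::rpois(1, config$artifact_rates$swings_per_recording)
  if (n_swing > 0 && length(eeg_names)) {
    for (k in seq_len(n_swing)) {
      ch <- sample(eeg_names, 1)
      len <- round(stats::runif(1, 2, 3) * srate)
      s0 <- round(stats::runif(1, srate, n - len - srate))
      f <- stats::runif(1, 1, 2)
      tt <- (seq_len(len) - 1) / srate
      ramp <- round(0.02 * srate)
      env <- c(seq(0, 1, length.out = ramp),
               rep(1, len - 2 * ramp), seq(1, 0, length.out = ramp))
      idx <- s0:(s0 + len - 1)
      data[ch, idx] <- data[ch, idx] +
        450 * sin(2 * pi * f * tt + stats::runif(1, 0, 2 * pi)) * env
      add_event("SWING", ch, s0, s0 + len - 1)
    }
  }

  # electrode bridging: one channel becomes its nearest neighbour + <0.5 uV
  bridged_pair <- NULL
  if (stats::runif(1) < config$artifact_rates$bridge_prob &&
      length(eeg_names) >= 2) {
    a <- sample(eeg_names, 1)
    nb <- nearest_neighbors(a, montage, k = length(eeg_names) - 1)
    nb <- nb$name[nb$name %in% eeg_names][1]
    if (!is.na(nb)) {
      data[nb, ] <- data[a, ] + stats::rnorm(n, 0, 0.3)
      bridged_pair <- c(a, nb)
      add_event("BRIDGE", a, 1, n)
      add_event("BRIDGE", nb, 1, n)
    }
  }

  rec <- new_recording(data, channels, srate = srate,
                       participant_id = participant_id, session = session,
                       condition = condition, age = age)
  events <- data.frame(kind = ev_kind, channel = ev_ch, start = ev_start,
                       end = ev_end, stringsAsFactors = FALSE)
  list(recording = rec,
       truth = list(true_iapf = truth$true_iapf,
                    alpha_rms_ec = truth$alpha_rms_ec,
                    ec_ratio = truth$ec_ratio,
                    alpha_rms = alpha_rms,
                    events = events,
                    bridged_pair = bridged_pair))
}

#' Ground-truth artifact mask from an event table
#'
#' @param truth the `truth` element returned by [simulate_recording()].
#' @param channels channel names of the mask rows.
#' @param n_samples number of samples.
#' @param kinds event kinds to include (default all).
#' @return logical matrix `length(channels) x n_samples`.
#' @export
ground_truth_mask <- function(truth, channels, n_samples,
                              kinds = unique(truth$events$kind)) {
  m <- matrix(FALSE, length(channels), n_samples,
              dimnames = list(channels, NULL))
  ev <- truth$events[truth$events$kind %in% kinds, , drop = FALSE]
  for (i in seq_len(nrow(ev))) {
    if (!ev$channel[i] %in% channels) next
    m[ev$channel[i], ev$start[i]:ev$end[i]] <- TRUE
  }
  m
}

#' Brute-force measurement of the programmed EO/EC alpha effect
#'
#' Simulates the Pz channel of every participant of a (typically very large)
#' cohort under both conditions, computes the per-session 7-13 Hz band-mean
#' log power with the package's spectral conventions, and returns the
#' standardized paired effect of the EC-EO difference measured directly from
#' the difference vector. This is the generator-side ground truth against
#' which [eo_ec_contrast()] estimates on desk-scale cohorts are compared.
#'
#' @param config a [cohort_config()]; `config$n_participants` participants
#'   are simulated.
#' @param band frequency band, Hz.
#' @return list with `d` (mean/sd of the paired differences), `mean_diff`,
#'   `sd_diff`, `n`, and the per-participant `values` data frame.
#' @export
simulated_band_effect <- function(config, band = c(7, 13)) {
  parts <- cohort_participants(config)
  eo <- numeric(nrow(parts)); ec <- numeric(nrow(parts))
  for (i in seq_len(nrow(parts))) {
    p <- parts[i, ]
    truth <- list(true_iapf = p$true_iapf, alpha_rms_ec = p$alpha_rms_ec,
                  ec_ratio = p$ec_ratio)
    for (cond in c("EO", "EC")) {
      res <- simulate_recording(p$age, cond, config,
                                seed = recording_seed(config$seed, i, cond),
                                truth = truth, channels = "Pz",
                                participant_id = p$participant_id)
      v <- .session_band_from_signal(res$recording$data["Pz", ],
                                     config$srate, band = band)
      if (cond == "EO") eo[i] <- v else ec[i] <- v
    }
  }
  d <- ec - eo
  list(d = mean(d) / stats::sd(d), mean_diff = mean(d), sd_diff = stats::sd(d),
       n = length(d),
       values = data.frame(participant_id = parts$participant_id,
                           eo = eo, ec = ec, stringsAsFactors = FALSE))
}

#' Deterministic per-recording seed
#'
#' Derives the seed [simulate_cohort()] uses for one recording from the
#' cohort seed, the participant index and the condition, so single
#' recordings can be regenerated without rebuilding the cohort. Always below
#' 2^31.
#'
#' @param seed cohort seed.
#' @param participant_index 1-based participant index.
#' @param condition `"EO"` or `"EC"`.
#' @return integer seed.
#' @export
recording_seed <- function(seed, participant_index, condition) {
  cond_code <- if (condition == "EO") 1L else 2L
  as.integer((as.numeric(seed) * 1009 + participant_index * 7 + cond_code) %%
               2147483647)
}

#' Draw the participant-level truth of a cohort
#'
#' Ages uniform over `age_range`, ids sequential 8-digit codes, genders
#' balanced; per-participant alpha peak, amplitude and EC/EO ratio drawn from
#' the configured population model. Everything is a deterministic function of
#' `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return data frame with one row per participant: `participant_id`, `age`,
#'   `gender`, `true_iapf`, `alpha_rms_ec`, `ec_ratio`.
#' @export
cohort_participants <- function(config) {
  set.seed(config$seed)
  n <- config$n_participants
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  gender <- sample(c("F", "M"), n, replace = TRUE)
  rows <- lapply(seq_len(n), function(i) {
    tr <- .draw_participant_truth(age[i], config)
    data.frame(participant_id = sprintf("%08d", 20000000 + i),
               age = age[i], gender = gender[i],
               true_iapf = tr$true_iapf, alpha_rms_ec = tr$alpha_rms_ec,
               ec_ratio = tr$ec_ratio, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate a cohort, optionally writing it in the dataset layout
#'
#' One EO and one EC recording per participant. When `dir` is given, the
#' recordings are written as CSV derivatives under
#' `sub-<id>/ses-1/eeg/<id>-1.<COND>.csv`, together with `participants.tsv`
#' and a JSON ground-truth manifest. Per-recording seeds are derived from
#' `(config$seed, participant, condition)` so any single recording can be
#' regenerated with [simulate_recording()].
#'
#' @param config a [cohort_config()].
#' @param dir optional output directory.
#' @param keep_data if TRUE, recordings and truths are also returned in
#'   memory (use only for small cohorts).
#' @param callback optional `function(result, participant_index)` called on
#'   each simulated recording (streaming access for large cohorts).
#' @return list with `config`, `participants` (see [cohort_participants()]),
#'   and when `keep_data` is TRUE, `recordings` and `truths`, each a list
#'   named by entry name.
#' @export
simulate_cohort <- function(config = cohort_config(), dir = NULL,
                            keep_data = is.null(dir) && is.null(callback),
                            callback = NULL) {
  parts <- cohort_participants(config)
  recordings <- list()
  truths <- list()
  if (!is.null(dir)) dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(parts))) {
    p <- parts[i, ]
    truth <- list(true_iapf = p$true_iapf, alpha_rms_ec = p$alpha_rms_ec,
                  ec_ratio = p$ec_ratio)
    for (cond in c("EO", "EC")) {
      res <- simulate_recording(p$age, cond, config,
                                seed = recording_seed(config$seed, i, cond),
                                truth = truth,
                                participant_id = p$participant_id,
                                session = 1L)
      entry <- format_entry_name(p$participant_id, 1L, cond)
      if (!is.null(dir)) {
        eegdir <- file.path(dir, paste0("sub-", p$participant_id), "ses-1", "eeg")
        write_csv_derivative(res$recording, eegdir, base = entry)
      }
      if (keep_data) {
        recordings[[entry]] <- res$recording
        truths[[entry]] <- res$truth
      }
      if (!is.null(callback)) callback(res, i)
    }
  }
  if (!is.null(dir)) {
    tsv <- data.frame(participant_id = paste0("sub-", parts$participant_id),
                      age = round(parts$age, 2), gender = parts$gender,
                      indication = "SYNTHETIC")
    utils::write.table(tsv, file.path(dir, "participants.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    manifest <- list(seed = config$seed,
                     n_participants = config$n_participants,
                     participants = parts)
    jsonlite::write_json(manifest, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out <- list(config = config, participants = parts)
  if (keep_data) {
    out$recordings <- recordings
    out$truths <- truths
  }
  invisible(out)
}
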