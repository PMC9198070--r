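test_that("maturation curve follows its closed form", {
  p <- c(a = 2.2, mu = log(18), sigma = 1, c = 8)
  expect_equal(maturation_curve(18, p), 10.2)          # maximum: c + a
  expect_equal(maturation_curve(unname(exp(p["mu"])), p),
               unname(p["c"] + p["a"]))
  expect_equal(maturation_curve(c(5, 40, 88), c(a = 0, mu = 1, sigma = 2, c = 9.5)),
               rep(9.5, 3))                             # flat when a = 0
  # direct evaluation at the lifespan extremes
  for (age in c(5, 88)) {
    expect_equal(maturation_curve(age, p),
                 8 + 2.2 * exp(-(log(age) - log(18))^2 / 2))
  }
  expect_error(maturation_curve(0, p), "positive")
  expect_error(maturation_curve(-3, p), "positive")
  expect_error(maturation_curve(10, c(a = 1, mu = 1, sigma = 0, c = 8)),
               "sigma")
})

test_that("simulation is deterministic given the seed", {
  cfg <- cohort_config(n_participants = 1, duration_s = 12, seed = 3)
  a <- simulate_recording(30, "EO", cfg, seed = 99)
  b <- simulate_recording(30, "EO", cfg, seed = 99)
  expect_identical(a$recording$data, b$recording$data)
  expect_identical(a$truth$events, b$truth$events)
  c <- simulate_recording(30, "EO", cfg, seed = 100)
  expect_false(identical(a$recording$data, c$recording$data))
})

test_that("zero rates and zero alpha give a pure background record", {
  cfg <- clean_config(n_participants = 1, duration_s = 12, seed = 3,
                      alpha_amp_uv = 0)
  res <- simulate_recording(30, "EC", cfg, seed = 5,
                            truth = list(true_iapf = 10, alpha_rms_ec = 0,
                                         ec_ratio = 2))
  expect_equal(nrow(res$truth$events), 0)
  gt <- ground_truth_mask(res$truth, res$recording$channels,
                          n_samples(res$recording))
  expect_false(any(gt))
  # background amplitude close to the configured RMS
  expect_equal(sd(res$recording$data["Pz", ]), 10, tolerance = 0.05)
})

test_that("eyes-closed alpha band power at Pz exceeds eyes-open", {
  cfg <- clean_config(n_participants = 1, duration_s = 30, seed = 3)
  truth <- list(true_iapf = 10, alpha_rms_ec = 10, ec_ratio = 2)
  # same seed: identical background, only the alpha amplitude differs
  ec <- simulate_recording(30, "EC", cfg, seed = 8, truth = truth,
                           channels = "Pz")
  eo <- simulate_recording(30, "EO", cfg, seed = 8, truth = truth,
                           channels = "Pz")
  bp <- function(r) session_band_value(r$recording, preprocess = "none")
  expect_gt(bp(ec), bp(eo))
})

test_that("ground-truth masks exactly cover the injected events", {
  cfg <- cohort_config(n_participants = 1, duration_s = 30, seed = 3,
                       artifact_rates = list(emg_per_min = 6,
                                             jumps_per_recording = 4,
                                             swings_per_recording = 2,
                                             bridge_prob = 1))
  res <- simulate_recording(40, "EO", cfg, seed = 21)
  ev <- res$truth$events
  expect_true(all(ev$kind %in% c("BLINK", "EMG", "JUMP", "SWING", "BRIDGE")))
  gt <- ground_truth_mask(res$truth, res$recording$channels,
                          n_samples(res$recording))
  for (i in seq_len(nrow(ev))) {
    expect_true(all(gt[ev$channel[i], ev$start[i]:ev$end[i]]))
  }
  expect_lte(sum(gt), sum(ev$end - ev$start + 1))
  expect_setequal(res$truth$bridged_pair,
                  unique(ev$channel[ev$kind == "BRIDGE"]))
})

test_that("the 1/f-corrected spectral maximum tracks the true alpha peak", {
  cfg <- clean_config(n_participants = 1, duration_s = 60, seed = 3)
  for (f0 in seq(7.2, 12.8, by = 0.8)) {
    truth <- list(true_iapf = f0, alpha_rms_ec = 12, ec_ratio = 2)
    res <- simulate_recording(30, "EC", cfg, seed = round(100 + 10 * f0),
                              truth = truth, channels = "Pz")
    seg <- segment_epochs(res$recording)
    sp <- session_spectrum(seg, "Pz")
    corrected <- sp$logpower - one_over_f_baseline(sp)
    in_band <- sp$freqs >= 7 & sp$freqs <= 13
    fmax <- sp$freqs[in_band][which.max(corrected[in_band])]
    expect_lte(abs(fmax - f0), 0.2 + 1e-9)
  }
})

test_that("noiseless cohorts reproduce the maturation parameters exactly", {
  cfg <- clean_config(n_participants = 50, seed = 7, iapf_noise_sd = 0)
  parts <- cohort_participants(cfg)
  expect_true(all(parts$age >= 5 & parts$age <= 88))
  fit <- fit_maturation(parts$age, parts$true_iapf)
  expect_equal(unname(fit$params), unname(cfg$maturation_params),
               tolerance = 1e-4)
  expect_gt(fit$r_squared, 1 - 1e-8)
})

test_that("written cohorts follow the dataset layout", {
  cfg <- clean_config(n_participants = 3, duration_s = 10, seed = 13)
  dir <- withr::local_tempdir()
  simulate_cohort(cfg, dir = dir)
  files <- list_condition_files(dir)
  expect_equal(nrow(files), 6)
  expect_setequal(files$condition, c("EO", "EC"))
  for (i in seq_len(nrow(files))) {
    parsed <- parse_entry_name(basename(files$path[i]))
    expect_equal(parsed$participant_id, files$participant_id[i])
    expect_true(grepl(paste0("sub-", parsed$participant_id), files$path[i]))
  }
  tab <- read_participants(file.path(dir, "participants.tsv"))
  expect_equal(nrow(tab), 3)
  expect_false(any(tab$replication_flag))
  manifest <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                                  simplifyVector = TRUE)
  expect_equal(nrow(manifest$participants), 3)
})

test_that("per-recording substreams make cohorts reproducible piecewise", {
  cfg <- clean_config(n_participants = 2, duration_s = 10, seed = 29)
  coh <- simulate_cohort(cfg, keep_data = TRUE)
  p2 <- coh$participants[2, ]
  redo <- simulate_recording(p2$age, "EC", cfg,
                             seed = recording_seed(cfg$seed, 2, "EC"),
                             truth = list(true_iapf = p2$true_iapf,
                                          alpha_rms_ec = p2$alpha_rms_ec,
                                          ec_ratio = p2$ec_ratio),
                             participant_id = p2$participant_id)
  entry <- paste0(p2$participant_id, "-1.EC")
  expect_identical(redo$recording$data, coh$recordings[[entry]]$data)
})
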