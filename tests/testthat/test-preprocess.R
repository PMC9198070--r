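test_that("bipolar EOG is the difference of the electrode pairs", {
  rec <- tiny_recording(duration_s = 2)
  rec$data["VPVA", ] <- 10
  rec$data["VNVB", ] <- -10
  rec$data["HOHL", ] <- rec$data["HNHR", ]
  eog <- compute_bipolar_eog(rec)
  expect_equal(eog$veog, rep(20, n_samples(rec)))
  expect_equal(eog$heog, rep(0, n_samples(rec)))

  rec2 <- tiny_recording(channels = c("Pz", "VPVA"), duration_s = 2)
  expect_error(compute_bipolar_eog(rec2), "VNVB.*HOHL|HOHL")
})

test_that("ocular regression removes exactly proportional contamination", {
  rec <- tiny_recording(duration_s = 4)
  veog <- rec$data["VPVA", ] - rec$data["VNVB", ]
  heog <- rec$data["HOHL", ] - rec$data["HNHR", ]
  rec$data["Fp1", ] <- 0.3 * veog        # pure ocular channel
  out <- gratton_correct(rec, veog, heog)
  expect_lt(max(abs(out$data["Fp1", ] - mean(out$data["Fp1", ]))), 1e-8)
  expect_equal(attr(out, "eog_coefficients")["Fp1", "veog"], 0.3,
               tolerance = 1e-6)
  # auxiliary channels pass through untouched
  expect_identical(out$data["VPVA", ], rec$data["VPVA", ])
})

test_that("zero-variance regressors are skipped with a warning", {
  rec <- tiny_recording(duration_s = 2)
  before <- rec$data
  expect_warning(out <- gratton_correct(rec, rep(0, n_samples(rec)),
                                        rep(0, n_samples(rec))),
                 "zero-variance")
  expect_equal(out$data, before)
})

test_that("blink contamination is removed from frontal channels", {
  cfg <- cohort_config(n_participants = 1, duration_s = 60, seed = 2,
                       artifact_rates = list(emg_per_min = 0,
                                             jumps_per_recording = 0,
                                             swings_per_recording = 0,
                                             bridge_prob = 0))
  res <- simulate_recording(30, "EO", cfg, seed = 17)
  rec <- res$recording
  eog <- compute_bipolar_eog(rec)
  expect_gt(abs(cor(rec$data["Fp1", ], eog$veog)), 0.6)
  out <- gratton_correct(rec, eog$veog, eog$heog)
  expect_lt(abs(cor(out$data["Fp1", ], eog$veog)), 0.1)
})

test_that("filtering demeans, passes alpha and notches line noise", {
  fs <- 500
  t <- (0:(20 * fs - 1)) / fs
  mk <- function(x) new_recording(matrix(x, 1), "Pz", srate = fs)
  mid <- (5 * fs):(15 * fs)  # avoid zero-phase edge transients

  out <- filter_recording(mk(sin(2 * pi * 10 * t) + 100))
  expect_lt(abs(mean(out$data[1, ])), 0.5)
  amp10 <- sqrt(2) * sd(out$data[1, mid])
  expect_equal(amp10, 1, tolerance = 0.05)

  out50 <- filter_recording(mk(sin(2 * pi * 50 * t)))
  att_db <- 20 * log10(sd(out50$data[1, mid]) / sd(sin(2 * pi * 50 * t)))
  expect_lt(att_db, -20)

  expect_error(filter_recording(mk(t[1:1000])), "10 s")
  # shape is preserved
  rec <- tiny_recording()
  expect_equal(dim(filter_recording(rec)$data), dim(rec$data))
})

test_that("injected steps are flagged as jumps in their windows", {
  rec <- tiny_recording(channels = c("Fp1", "Pz", "Oz"), duration_s = 12)
  rec$data["Pz", 3000] <- rec$data["Pz", 3000] + 200
  rec$data["Pz", 3001:3400] <- rec$data["Pz", 3001:3400] + 200
  mask <- detect_artifacts(rec)  # already "filtered" white noise fixture
  jumps <- mask_by_kind(mask, "JUMP")
  expect_true(all(jumps["Pz", 3001:3400]))
  expect_false(any(jumps["Fp1", ]))
})

test_that("bridged pairs carry BRIDGE provenance for the whole recording", {
  rec <- tiny_recording(channels = c("Fp1", "Fp2", "Pz", "Oz", "O1"),
                        duration_s = 12)
  set.seed(1)
  rec$data["O1", ] <- rec$data["Oz", ] + rnorm(n_samples(rec), 0, 0.3)
  mask <- detect_artifacts(rec)
  bridge <- mask$provenance[mask$provenance$kind == "BRIDGE", ]
  expect_setequal(bridge$channel, c("Oz", "O1"))
  expect_true(all(mask$flags["Oz", ]))
  expect_false(any(mask_by_kind(mask, "BRIDGE")["Pz", ]))
})

test_that("duplicated but unbridged channels are flagged as correlated", {
  rec <- tiny_recording(channels = c("Fp1", "Fp2", "Pz", "Oz"),
                        duration_s = 12)
  # perfectly correlated copy with a gain, so the difference variance is large
  rec$data["Fp2", ] <- 3 * rec$data["Fp1", ]
  mask <- detect_artifacts(rec)
  corr <- mask$provenance[mask$provenance$kind == "CORR", ]
  expect_setequal(corr$channel, c("Fp1", "Fp2"))
  expect_equal(nrow(mask$provenance[mask$provenance$kind == "BRIDGE", ]), 0)
})

test_that("clean recordings stay almost unflagged at default thresholds", {
  cfg <- clean_config(n_participants = 1, duration_s = 30, seed = 2)
  res <- simulate_recording(25, "EC", cfg, seed = 31)
  pp <- preprocess_recording(res$recording)
  montage <- load_builtin_montage()
  eeg <- res$recording$channels %in% montage$name[montage$role == "EEG"]
  expect_lt(mean(pp$mask$flags[eeg, ]), 0.05)
  expect_equal(pp$qc$n_epochs_retained, 6)  # 30 s / 5 s, nothing dropped
})

test_that("repair reproduces hand-computed inverse-distance averages", {
  # equidistant neighbours: equal weights
  m <- toy_montage(list(A = c(0, 0, 0), B = c(1, 0, 0), C = c(-0.5, sqrt(3)/2, 0),
                        D = c(-0.5, -sqrt(3)/2, 0)))
  n <- 1000
  rec <- new_recording(rbind(rnorm(n), 1, 2, 3), c("A", "B", "C", "D"),
                       srate = 500)
  flags <- matrix(FALSE, 4, n, dimnames = list(c("A", "B", "C", "D"), NULL))
  flags[1, 1:670] <- TRUE                     # 67% flagged
  out <- repair_channels(rec, manual_mask(flags), m)
  expect_equal(unname(out$recording$data["A", ]), rep(2, n), tolerance = 1e-10)
  expect_equal(sort(out$log$A$donors), c("B", "C", "D"))
  expect_equal(out$log$A$weights, rep(1/3, 3), tolerance = 1e-10)
  expect_false(any(out$mask$flags[1, ]))      # donors were clean

  # distances 1, 2, 2 with values 4, 1, 1: weights 0.5, 0.25, 0.25 -> 2.5
  m2 <- toy_montage(list(A = c(0, 0, 0), B = c(1, 0, 0), C = c(2, 0, 0),
                         D = c(0, 2, 0)))
  rec2 <- new_recording(rbind(0, 4, 1, 1), c("A", "B", "C", "D"), srate = 500)
  rec2$data <- rec2$data[, rep(1, n)]
  rownames(rec2$data) <- rec2$channels
  out2 <- repair_channels(rec2, manual_mask(flags), m2)
  expect_equal(unname(out2$recording$data["A", ]), rep(2.5, n),
               tolerance = 1e-10)
})

test_that("channels at or below the 66% boundary are left untouched", {
  m <- toy_montage(list(A = c(0, 0, 0), B = c(1, 0, 0), C = c(0, 1, 0),
                        D = c(0, 0, 1)))
  n <- 1000
  rec <- new_recording(rbind(rnorm(n), 1, 2, 3), c("A", "B", "C", "D"),
                       srate = 500)
  for (frac in c(0.5, 0.66)) {
    flags <- matrix(FALSE, 4, n, dimnames = list(rec$channels, NULL))
    flags[1, seq_len(round(frac * n))] <- TRUE
    out <- repair_channels(rec, manual_mask(flags), m)
    expect_identical(out$recording$data["A", ], rec$data["A", ])
    expect_equal(length(out$log), 0)
  }
})

test_that("repair recovers a channel constructed as its neighbours' average", {
  montage <- load_builtin_montage()
  rec <- tiny_recording(channels = c("Pz", "CPz", "P3", "P4", "POzlike" = "Oz"),
                        duration_s = 4)
  nb <- nearest_neighbors("Pz", montage, k = 26)
  donors <- nb$name[nb$name %in% rec$channels][1:4]
  dd <- nb$distance[match(donors, nb$name)]
  w <- (1 / dd) / sum(1 / dd)
  rec$data["Pz", ] <- as.vector(w %*% rec$data[donors, ])
  flags <- matrix(FALSE, nrow(rec$data), n_samples(rec),
                  dimnames = list(rec$channels, NULL))
  flags["Pz", 1:(0.7 * n_samples(rec))] <- TRUE
  out <- repair_channels(rec, manual_mask(flags), montage)
  expect_equal(out$recording$data["Pz", ], rec$data["Pz", ],
               tolerance = 1e-10)
})

test_that("channels without 3 clean neighbours are reported unrepairable", {
  m <- toy_montage(list(A = c(0, 0, 0), B = c(1, 0, 0), C = c(0, 1, 0),
                        D = c(0, 0, 1)))
  n <- 1000
  rec <- new_recording(matrix(rnorm(4 * n), 4), c("A", "B", "C", "D"),
                       srate = 500)
  flags <- matrix(FALSE, 4, n, dimnames = list(rec$channels, NULL))
  flags[1:2, 1:700] <- TRUE   # A bad, B bad -> only 2 clean donors for A
  out <- repair_channels(rec, manual_mask(flags), m)
  expect_setequal(out$unrepairable, c("A", "B"))
  expect_identical(out$recording$data, rec$data)
})

test_that("segmentation retains only fully clean 5-second epochs", {
  rec <- tiny_recording(channels = c("Fp1", "Pz"), duration_s = 25)
  flags <- matrix(FALSE, 2, n_samples(rec),
                  dimnames = list(rec$channels, NULL))
  seg <- segment_epochs(rec, manual_mask(flags))
  expect_equal(length(seg$epoch_indices), 5)        # 25 s / 5 s
  expect_equal(dim(seg$epochs), c(5, 2, 2500))

  flags["Pz", 7 * 500] <- TRUE                      # artifact at t = 7 s
  seg2 <- segment_epochs(rec, manual_mask(flags))
  expect_equal(seg2$epoch_indices, c(1, 3, 4, 5))   # epoch 2 (5-10 s) dropped

  # flags on an excluded (unrepairable) channel do not veto
  seg3 <- segment_epochs(rec, manual_mask(flags), exclude = "Pz")
  expect_equal(length(seg3$epoch_indices), 5)

  short <- tiny_recording(channels = c("Fp1", "Pz"), duration_s = 4.9)
  seg4 <- segment_epochs(short)
  expect_equal(length(seg4$epoch_indices), 0)
  expect_match(seg4$reason, "shorter")
})
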