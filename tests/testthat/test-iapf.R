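# Constructed spectra: log power = -log(f) baseline plus bumps specified in
# the corrected (detrended) domain, so the expected behaviour of both iAPF
# criteria can be computed by hand.
constructed_spectrum <- function(bumps = list(), scale_log = 5) {
  f <- seq(2, 45, by = 0.2)
  corrected <- rep(1, length(f))
  for (b in bumps) {
    corrected <- corrected + b$height * exp(-(f - b$freq)^2 / (2 * 0.15^2))
  }
  resteeg:::new_power_spectrum(f, scale_log - log(f) + log(corrected), 1L)
}

test_that("the aperiodic baseline recovers pure power laws", {
  sp <- constructed_spectrum()
  base <- one_over_f_baseline(sp)
  expect_equal(base, sp$logpower, tolerance = 1e-9)

  flat <- resteeg:::new_power_spectrum(seq(2, 45, by = 0.2),
                                       rep(2.5, 216), 1L)
  base_flat <- one_over_f_baseline(flat)
  expect_lt(diff(range(base_flat)), 1e-9)      # zero slope
  expect_error(one_over_f_baseline(
    resteeg:::new_power_spectrum(1:3, c(1, 2, 3), 1L)) , NA)
})

test_that("iAPF picks the dominant corrected peak inside 7-13 Hz", {
  sp <- constructed_spectrum(list(list(freq = 10.4, height = 9)))
  res <- find_iapf(sp)
  expect_equal(res$iapf, 10.4)

  none <- find_iapf(constructed_spectrum())
  expect_true(is.na(none$iapf))

  # secondary peak at 30% of the corrected maximum fails the 40% rule
  two <- constructed_spectrum(list(list(freq = 10.4, height = 9),
                                   list(freq = 8.0, height = 2)))
  # corrected heights: 10 at 10.4 Hz, 3 at 8 Hz -> 30% of the maximum
  expect_equal(find_iapf(two)$iapf, 10.4)
  # but it qualifies once the threshold admits it
  expect_equal(find_iapf(two, min_rel = 0.25)$iapf, 10.4)  # still the max
  sub <- find_iapf(constructed_spectrum(list(list(freq = 8.0, height = 2))))
  expect_equal(sub$iapf, 8.0)
})

test_that("peaks failing the neighbour-difference criterion are rejected", {
  # tiny absolute power: corrected ratio fine, raw neighbour gap < 0.05 uV^2
  sp <- constructed_spectrum(list(list(freq = 10.4, height = 9)),
                             scale_log = -15)
  expect_true(is.na(find_iapf(sp)$iapf))
  expect_error(find_iapf(resteeg:::new_power_spectrum(
    seq(8, 12, 0.2), rnorm(21), 1L)), "cover")
})

test_that("maturation fitting recovers noiseless parameters", {
  p <- c(a = 2.2, mu = log(18), sigma = 1, c = 8)
  age <- seq(5, 88, length.out = 50)
  fit <- fit_maturation(age, maturation_curve(age, p))
  expect_equal(unname(fit$params), unname(p), tolerance = 1e-4)
  expect_gt(fit$r_squared, 1 - 1e-8)
  expect_equal(fit$peak_age, 18, tolerance = 1e-3)
  expect_error(fit_maturation(age[1:5], maturation_curve(age[1:5], p)),
               "at least 10")
})

test_that("constant iAPF yields a flagged flat fit", {
  expect_warning(fit <- fit_maturation(seq(5, 80, length.out = 20),
                                       rep(10, 20)), "flat")
  expect_true(fit$flat)
  expect_equal(unname(fit$params["c"]), 10)
  expect_equal(fit$r_squared, 0)
})

test_that("the fit is equivariant under an offset of all observations", {
  set.seed(33)
  p <- c(a = 2.2, mu = log(18), sigma = 1, c = 8)
  age <- runif(120, 5, 88)
  iapf <- maturation_curve(age, p) + rnorm(120, 0, 0.4)
  f1 <- fit_maturation(age, iapf)
  f2 <- fit_maturation(age, iapf + 2.5)
  expect_equal(unname(f2$params["c"] - f1$params["c"]), 2.5, tolerance = 1e-4)
  expect_equal(f1$params[c("a", "mu", "sigma")],
               f2$params[c("a", "mu", "sigma")], tolerance = 1e-4)
})

test_that("R-squared matches the variance-ratio identity", {
  set.seed(34)
  p <- c(a = 2.2, mu = log(18), sigma = 1, c = 8)
  age <- runif(200, 5, 88)
  iapf <- maturation_curve(age, p) + rnorm(200, 0, 1)
  fit <- fit_maturation(age, iapf)
  expect_equal(fit$r_squared, 1 - var(fit$residuals) / var(iapf),
               tolerance = 1e-6)
  expect_equal(mean(fit$residuals), 0, tolerance = 1e-6)
  expect_lte(fit$r_squared, 1)
  expect_equal(length(fit$residuals), 200)
})

test_that("residual normality behaves on normal, bimodal and degenerate input", {
  set.seed(35)
  normal <- residual_normality(rnorm(5000))
  expect_gt(normal$shapiro_stat, 0.99)

  bimodal <- residual_normality(c(rnorm(2500, -3, 0.3), rnorm(2500, 3, 0.3)))
  expect_lt(bimodal$shapiro_stat, 0.95)
  expect_lt(bimodal$shapiro_stat, normal$shapiro_stat)

  deg <- residual_normality(rep(1, 10))
  expect_true(deg$degenerate)
  expect_true(is.na(deg$shapiro_stat))
  expect_error(residual_normality(c(0.1, 0.2)), "3 residuals")
})

test_that("lifespan cohorts produce a rising-then-declining fitted curve", {
  cfg <- clean_config(n_participants = 400, seed = 44, iapf_noise_sd = 1)
  parts <- cohort_participants(cfg)
  fit <- fit_maturation(parts$age, parts$true_iapf)
  young <- maturation_curve(seq(5, 18, by = 1), fit$params)
  old <- maturation_curve(seq(30, 88, by = 2), fit$params)
  expect_true(all(diff(young) > 0))
  expect_true(all(diff(old) <= 0))
})
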