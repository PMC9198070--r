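# Individual alpha peak frequency (iAPF) detection and the log-Gaussian
# lifespan maturation model.

#' Aperiodic 1/f baseline of a log-power spectrum
#'
#' Straight line fitted to log power versus log frequency over the whole
#' 2-45 Hz grid, excluding 6-14 Hz so the alpha bump does not bias the
#' aperiodic slope; evaluated back on the full grid.
#'
#' @param spec a `power_spectrum`.
#' @param exclude_band band excluded from the fit, Hz.
#' @return numeric vector of baseline log power per grid frequency.
#' @export
one_over_f_baseline <- function(spec, exclude_band = c(6, 14)) {
  if (any(!is.finite(spec$logpower))) stop("non-finite spectrum")
  keep <- spec$freqs < exclude_band[1] | spec$freqs > exclude_band[2]
  fit <- stats::lm.fit(cbind(1, log(spec$freqs[keep])), spec$logpower[keep])
  unname(cbind(1, log(spec$freqs)) %*% fit$coefficients)[, 1]
}

#' Individual alpha peak frequency of a spectrum
#'
#' Local maxima of the raw power within 7-13 Hz are screened with two
#' criteria: (i) the 1/f-corrected power (baseline-subtracted log power,
#' exponentiated) must reach at least `min_rel` of the maximum corrected
#' power in the band, and (ii) the raw power must exceed both neighbouring
#' grid frequencies by at least `min_neighbor_diff_uv2`. Among qualifying
#' candidates the one with maximal corrected power is the iAPF. When no
#' candidate qualifies the result is missing (`NA`), not an error.
#'
#' @param spec a `power_spectrum` covering at least 7-13 Hz at 0.2 Hz
#'   resolution.
#' @param band search band, Hz.
#' @param min_rel corrected-power ratio criterion (default 0.40).
#' @param min_neighbor_diff_uv2 raw-power prominence over the two adjacent
#'   grid points, uV^2.
#' @return list of class `iapf_result`: `iapf` (Hz or NA), `peak_logpower`,
#'   `corrected_peak_power`.
#' @export
find_iapf <- function(spec, band = c(7, 13), min_rel = 0.40,
                      min_neighbor_diff_uv2 = 0.05) {
  f <- spec$freqs
  if (min(f) > band[1] || max(f) < band[2]) {
    stop("spectrum grid does not cover the search band")
  }
  power <- exp(spec$logpower)
  corrected <- exp(spec$logpower - one_over_f_baseline(spec))
  in_band <- which(f >= band[1] - 1e-9 & f <= band[2] + 1e-9)

  miss <- structure(list(iapf = NA_real_, peak_logpower = NA_real_,
                         corrected_peak_power = NA_real_),
                    class = "iapf_result")
  interior <- in_band[in_band > 1 & in_band < length(f)]
  is_local_max <- power[interior] > power[interior - 1] &
    power[interior] > power[interior + 1]
  cand <- interior[is_local_max]
  if (!length(cand)) return(miss)

  max_corr <- max(corrected[in_band])
  ok <- corrected[cand] >= min_rel * max_corr &
    power[cand] - power[cand - 1] >= min_neighbor_diff_uv2 &
    power[cand] - power[cand + 1] >= min_neighbor_diff_uv2
  cand <- cand[ok]
  if (!length(cand)) return(miss)

  best <- cand[which.max(corrected[cand])]
  structure(list(iapf = f[best], peak_logpower = spec$logpower[best],
                 corrected_peak_power = corrected[best]),
            class = "iapf_result")
}

#' @export
print.iapf_result <- function(x, ...) {
  if (is.na(x$iapf)) cat("<iapf_result> no qualifying alpha peak\n")
  else cat(sprintf("<iapf_result> iAPF = %.1f Hz (corrected peak power %.3g)\n",
                   x$iapf, x$corrected_peak_power))
  invisible(x)
}

#' Fit the log-Gaussian maturation curve to (age, iAPF) observations
#'
#' Nonlinear least squares of [maturation_curve()] with multi-start over the
#' peak-age parameter (`mu` started at ln 10, ln 18 and ln 30; the objective
#' is multi-modal in `mu`), keeping the solution with the smallest residual
#' sum of squares. Observations with missing iAPF are excluded. Residual
#' normality is summarized with a Shapiro-Wilk test.
#'
#' @param age,iapf numeric vectors of ages (years) and alpha peak
#'   frequencies (Hz); `NA` iAPFs are dropped.
#' @param min_obs minimal number of complete observations.
#' @return list of class `maturation_fit`: `params` (named `a`, `mu`,
#'   `sigma`, `c`), `r_squared`, `fitted`, `residuals`, `residual_mean`,
#'   `residual_sd`, `shapiro_stat`, `shapiro_p`, `n`, `peak_age`
#'   (`exp(mu)`), `flat` (TRUE when the data carried no age signal).
#' @export
fit_maturation <- function(age, iapf, min_obs = 10) {
  keep <- is.finite(age) & is.finite(iapf)
  age <- age[keep]; iapf <- iapf[keep]
  if (length(age) < min_obs) {
    stop("need at least ", min_obs, " complete (age, iapf) observations, got ",
         length(age))
  }
  if (any(age <= 0)) stop("ages must be positive")

  if (stats::sd(iapf) < 1e-10) {
    warning("iAPF carries no variance; returning a flat curve")
    params <- c(a = 0, mu = log(18), sigma = 1, c = mean(iapf))
    return(.finish_maturation_fit(age, iapf, params, flat = TRUE))
  }

  df <- data.frame(age = age, iapf = iapf)
  c0 <- unname(stats::quantile(iapf, 0.05))
  a0 <- max(diff(range(iapf)), 0.1)
  best <- NULL
  errors <- character()
  for (mu0 in log(c(10, 18, 30))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        iapf ~ c + a * exp(-(log(age) - mu)^2 / (2 * sigma^2)),
        data = df,
        start = list(a = a0, mu = mu0, sigma = 0.7, c = c0),
        lower = c(a = 0, mu = log(1), sigma = 0.05, c = 0),
        upper = c(a = 20, mu = log(120), sigma = 10, c = 30),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) e)
    if (inherits(fit, "error")) {
      errors <- c(errors, conditionMessage(fit))
      next
    }
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) {
    stop("maturation fit failed to converge from any start: ",
         paste(unique(errors), collapse = "; "))
  }
  params <- stats::coef(best$fit)[c("a", "mu", "sigma", "c")]
  .finish_maturation_fit(age, iapf, params, flat = FALSE)
}

.finish_maturation_fit <- function(age, iapf, params, flat) {
  fitted <- maturation_curve(age, params)
  res <- iapf - fitted
  ss_tot <- sum((iapf - mean(iapf))^2)
  r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else 0
  sw <- if (length(res) >= 3 && length(res) <= 5000 && stats::sd(res) > 1e-12) {
    tryCatch(stats::shapiro.test(res), error = function(e) NULL)
  }
  structure(list(params = params, r_squared = r2, fitted = fitted,
                 residuals = res, residual_mean = mean(res),
                 residual_sd = stats::sd(res),
                 shapiro_stat = if (!is.null(sw)) unname(sw$statistic) else NA_real_,
                 shapiro_p = if (!is.null(sw)) sw$p.value else NA_real_,
                 n = length(res), peak_age = exp(unname(params["mu"])),
                 flat = flat),
            class = "maturation_fit")
}

#' @export
print.maturation_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<maturation_fit> n = %d: iAPF ~ %.2f + %.2f exp(-(ln age - %.2f)^2 / (2 * %.2f^2))\n",
    x$n, p["c"], p["a"], p["mu"], p["sigma"]))
  cat(sprintf("  peak age %.1f y, R^2 = %.3f, residuals %.3f +/- %.3f, Shapiro W = %.3f\n",
              x$peak_age, x$r_squared, x$residual_mean, x$residual_sd,
              x$shapiro_stat))
  invisible(x)
}

#' Residual normality summary of a maturation fit
#'
#' @param fit a `maturation_fit` or a numeric residual vector (>= 3 values).
#' @return list with `shapiro_stat`, `shapiro_p`, `residual_mean`,
#'   `residual_sd` and `degenerate` (TRUE for zero-variance residuals, whose
#'   Shapiro statistic is undefined).
#' @export
residual_normality <- function(fit) {
  res <- if (inherits(fit, "maturation_fit")) fit$residuals else as.numeric(fit)
  if (length(res) < 3) stop("need at least 3 residuals")
  if (stats::sd(res) < 1e-12) {
    return(list(shapiro_stat = NA_real_, shapiro_p = NA_real_,
                residual_mean = mean(res), residual_sd = stats::sd(res),
                degenerate = TRUE))
  }
  sw <- stats::shapiro.test(res)
  list(shapiro_stat = unname(sw$statistic), shapiro_p = sw$p.value,
       residual_mean = mean(res), residual_sd = stats::sd(res),
       degenerate = FALSE)
}
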