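# Hann-windowed FFT log-power spectra per 5-s epoch and the eyes-open /
# eyes-closed alpha attenuation contrast.

#' Two-sided FFT power spectrum of one epoch
#'
#' Power is `|X_k / N|^2` on the full FFT grid, so that (without windowing)
#' the sum over all bins equals the time-domain mean square (Parseval) and an
#' on-grid sinusoid of amplitude A gives `(A/2)^2` in each of its two bins.
#'
#' @param x numeric vector (one epoch of one channel).
#' @param srate sampling rate, Hz.
#' @param window `"hann"` (periodic Hann, coherent gain exactly 0.5) or
#'   `"rect"`.
#' @return list with `freqs` (full grid, Hz) and `power`.
#' @export
epoch_power_spectrum <- function(x, srate, window = c("hann", "rect")) {
  window <- match.arg(window)
  n <- length(x)
  w <- switch(window,
              hann = 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n),
              rect = rep(1, n))
  X <- stats::fft(x * w)
  list(freqs = (0:(n - 1)) * srate / n, power = Mod(X / n)^2)
}

# coherent gain of the analysis window (peak-amplitude scaling)
.window_gain <- function(window) if (window == "hann") 0.5 else 1

#' Log-power spectrum of a 5-second segment
#'
#' The segment is multiplied by a segment-length Hann window, Fourier
#' transformed, and the power restricted to the 2-45 Hz grid (0.2 Hz
#' resolution for 5 s at 500 Hz). The natural logarithm is taken after
#' adding a small declared floor so zero-power bins stay finite.
#'
#' @param x numeric vector, one epoch of one channel (2500 samples at 500 Hz).
#' @param srate sampling rate, Hz.
#' @param epoch_s required epoch duration, seconds.
#' @param fmin,fmax spectrum band edges, Hz (inclusive).
#' @param floor_uv2 power floor added before the log, uV^2.
#' @return object of class `power_spectrum`: list with `freqs`, `logpower`,
#'   `n_segments` (= 1) and `condition` (`NA`; set by the callers).
#' @export
segment_log_spectrum <- function(x, srate = 500, epoch_s = 5,
                                 fmin = 2, fmax = 45, floor_uv2 = 1e-12) {
  n_expected <- round(epoch_s * srate)
  if (length(x) != n_expected) {
    stop(sprintf("epoch has %d samples; expected %d (%g s at %g Hz)",
                 length(x), n_expected, epoch_s, srate))
  }
  ps <- epoch_power_spectrum(x, srate, "hann")
  sel <- ps$freqs >= fmin - 1e-9 & ps$freqs <= fmax + 1e-9
  new_power_spectrum(freqs = ps$freqs[sel],
                     logpower = log(ps$power[sel] + floor_uv2),
                     n_segments = 1L)
}

new_power_spectrum <- function(freqs, logpower, n_segments, condition = NA_character_) {
  stopifnot(length(freqs) == length(logpower), all(diff(freqs) > 0),
            all(is.finite(logpower)))
  structure(list(freqs = freqs, logpower = logpower,
                 n_segments = as.integer(n_segments), condition = condition),
            class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %g-%g Hz (%d bins, %.3g Hz resolution), %d segment(s)%s\n",
              min(x$freqs), max(x$freqs), length(x$freqs), diff(x$freqs[1:2]),
              x$n_segments,
              if (is.na(x$condition)) "" else paste0(", ", x$condition)))
  invisible(x)
}

#' Average spectra in the log domain
#'
#' Element-wise mean of the log-power vectors. Applied twice in the pipeline:
#' first over segments within a session, then over sessions within a
#' condition, so each session contributes equally regardless of its segment
#' count.
#'
#' @param spectra list of `power_spectrum` objects on identical grids.
#' @param condition optional condition tag for the result.
#' @return a `power_spectrum` with `n_segments = length(spectra)`.
#' @export
average_spectra <- function(spectra, condition = NA_character_) {
  stopifnot(length(spectra) >= 1)
  f <- spectra[[1]]$freqs
  for (s in spectra) {
    if (!isTRUE(all.equal(s$freqs, f))) stop("spectra on different grids")
  }
  lp <- rowMeans(vapply(spectra, function(s) s$logpower, f))
  new_power_spectrum(f, lp, length(spectra), condition)
}

#' Session-mean log power in a frequency band
#'
#' @param spec a `power_spectrum`.
#' @param band `(low, high)` in Hz, inclusive on both edges.
#' @return mean log power over the band's grid points.
#' @export
band_logpower <- function(spec, band = c(7, 13)) {
  sel <- spec$freqs >= band[1] - 1e-9 & spec$freqs <= band[2] + 1e-9
  if (!any(sel)) stop("band outside the spectrum grid")
  mean(spec$logpower[sel])
}

# Session band-mean log power straight from a single-channel signal:
# consecutive epochs as matrix columns, one batched FFT, Hann window and the
# same power scaling and log floor as segment_log_spectrum.
.session_band_from_signal <- function(x, srate, epoch_s = 5, band = c(7, 13),
                                      floor_uv2 = 1e-12) {
  len <- round(epoch_s * srate)
  n_ep <- length(x) %/% len
  if (n_ep < 1) return(NA_real_)
  X <- matrix(x[seq_len(n_ep * len)], nrow = len)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(len - 1)) / len)
  P <- Mod(stats::mvfft(X * w) / len)^2
  f <- (0:(len - 1)) * srate / len
  sel <- f >= band[1] - 1e-9 & f <= band[2] + 1e-9
  mean(log(P[sel, , drop = FALSE] + floor_uv2))
}

#' Recover the amplitude of a sinusoid from its windowed spectral peak
#'
#' Inverts the two-sided power scaling and the Hann coherent gain:
#' `A = 2 * sqrt(P_peak) / gain`.
#'
#' @param peak_power power at the spectral peak (uV^2, scale of
#'   [epoch_power_spectrum()]).
#' @param window window the spectrum was computed with.
#' @return amplitude (half peak-to-peak) in uV.
#' @export
recover_sine_amplitude <- function(peak_power, window = "hann") {
  2 * sqrt(peak_power) / .window_gain(window)
}

#' Paired eyes-open / eyes-closed band contrast
#'
#' Dependent-samples t-test and paired Cohen's d on per-session band-mean
#' log-power values: `d = mean(EC - EO) / sd(EC - EO)`. With all differences
#' exactly zero the degenerate null result `(t = 0, p = 1, d = 0)` is
#' returned; identical nonzero differences (zero variance) give a flagged
#' degenerate result rather than an infinite statistic.
#'
#' @param eo,ec numeric vectors of per-session band values, paired by
#'   position (same session in both conditions).
#' @param band the frequency band the values summarize (metadata only).
#' @return list of class `eoec_contrast`: `t`, `p`, `d`, `n`, `mean_diff`,
#'   `band`, `degenerate`.
#' @export
eo_ec_contrast <- function(eo, ec, band = c(7, 13)) {
  stopifnot(length(eo) == length(ec))
  if (length(eo) < 3) stop("need at least 3 paired sessions for inference")
  d <- ec - eo
  sdd <- stats::sd(d)
  if (sdd < 1e-12) {
    if (all(abs(d) < 1e-12)) {
      res <- list(t = 0, p = 1, d = 0, n = length(d), mean_diff = 0,
                  band = band, degenerate = FALSE)
    } else {
      res <- list(t = sign(mean(d)) * Inf, p = NA_real_, d = NA_real_,
                  n = length(d), mean_diff = mean(d), band = band,
                  degenerate = TRUE)
    }
  } else {
    tt <- stats::t.test(ec, eo, paired = TRUE)
    res <- list(t = unname(tt$statistic), p = tt$p.value,
                d = mean(d) / sdd, n = length(d), mean_diff = mean(d),
                band = band, degenerate = FALSE)
  }
  structure(res, class = "eoec_contrast")
}

#' @export
print.eoec_contrast <- function(x, ...) {
  cat(sprintf(
    "<eoec_contrast> %g-%g Hz, n = %d pairs: t = %.3f, p = %.3g, d = %.3f%s\n",
    x$band[1], x$band[2], x$n, x$t, x$p, x$d,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}
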