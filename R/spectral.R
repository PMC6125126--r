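#' Complex Morlet time-frequency decomposition
#'
#' Continuous wavelet transform of a waveform (typically the pip-averaged
#' evoked response) using complex Morlet wavelets in the bandwidth/centre
#' frequency parameterization: the mother wavelet is
#' `(pi*fb)^(-1/2) * exp(2i*pi*fc*t) * exp(-t^2/fb)` with bandwidth `fb = 2`
#' and centre frequency `fc = 1` Hz. A wavelet analysing frequency `f` uses
#' scale `a = fc/f`; kernels are L1-normalized (`psi(t/a)/a`), so a unit
#' sinusoid produces the same modulus at every frequency and the power ridge
#' sits at the sinusoid frequency without scale bias. The transform is
#' evaluated in the frequency domain, where the scaled wavelet is
#' `exp(-pi^2 * fb * (a*f - fc)^2)`.
#'
#' Edges are handled by reflecting the waveform by one wavelet support
#' (three envelope standard deviations of the lowest-frequency wavelet) on
#' each side before transforming; the cone of influence is not masked.
#' Power is `|W|^2` expressed in decibels with a floor of `1e-12` before the
#' logarithm.
#'
#' @param waveform Numeric vector (microvolts), or an `evoked_response`.
#' @param rate Sampling rate in Hz (taken from the evoked response when one
#'   is supplied).
#' @param freqs Analysis frequency grid in Hz (default 2-100 Hz in 0.1 Hz
#'   steps); all frequencies must be below the Nyquist frequency.
#' @param fb,fc Morlet bandwidth parameter and centre frequency (Hz).
#' @param time_ms Time axis of the waveform in ms; defaults to the evoked
#'   response axis or to samples starting at 0.
#' @return Object of class `tfmap`: `power` (frequency x time, dB),
#'   `freq_hz`, `time_ms`, and the wavelet parameters. `normalized` is
#'   `FALSE` until [zscore_baseline()] is applied.
#' @export
morlet_tfr <- function(waveform, rate = NULL, freqs = seq(2, 100, by = 0.1),
                       fb = 2, fc = 1, time_ms = NULL) {
  if (inherits(waveform, "evoked_response")) {
    time_ms <- time_ms %||% waveform$time_ms
    waveform <- waveform$waveform
  }
  if (is.null(rate)) {
    if (is.null(time_ms)) stop("rate is required")
    rate <- 1000 / mean(diff(time_ms))
  }
  if (is.null(time_ms)) time_ms <- (seq_along(waveform) - 1) / rate * 1000
  if (max(freqs) >= rate / 2) stop("analysis frequency at or above Nyquist")
  n <- length(waveform)
  # wavelet support at the lowest analysis frequency: 3 envelope SDs,
  # sd_t = a * sqrt(fb / 2)
  a_max <- fc / min(freqs)
  pad <- ceiling(3 * a_max * sqrt(fb / 2) * rate)
  if (n < 2) stop("waveform shorter than the longest wavelet support")
  ext <- extend_reflect(waveform, pad)
  nfft <- stats::nextn(length(ext), 2)
  ext <- c(ext, numeric(nfft - length(ext)))
  X <- stats::fft(ext)
  fbin <- fft_bin_freqs(nfft, rate)
  power <- matrix(NA_real_, nrow = length(freqs), ncol = n)
  take <- pad + seq_len(n)
  for (k in seq_along(freqs)) {
    a <- fc / freqs[k]
    H <- exp(-pi^2 * fb * (a * fbin - fc)^2)
    w <- stats::fft(X * H, inverse = TRUE) / nfft
    power[k, ] <- Mod(w[take])^2
  }
  power <- 10 * log10(pmax(power, 1e-12))
  structure(list(power = power, freq_hz = freqs, time_ms = time_ms,
                 fb = fb, fc = fc, rate = rate, normalized = FALSE),
            class = "tfmap")
}

#' Z-score a time-frequency map and subtract the pre-stimulus baseline
#'
#' Each frequency row of the dB power map is z-scored across the full time
#' span of the epoch, then the mean of the z-scored row over the baseline
#' window (default -200 to 0 ms, half-open at 0) is subtracted from the
#' whole row. After the z-step (before baseline subtraction) every row has
#' mean 0 and SD 1 over the epoch; the z-scored map is invariant to overall
#' signal gain.
#'
#' @param tfmap A `tfmap` from [morlet_tfr()].
#' @param baseline_ms Baseline window in ms relative to pip onset.
#' @return The normalized `tfmap` (power now in z units).
#' @export
zscore_baseline <- function(tfmap, baseline_ms = c(-200, 0)) {
  stopifnot(inherits(tfmap, "tfmap"))
  t <- tfmap$time_ms
  bl <- t >= baseline_ms[1] & t < baseline_ms[2]
  if (!any(bl)) stop("baseline window lies outside the time axis")
  p <- tfmap$power
  mu <- rowMeans(p)
  sdv <- apply(p, 1, stats::sd)
  bad <- which(sdv == 0)
  if (length(bad)) {
    stop(sprintf("zero variance in frequency row(s) %s (%.1f Hz ...)",
                 paste(utils::head(bad, 3), collapse = ","),
                 tfmap$freq_hz[bad[1]]))
  }
  z <- (p - mu) / sdv
  z <- z - rowMeans(z[, bl, drop = FALSE])
  tfmap$power <- z
  tfmap$normalized <- TRUE
  tfmap$baseline_ms <- baseline_ms
  tfmap
}

#' Evoked theta power from a normalized time-frequency map
#'
#' Mean of the z-scored, baseline-subtracted power over the evoked window
#' (default 0-250 ms from pip onset) and the theta band (2-12 Hz).
#'
#' @param tfmap A normalized `tfmap` from [zscore_baseline()].
#' @param window_ms Evoked time window in ms (half-open at the upper edge).
#' @param band Frequency band in Hz (closed interval).
#' @return Mean power (z units) over the window-band submatrix.
#' @export
evoked_theta_power <- function(tfmap, window_ms = c(0, 250), band = c(2, 12)) {
  stopifnot(inherits(tfmap, "tfmap"))
  if (!isTRUE(tfmap$normalized)) {
    warning("tfmap has not been z-scored/baseline-subtracted")
  }
  ti <- tfmap$time_ms >= window_ms[1] & tfmap$time_ms < window_ms[2]
  fi <- tfmap$freq_hz >= band[1] & tfmap$freq_hz <= band[2]
  if (!any(ti) || !any(fi)) {
    stop("tfmap axes do not cover the requested window/band")
  }
  mean(tfmap$power[fi, ti])
}

#' @export
print.tfmap <- function(x, ...) {
  cat(sprintf("<tfmap> %d freqs (%g-%g Hz) x %d times (%g..%g ms), %s\n",
              length(x$freq_hz), min(x$freq_hz), max(x$freq_hz),
              length(x$time_ms), min(x$time_ms), max(x$time_ms),
              if (isTRUE(x$normalized)) "z-scored" else "dB"))
  invisible(x)
}

#' @export
plot.tfmap <- function(x, ...) {
  graphics::image(x$time_ms, x$freq_hz, t(x$power),
                  xlab = "time from pip onset (ms)", ylab = "frequency (Hz)",
                  main = if (isTRUE(x$normalized)) "evoked power (z)"
                         else "evoked power (dB)", ...)
  graphics::abline(v = 0, lty = 3, col = "white")
  invisible(x)
}
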