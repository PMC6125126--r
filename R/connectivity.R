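#' Magnitude-squared coherence by Welch's method
#'
#' Welch-averaged auto- and cross-spectra with 500 ms Hamming windows,
#' 1024-point FFT and 50% overlap; the coherence is
#' `|Sxy|^2 / (Sxx * Syy)` at every frequency bin, and the theta summary is
#' the mean coherence over 2-12 Hz.
#'
#' @param x,y Equal-length signal segments (microvolts).
#' @param rate Sampling rate in Hz.
#' @param window_s Welch window length in seconds.
#' @param nfft FFT length (windows are zero-padded to `nfft`).
#' @param overlap Fractional window overlap.
#' @param theta_band Band for the theta summary, Hz.
#' @return Object of class `coherence_spectrum` with `freq_hz`,
#'   `coherence`, `theta_coherence` and `n_windows`.
#' @export
coherence_spectrum <- function(x, y, rate, window_s = 0.5, nfft = 1024,
                               overlap = 0.5, theta_band = c(2, 12)) {
  n <- length(x)
  if (length(y) != n) stop("segments must have equal length")
  wlen <- round(window_s * rate)
  if (n < wlen) stop("segment shorter than one Welch window")
  if (wlen > nfft) stop("window longer than nfft")
  win <- signal::hamming(wlen)
  step <- max(1L, round(wlen * (1 - overlap)))
  starts <- seq(1L, n - wlen + 1L, by = step)
  sxx <- syy <- numeric(nfft)
  sxy <- complex(nfft)
  for (s in starts) {
    idx <- s:(s + wlen - 1L)
    xw <- c(x[idx] * win, numeric(nfft - wlen))
    yw <- c(y[idx] * win, numeric(nfft - wlen))
    X <- stats::fft(xw)
    Y <- stats::fft(yw)
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + X * Conj(Y)
  }
  k <- length(starts)
  half <- seq_len(nfft / 2 + 1)
  freq <- (half - 1) * rate / nfft
  coh <- Mod(sxy[half])^2 / (sxx[half] * syy[half])
  coh[!is.finite(coh)] <- NA_real_
  th <- freq >= theta_band[1] & freq <= theta_band[2]
  structure(list(freq_hz = freq, coherence = coh,
                 theta_coherence = mean(coh[th], na.rm = TRUE),
                 theta_band = theta_band, n_windows = k,
                 window_s = window_s, nfft = nfft, overlap = overlap),
            class = "coherence_spectrum")
}

#' @export
print.coherence_spectrum <- function(x, ...) {
  cat(sprintf("<coherence_spectrum> %d windows of %g s, nfft %d\n",
              x$n_windows, x$window_s, x$nfft))
  cat(sprintf("  theta (%g-%g Hz) coherence: %.3f\n", x$theta_band[1],
              x$theta_band[2], x$theta_coherence))
  invisible(x)
}

#' @export
plot.coherence_spectrum <- function(x, xlim = c(0, 50), ...) {
  graphics::plot(x$freq_hz, x$coherence, type = "l", xlim = xlim,
                 ylim = c(0, 1), xlab = "frequency (Hz)",
                 ylab = "magnitude-squared coherence", ...)
  graphics::abline(v = x$theta_band, lty = 3)
  invisible(x)
}

#' Demeaned theta-band amplitude envelope
#'
#' Zero-phase (forward-backward Butterworth) bandpass between 2 and 12 Hz,
#' followed by the analytic-signal modulus (instantaneous amplitude), with
#' the mean amplitude subtracted to remove the DC component.
#'
#' @param x Signal in microvolts.
#' @param rate Sampling rate in Hz.
#' @param band Passband in Hz; the upper edge must be below Nyquist.
#' @param order Butterworth design order.
#' @return Numeric envelope (zero mean).
#' @export
theta_envelope <- function(x, rate, band = c(2, 12), order = 4) {
  if (band[2] >= rate / 2) stop("band extends to or beyond Nyquist")
  if (length(x) < 3 * order * round(rate / band[1])) {
    stop("signal too short for the filter transient")
  }
  bf <- signal::butter(order, band / (rate / 2), type = "pass")
  xf <- signal::filtfilt(bf, x)
  env <- Mod(analytic_signal(xf))
  env - mean(env)
}

#' Normalized cross-correlation of two envelopes over short lags
#'
#' Pearson correlation at every integer-sample lag within `max_lag` seconds,
#' computed on the overlapping samples only. Positive lags mean the first
#' envelope (dmPFC by convention) leads the second (BLA).
#'
#' @param env_a,env_b Equal-length envelopes (from [theta_envelope()]).
#' @param rate Sampling rate in Hz.
#' @param max_lag Maximum lag in seconds.
#' @return List with `lag_s`, `r`, `peak_lag_s`, `peak_r`.
#' @export
envelope_xcorr <- function(env_a, env_b, rate, max_lag = 0.1) {
  n <- length(env_a)
  if (length(env_b) != n) stop("envelopes must have equal length")
  L <- round(max_lag * rate)
  if (L >= n / 2) stop("max_lag must be below half the segment duration")
  if (stats::sd(env_a) == 0 || stats::sd(env_b) == 0) {
    stop("zero-variance envelope")
  }
  cc <- xcorr_pearson_cpp(as.numeric(env_a), as.numeric(env_b), L)
  pk <- which.max(cc$r)
  list(lag_s = cc$lag / rate, r = cc$r,
       peak_lag_s = cc$lag[pk] / rate, peak_r = cc$r[pk])
}

#' Surrogate cross-correlation peaks from random time shifts
#'
#' Builds the chance distribution of cross-correlation peaks by shifting the
#' second envelope by a random amount between `shift_range` seconds (sign
#' randomized) and recording the peak correlation within `max_lag`, repeated
#' `n` times. The default edge policy is a plain (linear) shift that simply
#' cross-correlates the overlapping samples at the displaced alignment; a
#' circular shift, which preserves the overlap length but introduces a wrap
#' seam that measurably weakens the surrogate peaks (making the test fire
#' too often on independent signals), is available as `edges = "circular"`.
#'
#' @param env_a,env_b Envelopes as in [envelope_xcorr()].
#' @param rate Sampling rate in Hz.
#' @param n Number of surrogates.
#' @param shift_range Shift magnitude range in seconds.
#' @param max_lag Maximum lag in seconds.
#' @param seed Seed for the shift draws.
#' @param edges Shift edge policy, `"linear"` (default) or `"circular"`.
#' @return Numeric vector of `n` surrogate peak correlations.
#' @export
surrogate_peaks <- function(env_a, env_b, rate, n = 100,
                            shift_range = c(2, 5), max_lag = 0.1, seed = 1L,
                            edges = c("linear", "circular")) {
  edges <- match.arg(edges)
  if (n < 1) stop("need at least one surrogate")
  dur <- length(env_b) / rate
  if (dur <= 2 * shift_range[2]) {
    stop("segment too short for the surrogate shift range")
  }
  with_seed(seed, {
    u <- stats::runif(n, shift_range[1], shift_range[2])
    sgn <- sample(c(-1, 1), n, replace = TRUE)
    shifts <- as.integer(round(sgn * u * rate))
    if (edges == "linear") {
      surrogate_peaks_linear_cpp(as.numeric(env_a), as.numeric(env_b),
                                 round(max_lag * rate), shifts)
    } else {
      surrogate_peaks_cpp(as.numeric(env_a), as.numeric(env_b),
                          round(max_lag * rate), shifts)
    }
  })
}

#' Lead/lag between two regions from envelope cross-correlation
#'
#' For each analysis segment (a pair of theta envelopes, dmPFC first), the
#' cross-correlation peak lag and value are computed, along with `n_surrogates`
#' chance peaks from random 2-5 s circular shifts. A segment is significant
#' when its actual peak exceeds more than 95% of its own surrogate peaks;
#' the overall result is significant when the majority of segments are
#' (both, for the usual two-trial analysis). The summary lead/lag is
#' the centre of the maximal bin of the per-segment peak-lag histogram
#' (5 ms bins centred on zero lag); ties are broken towards the bin with the
#' larger total peak correlation.
#'
#' @param segments List of segments, each a list/pair
#'   `(dmPFC envelope, BLA envelope)`.
#' @param rate Sampling rate in Hz.
#' @param n_surrogates Surrogates per segment.
#' @param shift_range,max_lag As in [surrogate_peaks()].
#' @param bin_width_s Histogram bin width for the summary lag, seconds.
#' @param seed Seed for the surrogate shifts.
#' @return Object of class `lead_lag`: per-segment `peak_lag_s`, `peak_r`,
#'   `exceedance` and `segment_significant`, the surrogate peak matrix
#'   (segments x replicates), `summary_lag_s` and the overall `significant`
#'   flag.
#' @export
lead_lag <- function(segments, rate, n_surrogates = 100,
                     shift_range = c(2, 5), max_lag = 0.1,
                     bin_width_s = 0.005, seed = 1L) {
  if (length(segments) < 1) stop("need at least one segment")
  peaks <- numeric(length(segments))
  vals <- numeric(length(segments))
  sur <- matrix(NA_real_, nrow = length(segments), ncol = n_surrogates)
  for (i in seq_along(segments)) {
    sg <- segments[[i]]
    xc <- envelope_xcorr(sg[[1]], sg[[2]], rate, max_lag)
    peaks[i] <- xc$peak_lag_s
    vals[i] <- xc$peak_r
    sur[i, ] <- surrogate_peaks(sg[[1]], sg[[2]], rate, n = n_surrogates,
                                shift_range = shift_range, max_lag = max_lag,
                                seed = seed + i)
  }
  exceed <- vapply(seq_along(segments),
                   function(i) mean(vals[i] > sur[i, ]), numeric(1))
  seg_sig <- exceed > 0.95
  significant <- mean(seg_sig) > 0.5

  centers <- seq(-max_lag, max_lag, by = bin_width_s)
  bin <- vapply(peaks, function(p) which.min(abs(centers - p)), integer(1))
  counts <- tabulate(bin, nbins = length(centers))
  best <- which(counts == max(counts))
  if (length(best) > 1) {
    score <- vapply(best, function(bb) sum(vals[bin == bb]), numeric(1))
    best <- best[which.max(score)]
  }
  structure(list(peak_lag_s = peaks, peak_r = vals, surrogates = sur,
                 summary_lag_s = centers[best], significant = significant,
                 segment_significant = seg_sig, exceedance = exceed,
                 bin_width_s = bin_width_s,
                 n_surrogates = n_surrogates, rate = rate, seed = seed),
            class = "lead_lag")
}

#' Lead/lag for one recording at one timepoint
#'
#' Convenience wrapper: selects the timepoint's two analysis trials, takes
#' the theta envelopes of both channels over each 30 s CS window, and runs
#' [lead_lag()].
#'
#' @param recording A [session_recording()] with `dmPFC` and `BLA` channels.
#' @param timepoint As in [select_block_trials()].
#' @param band Theta band for the envelopes, Hz.
#' @param ... Passed to [lead_lag()].
#' @return A `lead_lag` object.
#' @export
lead_lag_session <- function(recording, timepoint, band = c(2, 12), ...) {
  trials <- select_block_trials(recording, timepoint)
  segs <- cs_envelope_segments(recording, trials, band)
  lead_lag(segs, rate = recording$rate, ...)
}

# Theta-envelope pairs (dmPFC, BLA) for the CS windows of the given trials.
# Envelopes are computed once on the continuous channels and sliced
# afterwards, so filter/Hilbert edge transients (which would appear at the
# same positions in both channels and mimic zero-lag coupling) never fall
# inside an analysis segment.
cs_envelope_segments <- function(recording, trials, band = c(2, 12)) {
  rate <- recording$rate
  dur <- if (!is.null(recording$design)) recording$design$tone_duration_s else 30
  env <- lapply(recording$channels[c("dmPFC", "BLA")], theta_envelope,
                rate = rate, band = band)
  lapply(trials, function(tr) {
    on <- recording$trials$tone_onset_s[recording$trials$trial_index == tr]
    idx <- (round(on * rate) + 1L):(round((on + dur) * rate))
    list(env$dmPFC[idx], env$BLA[idx])
  })
}

#' @export
print.lead_lag <- function(x, ...) {
  cat(sprintf("<lead_lag> %d segment(s), %d surrogates each\n",
              length(x$peak_lag_s), x$n_surrogates))
  cat(sprintf("  summary lag: %+.3f s (%s; segment exceedance %s)\n",
              x$summary_lag_s,
              if (x$significant) "significant" else "not significant",
              paste(sprintf("%.0f%%", 100 * x$exceedance), collapse = ", ")))
  cat(sprintf("  per-segment peak lags (s): %s\n",
              paste(sprintf("%+.3f", x$peak_lag_s), collapse = ", ")))
  invisible(x)
}

#' @export
plot.lead_lag <- function(x, ...) {
  graphics::hist(x$peak_lag_s, breaks = seq(-0.1 - x$bin_width_s / 2,
                                            0.1 + x$bin_width_s / 2,
                                            by = x$bin_width_s),
                 xlab = "peak lag (s, + = dmPFC leads)", main = "peak-lag distribution",
                 ...)
  graphics::abline(v = x$summary_lag_s, col = 2, lwd = 2)
  invisible(x)
}
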