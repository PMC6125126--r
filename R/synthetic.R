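#' Simulation parameters for the dual-region LFP generator
#'
#' Bundles the physical and statistical parameters of the synthetic
#' dmPFC/BLA recording: sampling rate, band limits of the recorded signal,
#' the band of the shared theta source, the fraction of BLA theta variance
#' shared with the dmPFC (`coupling`), the directional delay between the two
#' regions (`lag`, positive when the dmPFC leads the BLA), per-trial
#' per-region multipliers for ongoing/evoked theta (`region_theta_gain`),
#' per-trial per-region evoked-potential amplitudes in microvolts
#' (`aep_amplitude`, scored peak-minus-trough of the injected template), and
#' background-noise settings.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param band_limits Recording band in Hz; all generated power is confined
#'   to this band.
#' @param theta_source_band Band of the shared theta source in Hz; must lie
#'   inside the 2-12 Hz analysis band.
#' @param coupling Fraction (0-1) of BLA theta variance shared with dmPFC.
#' @param lag Delay in seconds applied to the shared source in the BLA
#'   channel; positive means the dmPFC leads. Must satisfy `abs(lag) < 2`.
#' @param region_theta_gain Per-trial evoked theta multiplier. A scalar, a
#'   vector recycled over trials, or a list with elements `dmPFC` and `BLA`
#'   each a scalar/vector over trials. Scales the pip-locked theta burst
#'   (the evoked theta); the ongoing theta source stays stationary so that
#'   baseline-referenced measures can recover the injected gain.
#' @param aep_amplitude Evoked-potential amplitude in microvolts (scored
#'   peak-trough of the injected template); same shapes as
#'   `region_theta_gain`.
#' @param theta_sd Standard deviation of the ongoing theta component, in
#'   microvolts, at gain 1.
#' @param noise_sd Standard deviation of the pink background noise in
#'   microvolts; must be positive.
#' @param pink_noise_exponent Spectral exponent of the background noise
#'   (power ~ 1/f^exponent).
#' @param theta_burst_uv Peak amplitude in microvolts, at gain 1, of the
#'   pip-locked theta burst that carries the evoked theta power.
#' @param seed Integer seed; together with the design it fully determines
#'   the simulated session.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(sampling_rate = 1000,
                       band_limits = c(1, 500),
                       theta_source_band = c(4, 10),
                       coupling = 0.9,
                       lag = 0.02,
                       region_theta_gain = 1,
                       aep_amplitude = 75,
                       theta_sd = 15,
                       noise_sd = 10,
                       pink_noise_exponent = 1,
                       theta_burst_uv = 8,
                       seed = 1L) {
  stopifnot(length(band_limits) == 2, band_limits[1] < band_limits[2],
            length(theta_source_band) == 2,
            theta_source_band[1] < theta_source_band[2])
  if (coupling < 0 || coupling > 1) stop("coupling must lie in [0, 1]")
  if (abs(lag) >= 2) stop("abs(lag) must be below 2 s")
  if (sampling_rate < 2 * band_limits[2]) {
    stop("sampling_rate must be at least twice the upper band limit")
  }
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("noise_sd must be non-negative")
  }
  structure(list(sampling_rate = sampling_rate, band_limits = band_limits,
                 theta_source_band = theta_source_band, coupling = coupling,
                 lag = lag, region_theta_gain = region_theta_gain,
                 aep_amplitude = aep_amplitude, theta_sd = theta_sd,
                 noise_sd = noise_sd,
                 pink_noise_exponent = pink_noise_exponent,
                 theta_burst_uv = theta_burst_uv, seed = as.integer(seed)),
            class = "sim_params")
}

#' Session design for the fear-conditioning protocol
#'
#' Describes one behavioural session: a train of 30-s CS tones, each made of
#' 30 pips of 100 ms at 1 Hz, separated by inter-trial intervals drawn
#' uniformly from 80-160 s (mean 120 s). Habituation sessions present 5
#' tones; fear-recall/extinction and extinction-recall sessions present 15.
#' The conditioning session co-terminates each tone with a 0.5 s foot shock
#' (0.7 mA, recorded as metadata only); its tone count is configurable and
#' has no default taken from the protocol.
#'
#' @param session_label One of `"context_habituation"`, `"tone_habituation"`,
#'   `"conditioning"`, `"fear_recall_extinction"`, `"extinction_recall"`.
#' @param n_tones Number of CS presentations. Defaults to 5 for tone
#'   habituation and 15 for the recall/extinction sessions; required for
#'   conditioning.
#' @param pips_per_tone,pip_rate,pip_duration_ms Pip train layout; the
#'   product `pips_per_tone / pip_rate` must equal `tone_duration_s`.
#' @param tone_duration_s CS duration in seconds.
#' @param iti_mean_s,iti_range_s Inter-trial interval mean and range in
#'   seconds; draws are uniform over the range.
#' @param pretone_s Seconds of recording before the first tone onset (must
#'   cover the 30 s pretone scoring window).
#' @param tail_s Seconds of recording after the last tone ends.
#' @param us_duration_s,us_amplitude_ma Foot-shock parameters (conditioning
#'   only; amplitude is metadata).
#' @return An object of class `session_design`.
#' @export
session_design <- function(session_label,
                           n_tones = NULL,
                           pips_per_tone = 30,
                           pip_rate = 1,
                           pip_duration_ms = 100,
                           tone_duration_s = 30,
                           iti_mean_s = 120,
                           iti_range_s = c(80, 160),
                           pretone_s = 45,
                           tail_s = 10,
                           us_duration_s = 0.5,
                           us_amplitude_ma = 0.7) {
  session_label <- match.arg(session_label, session_labels())
  if (is.null(n_tones)) {
    n_tones <- switch(session_label,
                      tone_habituation = 5L,
                      fear_recall_extinction = 15L,
                      extinction_recall = 15L,
                      stop("n_tones has no default for session '",
                           session_label, "'"))
  }
  if (abs(pips_per_tone / pip_rate - tone_duration_s) > 1e-9) {
    stop("pips_per_tone / pip_rate must equal tone_duration_s")
  }
  stopifnot(iti_range_s[1] <= iti_mean_s, iti_mean_s <= iti_range_s[2],
            pretone_s >= 30, n_tones >= 1)
  structure(list(session_label = session_label, n_tones = as.integer(n_tones),
                 pips_per_tone = as.integer(pips_per_tone),
                 pip_rate = pip_rate, pip_duration_ms = pip_duration_ms,
                 tone_duration_s = tone_duration_s, iti_mean_s = iti_mean_s,
                 iti_range_s = iti_range_s, pretone_s = pretone_s,
                 tail_s = tail_s, us_duration_s = us_duration_s,
                 us_amplitude_ma = us_amplitude_ma),
            class = "session_design")
}

session_labels <- function() {
  c("context_habituation", "tone_habituation", "conditioning",
    "fear_recall_extinction", "extinction_recall")
}

#' Build a smooth evoked-potential template
#'
#' The template is the sum of two Gaussian-windowed deflections: a positive
#' bump reaching `peak_uv` at `peak_latency_ms` followed by a negative bump
#' reaching `trough_uv` at `trough_latency_ms`. Coefficients are solved so
#' the waveform attains exactly the requested values at the two latencies;
#' the Gaussian widths are narrow enough that the template is effectively
#' zero at both ends.
#'
#' @param peak_uv,trough_uv Target values in microvolts at the peak and
#'   trough latencies (`trough_uv` is typically negative).
#' @param peak_latency_ms,trough_latency_ms Latencies in ms; must satisfy
#'   `peak_latency_ms < trough_latency_ms < duration_ms`.
#' @param duration_ms Template length in ms; must not exceed the pip period.
#' @param rate Sampling rate in Hz.
#' @return Numeric waveform sampled at `rate`, with attribute `time_s`.
#' @export
make_aep_template <- function(peak_uv, trough_uv,
                              peak_latency_ms = 15, trough_latency_ms = 30,
                              duration_ms = 100, rate = 1000) {
  vals <- c(peak_uv, trough_uv, peak_latency_ms, trough_latency_ms, duration_ms)
  if (any(!is.finite(vals))) stop("non-finite template parameter")
  if (!(peak_latency_ms < trough_latency_ms && trough_latency_ms < duration_ms)) {
    stop("latencies must satisfy peak < trough < duration")
  }
  t <- seq(0, duration_ms / 1000, by = 1 / rate)
  tp <- peak_latency_ms / 1000
  tt <- trough_latency_ms / 1000
  gap <- tt - tp
  s1 <- min(tp, gap) / 5
  s2 <- min(gap, duration_ms / 1000 - tt) / 5
  g1 <- exp(-(t - tp)^2 / (2 * s1^2))
  g2 <- exp(-(t - tt)^2 / (2 * s2^2))
  if (peak_uv == 0 && trough_uv == 0) {
    w <- numeric(length(t))
  } else {
    A <- rbind(c(1, exp(-gap^2 / (2 * s2^2))),
               c(exp(-gap^2 / (2 * s1^2)), 1))
    cf <- solve(A, c(peak_uv, trough_uv))
    w <- cf[1] * g1 + cf[2] * g2
  }
  attr(w, "time_s") <- t
  w
}

# Pip-locked theta burst carrying the evoked theta power: a Gaussian-windowed
# 6 Hz cosine over 0-250 ms, unit peak amplitude.
theta_burst_template <- function(rate, freq = 6, duration_s = 0.25) {
  t <- seq(0, duration_s, by = 1 / rate)
  mid <- duration_s / 2
  env <- exp(-(t - mid)^2 / (2 * (duration_s / 6)^2))
  w <- env * cos(2 * pi * freq * (t - mid))
  w / max(abs(w))
}

# Expand a per-trial, per-region parameter spec to an n_trials x 2 matrix
# with columns dmPFC, BLA.
expand_region_trial <- function(x, n_trials, what) {
  if (is.list(x)) {
    m <- cbind(dmPFC = rep_len(x$dmPFC %||% 1, n_trials),
               BLA = rep_len(x$BLA %||% 1, n_trials))
  } else {
    v <- rep_len(x, n_trials)
    m <- cbind(dmPFC = v, BLA = v)
  }
  if (any(!is.finite(m))) stop("non-finite ", what)
  m
}

#' Simulate one dual-region LFP session with known ground truth
#'
#' Generates a two-channel (dmPFC, BLA) recording following the session
#' design: a stationary shared band-limited Gaussian theta source with
#' configurable coupling and directional delay, plus, at every pip onset, an
#' evoked-potential template (scaled by the trial's AEP amplitude) and a
#' theta burst (scaled by the trial's theta gain), over pink background
#' noise confined to the recording band. The
#' returned recording carries a `ground_truth` element with every injected
#' per-trial value, the lag, the coupling and the seed.
#'
#' The BLA theta component is
#' `sqrt(coupling) * s(t - lag) + sqrt(1 - coupling) * p(t)` where `s` is the
#' shared source and `p` an independent source of equal variance, so BLA
#' theta variance is constant across coupling levels.
#'
#' @param design A [session_design()].
#' @param params A [sim_params()].
#' @param animal_id,group Metadata attached to the recording.
#' @return A [session_recording()] with an extra `ground_truth` element.
#' @export
simulate_session <- function(design, params,
                             animal_id = "sim01", group = "control") {
  stopifnot(inherits(design, "session_design"), inherits(params, "sim_params"))
  if (abs(params$lag) >= design$iti_range_s[1]) {
    stop("lag must be shorter than the shortest inter-trial interval")
  }
  rate <- params$sampling_rate
  with_seed(params$seed, {
    n_tones <- design$n_tones
    itis <- if (n_tones > 1) {
      stats::runif(n_tones - 1, design$iti_range_s[1], design$iti_range_s[2])
    } else {
      numeric(0)
    }
    tone_onsets <- design$pretone_s +
      c(0, cumsum(itis + design$tone_duration_s))
    duration <- tone_onsets[n_tones] + design$tone_duration_s + design$tail_s
    n <- round(duration * rate)
    tvec <- (seq_len(n) - 1) / rate

    gains <- expand_region_trial(params$region_theta_gain, n_tones,
                                 "region_theta_gain")
    aeps <- expand_region_trial(params$aep_amplitude, n_tones,
                                "aep_amplitude")

    # shared source and its delayed copy are built at the padded power-of-2
    # length so the delay is applied before truncation
    m <- stats::nextn(n, 2)
    shared_m <- bandlimited_noise(m, rate, params$theta_source_band)
    shared_lag <- delay_signal(shared_m, rate, params$lag)[seq_len(n)]
    shared <- shared_m[seq_len(n)]
    private_bla <- bandlimited_noise(n, rate, params$theta_source_band)
    theta_dmpfc <- shared
    theta_bla <- sqrt(params$coupling) * shared_lag +
      sqrt(1 - params$coupling) * private_bla

    # unit-amplitude evoked template (scored peak-trough amplitude 1 uV)
    unit_tpl <- make_aep_template(40, -35, 15, 30,
                                  duration_ms = design$pip_duration_ms,
                                  rate = rate)
    unit_tpl <- unit_tpl / (max(unit_tpl) - min(unit_tpl))
    burst <- theta_burst_template(rate)
    seg_len <- max(length(unit_tpl), length(burst))
    tpl_pad <- c(unit_tpl, numeric(seg_len - length(unit_tpl)))
    burst_pad <- c(burst, numeric(seg_len - length(burst)))

    pip_offsets <- (seq_len(design$pips_per_tone) - 1) / design$pip_rate
    pip_onsets <- as.vector(outer(pip_offsets, tone_onsets, `+`))
    pip_trial <- rep(seq_len(n_tones), each = design$pips_per_tone)

    evoked <- cbind(dmPFC = numeric(n), BLA = numeric(n))
    for (k in seq_along(pip_onsets)) {
      i0 <- round(pip_onsets[k] * rate) + 1L
      tr <- pip_trial[k]
      for (rg in c("dmPFC", "BLA")) {
        seg <- aeps[tr, rg] * tpl_pad +
          gains[tr, rg] * params$theta_burst_uv * burst_pad
        j <- i0:min(n, i0 + length(seg) - 1L)
        evoked[j, rg] <- evoked[j, rg] + seg[seq_along(j)]
      }
    }

    bg <- function() {
      if (params$noise_sd == 0) return(0)
      params$noise_sd * pink_noise(n, rate, params$pink_noise_exponent,
                                   params$band_limits)
    }
    channels <- list(
      dmPFC = params$theta_sd * theta_dmpfc + evoked[, "dmPFC"] + bg(),
      BLA = params$theta_sd * theta_bla + evoked[, "BLA"] + bg()
    )

    events <- rbind(
      data.frame(time_s = tone_onsets, kind = "tone_onset",
                 trial_index = seq_len(n_tones)),
      data.frame(time_s = pip_onsets, kind = "pip_onset",
                 trial_index = pip_trial)
    )
    if (design$session_label == "conditioning") {
      us_onsets <- tone_onsets + design$tone_duration_s - design$us_duration_s
      events <- rbind(events,
                      data.frame(time_s = us_onsets, kind = "us_onset",
                                 trial_index = seq_len(n_tones)))
    }
    events <- events[order(events$time_s, events$kind), , drop = FALSE]
    rownames(events) <- NULL

    trials <- data.frame(trial_index = seq_len(n_tones),
                         session_label = design$session_label,
                         tone_onset_s = tone_onsets)

    gt <- list(lag = params$lag, coupling = params$coupling,
               seed = params$seed,
               trials = data.frame(trial_index = seq_len(n_tones),
                                   theta_gain_dmpfc = gains[, "dmPFC"],
                                   theta_gain_bla = gains[, "BLA"],
                                   aep_uv_dmpfc = aeps[, "dmPFC"],
                                   aep_uv_bla = aeps[, "BLA"]))

    rec <- session_recording(channels = channels, rate = rate,
                             events = events, trials = trials,
                             animal_id = animal_id, group = group,
                             design = design)
    rec$ground_truth <- gt
    rec
  })
}

#' Simulate freezing intervals for a session
#'
#' Produces freezing intervals whose union length inside each 30 s CS window
#' matches the requested per-trial fraction: exactly in deterministic mode
#' (one bout starting at tone onset), or in expectation in stochastic mode
#' (independent per-second freezing with the given probability). A pretone
#' entry (trial index 0) covers the 30 s window ending at the first tone
#' onset.
#'
#' @param trial_freeze_fracs Per-trial freezing fractions in `[0, 1]`.
#' @param tone_onsets Tone onset times in seconds (one per trial).
#' @param tone_duration_s CS duration in seconds.
#' @param pretone_frac Freezing fraction for the 30 s pretone window.
#' @param mode `"deterministic"` or `"stochastic"`.
#' @param seed Seed for stochastic mode.
#' @return data.frame with columns `trial_index`, `start_s`, `end_s`
#'   (trial 0 = pretone).
#' @export
simulate_freezing <- function(trial_freeze_fracs, tone_onsets,
                              tone_duration_s = 30, pretone_frac = 0,
                              mode = c("deterministic", "stochastic"),
                              seed = 1L) {
  mode <- match.arg(mode)
  fr <- c(pretone_frac, rep_len(trial_freeze_fracs, length(tone_onsets)))
  if (any(fr < 0 | fr > 1)) stop("freezing fractions must lie in [0, 1]")
  starts <- c(tone_onsets[1] - 30, tone_onsets)
  durs <- c(30, rep(tone_duration_s, length(tone_onsets)))
  idx <- c(0L, seq_along(tone_onsets))
  out <- with_seed(seed, {
    rows <- list()
    for (k in seq_along(fr)) {
      if (fr[k] == 0) next
      if (mode == "deterministic") {
        rows[[length(rows) + 1L]] <-
          data.frame(trial_index = idx[k], start_s = starts[k],
                     end_s = starts[k] + fr[k] * durs[k])
      } else {
        frozen <- stats::runif(durs[k]) < fr[k]
        if (!any(frozen)) next
        m <- merge_intervals(which(frozen) - 1, which(frozen))
        rows[[length(rows) + 1L]] <-
          data.frame(trial_index = idx[k], start_s = starts[k] + m[, "start"],
                     end_s = starts[k] + m[, "end"])
      }
    }
    if (length(rows) == 0) {
      data.frame(trial_index = integer(0), start_s = numeric(0),
                 end_s = numeric(0))
    } else {
      do.call(rbind, rows)
    }
  })
  rownames(out) <- NULL
  out
}
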