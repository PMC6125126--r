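test_that("parameter validation rejects out-of-range settings", {
  expect_error(sim_params(coupling = 1.2), "coupling")
  expect_error(sim_params(lag = 2.5), "lag")
  expect_error(sim_params(noise_sd = -1), "noise_sd")
  expect_error(sim_params(sampling_rate = 800, band_limits = c(1, 500)),
               "twice")
  expect_error(session_design("tone_habituation", pips_per_tone = 20),
               "tone_duration")
  expect_error(session_design("conditioning"), "no default")
})

test_that("identical params and seed give bit-identical sessions", {
  des <- session_design("tone_habituation", n_tones = 2)
  p <- sim_params(seed = 42)
  a <- simulate_session(des, p)
  b <- simulate_session(des, p)
  expect_identical(a$channels, b$channels)
  expect_identical(a$events, b$events)
  expect_identical(a$ground_truth, b$ground_truth)
  c2 <- simulate_session(des, sim_params(seed = 43))
  expect_false(identical(a$channels$dmPFC, c2$channels$dmPFC))
})

test_that("full coupling, zero lag and zero noise give identical channels", {
  rec <- simulate_session(session_design("tone_habituation", n_tones = 2),
                          sim_params(coupling = 1, lag = 0, noise_sd = 0,
                                     seed = 5))
  expect_identical(rec$channels$dmPFC, rec$channels$BLA)
})

test_that("simulated power is confined to the recording band", {
  rec <- simulate_session(session_design("tone_habituation", n_tones = 2),
                          sim_params(seed = 11))
  for (ch in rec$channels) {
    n <- length(ch)
    pw <- Mod(stats::fft(ch - mean(ch)))^2
    f <- abs(fearlfp:::fft_bin_freqs(n, rec$rate))
    inband <- f >= 1 & f <= 500
    expect_lt(sum(pw[!inband]) / sum(pw[inband]), 0.01)
  }
})

test_that("session timeline matches the design contract", {
  des <- session_design("fear_recall_extinction", n_tones = 3)
  rec <- simulate_session(des, sim_params(seed = 9))
  tones <- rec$events[rec$events$kind == "tone_onset", ]
  expect_equal(nrow(tones), 3)
  itis <- diff(tones$time_s) - des$tone_duration_s
  expect_true(all(itis >= 80 & itis <= 160))
  pips <- rec$events[rec$events$kind == "pip_onset", ]
  expect_equal(nrow(pips), 3 * 30)
  # pips at 1 Hz from each tone onset
  p1 <- pips$time_s[pips$trial_index == 1]
  expect_equal(p1, tones$time_s[1] + 0:29)
  expect_false(is.unsorted(rec$events$time_s))
  expect_equal(length(rec$channels$dmPFC), length(rec$channels$BLA))
})

test_that("evoked template honours requested extrema and stays smooth", {
  tpl <- make_aep_template(40, -35, 15, 30, 100)
  t_ms <- attr(tpl, "time_s") * 1000
  expect_equal(max(tpl) - min(tpl), 75, tolerance = 1e-3)
  expect_equal(t_ms[which.max(tpl)], 15)
  expect_equal(t_ms[which.min(tpl)], 30)
  expect_lt(max(abs(tpl[c(1, length(tpl))])), 0.05)
  expect_identical(make_aep_template(0, 0, 15, 30, 100),
                   structure(numeric(101), time_s = attr(tpl, "time_s")))
  expect_error(make_aep_template(40, -35, 30, 15, 100), "latencies")
  expect_error(make_aep_template(NaN, -35, 15, 30, 100), "non-finite")
})

test_that("scored template amplitude equals peak minus trough on a grid", {
  for (pk in c(10, 40, 80)) {
    for (tr in c(-5, -35, -60)) {
      tpl <- make_aep_template(pk, tr, 15, 30, 100)
      ev <- structure(list(waveform = c(numeric(100), as.numeric(tpl)),
                           time_ms = seq(-100, 100, by = 1)),
                      class = "evoked_response")
      sc <- score_amplitude(ev, search_window_ms = c(0, 90))
      expect_equal(sc$amplitude_uv, pk - tr, tolerance = 1e-3 * (pk - tr))
    }
  }
})

test_that("deterministic freezing fractions are recovered exactly", {
  onsets <- c(100, 250)
  fr <- simulate_freezing(c(0.5, 0.25), onsets, mode = "deterministic")
  expect_equal(freezing_percent(fr[fr$trial_index == 1, ], c(100, 130)), 50)
  expect_equal(freezing_percent(fr[fr$trial_index == 2, ], c(250, 280)), 25)
  # zero fraction -> no intervals -> 0 %
  fr0 <- simulate_freezing(c(0, 0), onsets, mode = "deterministic")
  expect_equal(nrow(fr0), 0)
  expect_equal(freezing_percent(fr0, c(100, 130)), 0)
  expect_error(simulate_freezing(c(1.5), onsets), "fractions")
})

test_that("stochastic freezing recovers the fraction in expectation", {
  onsets <- 100
  got <- vapply(1:500, function(s) {
    fr <- simulate_freezing(0.6, onsets, mode = "stochastic", seed = s)
    freezing_percent(fr[fr$trial_index == 1, ], c(100, 130))
  }, numeric(1))
  expect_lt(abs(mean(got) - 60), 1)
})

test_that("per-trial theta gain is monotonically recovered as evoked theta power", {
  # z-scored power is informative while the evoked burst is comparable to
  # the averaging residual, so the sweep spans sub-threshold to saturation
  # on a log grid, at low background noise, with replicate sessions
  gains <- 10^seq(log10(0.1), log10(4), length.out = 12)
  des <- session_design("tone_habituation", n_tones = 1, pretone_s = 31,
                        tail_s = 2)
  power <- vapply(seq_along(gains), function(i) {
    mean(vapply(1:4, function(r) {
      p <- sim_params(seed = 100 * i + r, noise_sd = 5, theta_sd = 5,
                      region_theta_gain = gains[i])
      rec <- simulate_session(des, p)
      segs <- epoch_pips(rec, "BLA", 1)
      tf <- zscore_baseline(morlet_tfr(average_aep(segs), rate = rec$rate))
      evoked_theta_power(tf)
    }, numeric(1)))
  }, numeric(1))
  expect_gt(cor(gains, power, method = "spearman"), 0.9)
})
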