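test_that("coherence is exactly one for identical signals", {
  set.seed(61)
  x <- rnorm(10000)
  cs <- coherence_spectrum(x, x, 1000)
  expect_true(all(abs(cs$coherence - 1) < 1e-6, na.rm = TRUE))
  expect_equal(cs$theta_coherence, 1, tolerance = 1e-6)
})

test_that("a pure delay leaves magnitude coherence near one", {
  set.seed(62)
  x <- uncoupled_channel(30000, 1000, noise_sd = 0)
  y <- c(numeric(10), x)[1:30000]  # 10 ms delay
  cs <- coherence_spectrum(x, y, 1000)
  expect_gt(cs$theta_coherence, 0.95)
})

test_that("independent signals fall to the finite-sample coherence floor", {
  rate <- 1000
  n <- 30000
  floor_dist <- coherence_floor_oracle(n, rate, reps = 60, seed = 63)
  set.seed(64)
  vals <- vapply(1:8, function(i) {
    coherence_spectrum(uncoupled_channel(n, rate), uncoupled_channel(n, rate),
                       rate)$theta_coherence
  }, numeric(1))
  expect_gt(mean(vals), quantile(floor_dist, 0.005))
  expect_lt(mean(vals), quantile(floor_dist, 0.995))
  expect_lt(mean(vals), 0.1)
  expect_error(coherence_spectrum(rnorm(100), rnorm(100), 1000), "shorter")
})

test_that("theta envelope is flat for a pure tone and tracks slow AM", {
  rate <- 1000
  t <- seq(0, 20, by = 1 / rate)
  interior <- t > 2 & t < 18
  env0 <- theta_envelope(5 * sin(2 * pi * 8 * t), rate)
  expect_lt(max(abs(env0[interior])), 0.02 * 5)
  A <- 3 + sin(2 * pi * 0.2 * t)
  env1 <- theta_envelope(A * sin(2 * pi * 8 * t), rate)
  target <- A - mean(A[interior])
  expect_lt(max(abs(env1[interior] - target[interior])),
            0.05 * max(A))
  expect_equal(theta_envelope(numeric(20000), rate), numeric(20000))
  expect_error(theta_envelope(rnorm(20000), rate, band = c(2, 600)),
               "Nyquist")
})

test_that("envelope cross-correlation matches the brute-force oracle", {
  rate <- 200
  set.seed(65)
  for (i in 1:3) {
    # smooth AR(1)-style envelopes
    a <- as.numeric(stats::filter(rnorm(3000), 0.95, method = "recursive"))
    b <- 0.4 * a + as.numeric(stats::filter(rnorm(3000), 0.95,
                                            method = "recursive"))
    xc <- envelope_xcorr(a, b, rate, max_lag = 0.1)
    orc <- xcorr_oracle(a, b, rate, max_lag = 0.1)
    expect_equal(xc$r, orc$r, tolerance = 1e-10)
    expect_equal(xc$lag_s, orc$lag_s)
  }
})

test_that("cross-correlation peaks sit at the constructed delay", {
  rate <- 1000
  set.seed(66)
  a <- theta_envelope(uncoupled_channel(30000, rate, noise_sd = 0), rate)
  xc0 <- envelope_xcorr(a, a, rate)
  expect_equal(xc0$peak_lag_s, 0)
  expect_equal(xc0$peak_r, 1, tolerance = 1e-12)
  b <- c(numeric(20), a)[1:30000]  # a leads b by 20 ms
  xc <- envelope_xcorr(a, b, rate)
  expect_lte(abs(xc$peak_lag_s - 0.020), 1 / rate)
  expect_error(envelope_xcorr(a, numeric(30000), rate), "zero-variance")
})

test_that("swapping channels negates every lag (antisymmetry)", {
  rate <- 500
  set.seed(67)
  x <- uncoupled_channel(15000, rate)
  y <- 0.5 * c(numeric(11), x)[1:15000] + 0.5 * uncoupled_channel(15000, rate)
  ea <- theta_envelope(x, rate); eb <- theta_envelope(y, rate)
  ab <- envelope_xcorr(ea, eb, rate)
  ba <- envelope_xcorr(eb, ea, rate)
  expect_equal(ab$r, rev(ba$r), tolerance = 1e-12)
  expect_equal(ab$peak_lag_s, -ba$peak_lag_s)
  # gain invariance
  sc <- envelope_xcorr(3.3 * ea, 0.2 * eb, rate)
  expect_equal(sc$r, ab$r, tolerance = 1e-12)
})

test_that("surrogate peaks are reproducible and detect a real lead", {
  rate <- 1000
  set.seed(68)
  x <- uncoupled_channel(30000, rate, noise_sd = 3)
  y <- c(numeric(20), x)[1:30000] + 0.1 * uncoupled_channel(30000, rate)
  ea <- theta_envelope(x, rate); eb <- theta_envelope(y, rate)
  s1 <- surrogate_peaks(ea, eb, rate, n = 50, seed = 9)
  s2 <- surrogate_peaks(ea, eb, rate, n = 50, seed = 9)
  expect_identical(s1, s2)
  xc <- envelope_xcorr(ea, eb, rate)
  expect_true(all(xc$peak_r > s1))
  expect_error(surrogate_peaks(ea, eb, rate, n = 0), "at least one")
  expect_error(surrogate_peaks(ea[1:5000], eb[1:5000], rate), "too short")
})

test_that("lead/lag summary takes the maximal histogram bin", {
  rate <- 1000
  set.seed(69)
  segs <- lapply(1:3, function(i) {
    x <- uncoupled_channel(30000, rate, noise_sd = 0)
    y <- c(numeric(20), x)[1:30000]
    list(theta_envelope(x, rate), theta_envelope(y, rate))
  })
  ll <- lead_lag(segs, rate, n_surrogates = 30, seed = 5)
  expect_equal(ll$summary_lag_s, 0.020, tolerance = 1e-9)
  expect_true(ll$significant)
  expect_equal(dim(ll$surrogates), c(3, 30))
  # per-segment peaks all at +20 ms
  expect_true(all(abs(ll$peak_lag_s - 0.020) <= 1 / rate))
})

test_that("recording-level lead/lag recovers the injected delay and sign", {
  des <- session_design("fear_recall_extinction", n_tones = 2)
  rec <- simulate_session(des, sim_params(coupling = 0.9, lag = 0.02,
                                          noise_sd = 7.5, seed = 71))
  ll <- lead_lag_session(rec, "fear_recall", seed = 72)
  expect_lte(abs(ll$summary_lag_s - 0.02), 0.005 + 1e-9)
  expect_true(ll$significant)
  expect_gt(ll$summary_lag_s, 0)  # dmPFC leads
  # swapped injection: BLA leads -> negative summary
  rec2 <- simulate_session(des, sim_params(coupling = 0.9, lag = -0.02,
                                           noise_sd = 7.5, seed = 73))
  ll2 <- lead_lag_session(rec2, "fear_recall", seed = 74)
  expect_lte(abs(ll2$summary_lag_s + 0.02), 0.005 + 1e-9)
  # uncoupled channels: not significant
  rec3 <- simulate_session(des, sim_params(coupling = 0, lag = 0, seed = 75))
  ll3 <- lead_lag_session(rec3, "fear_recall", seed = 76)
  expect_false(ll3$significant)
})
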