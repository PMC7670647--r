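# Cross-PLV machinery: filter, phase, PLV, lag profile, surrogates.

test_that("zero-phase band-pass keeps the band and kills out-of-band lines", {
  fs <- 1000
  t <- (0:2999) / fs
  x65 <- sin(2 * pi * 65 * t)
  y65 <- bandpass_zero_phase(x65, fs = fs)
  core <- 500:2500
  # analytic double-pass Butterworth amplitude at 65 Hz:
  # |H_hp|^2 * |H_lp|^2 = 1/(1+(55/65)^8) * 1/(1+(65/75)^8)
  gain_expected <- 1 / (1 + (55 / 65)^8) * 1 / (1 + (65 / 75)^8)
  expect_equal(stats::sd(y65[core]) / stats::sd(x65[core]), gain_expected,
    tolerance = 0.02
  )
  x10 <- sin(2 * pi * 10 * t)
  y10 <- bandpass_zero_phase(x10, fs = fs)
  atten_db <- 20 * log10(stats::sd(y10[core]) / stats::sd(x10[core]))
  expect_lt(atten_db, -40)
  # symmetric impulse response: zero net group delay
  imp <- numeric(2001)
  imp[1001] <- 1
  h <- bandpass_zero_phase(imp, fs = fs)
  expect_equal(h[1001 + 1:400], h[1001 - 1:400], tolerance = 1e-8)
  expect_error(bandpass_zero_phase(x65, 55, 600, fs = fs), "Nyquist")
})

test_that("instantaneous phase advances at the line frequency and respects sign flips", {
  fs <- 1000
  t <- (0:1999) / fs
  x <- cos(2 * pi * 65 * t)
  ph <- unwrap_phase(instantaneous_phase(x))
  rate <- diff(ph[200:1800]) * fs / (2 * pi)
  expect_equal(mean(rate), 65, tolerance = 0.01)
  ph_flip <- instantaneous_phase(-x)
  dphi <- (instantaneous_phase(x) - ph_flip + pi) %% (2 * pi) - pi
  expect_equal(abs(dphi[200:1800]), rep(pi, 1601), tolerance = 1e-6)
})

test_that("tagging-signal phase recovers the generator's modulation", {
  sig <- generate_tagging_signal(seed = 6)
  t <- (0:1999) / 1000
  ph <- unwrap_phase(instantaneous_phase(sig$samples))
  recovered <- ph - 2 * pi * 65 * t
  truth <- rowSums(vapply(1:3, function(i) {
    sin(2 * pi * i * t + sig$phase_offsets[i])
  }, numeric(2000)))
  core <- 150:1850
  # allow a common constant offset (2*pi branch of the unwrap)
  err <- (recovered - truth) - mean((recovered - truth)[core])
  expect_lt(max(abs(err[core])), 0.05)
})

test_that("PLV identities, bounds, symmetry and offset invariance", {
  expect_equal(plv(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(plv(c(0, 0), c(0, pi)), 0, tolerance = 1e-12)
  expect_error(plv(1:3, 1:4), "equal length")
  set.seed(1)
  x <- stats::runif(500, -pi, pi)
  y <- stats::runif(500, -pi, pi)
  expect_equal(plv(x, y), plv(y, x), tolerance = 1e-12)
  expect_equal(plv(x + 1.3, y), plv(x, y), tolerance = 1e-12)
  expect_gte(plv(x, y), 0)
  expect_lte(plv(x, y), 1)
})

test_that("null PLV of independent phases matches the Rayleigh expectation", {
  # E[PLV] for N iid uniform phase differences ~= sqrt(pi)/2 / sqrt(N)
  set.seed(2)
  n <- 2000
  sims <- replicate(300, plv(stats::runif(n, -pi, pi), stats::runif(n, -pi, pi)))
  expect_equal(mean(sims), sqrt(pi) / 2 / sqrt(n), tolerance = 0.1)
})

test_that("FFT lag profile equals the naive per-lag loop to machine precision", {
  set.seed(3)
  fs <- 1000
  n_time <- 1200
  time <- -0.3 + (0:(n_time - 1)) / fs
  meg <- one_over_f_noise(n_time)
  tag <- one_over_f_noise(n_time)
  lags_ms <- -60:60
  pr <- cross_plv(meg, tag,
    fs = fs, time = time, lags_ms = lags_ms,
    window = c(0, 0.8), edge_exclude_ms = 100
  )
  # oracle: same filtering/phase operators, then an explicit lag loop
  phi_m <- instantaneous_phase(bandpass_zero_phase(meg, fs = fs))
  phi_t <- instantaneous_phase(bandpass_zero_phase(tag, fs = fs))
  win_idx <- which(time >= 0.1 - 1e-9 & time < 0.7 - 1e-9)
  ref <- naive_crossplv_profile(phi_m, phi_t, win_idx, lags_ms)
  expect_equal(pr$plv, ref, tolerance = 1e-10)
  expect_equal(pr$n_samples_used, length(win_idx))
})

test_that("delayed and advanced copies localize at the signed lag", {
  fs <- 1000
  time <- -1 + (0:3499) / fs
  act <- time >= 0 & time < 2
  tag <- numeric(3500)
  tag[act] <- generate_tagging_signal(seed = 7)$samples
  base <- bandpass_zero_phase(tag, fs = fs)
  pr50 <- cross_plv(delay_signal_for_test(base, 50), tag, fs = fs, time = time)
  expect_equal(pr50$peak_lag_ms, 50)
  expect_gt(pr50$peak_plv, 0.99)
  pr_neg <- cross_plv(delay_signal_for_test(base, -20), tag, fs = fs, time = time)
  expect_equal(pr_neg$peak_lag_ms, -20)
  expect_error(
    cross_plv(base, tag, fs = fs, time = time, lags_ms = -1200:1200),
    "margin"
  )
})

test_that("surrogate bound is seeded, bounded and detects real coupling", {
  fs <- 1000
  time <- -1 + (0:3499) / fs
  act <- time >= 0 & time < 2
  set.seed(8)
  n_tr <- 6
  tag <- matrix(0, n_tr, 3500)
  meg <- matrix(0, n_tr, 3500)
  for (k in seq_len(n_tr)) {
    tag[k, act] <- generate_tagging_signal()$samples
    meg[k, ] <- delay_signal_for_test(bandpass_zero_phase(tag[k, ], fs = fs), 50) +
      0.5 * one_over_f_noise(3500)
  }
  ci <- surrogate_ci(meg, tag, fs = fs, time = time, n_shifts = 40, seed = 9)
  ci_b <- surrogate_ci(meg, tag, fs = fs, time = time, n_shifts = 40, seed = 9)
  expect_identical(ci$threshold, ci_b$threshold)
  pr <- cross_plv(meg, tag, fs = fs, time = time)
  expect_gt(pr$peak_plv, ci$threshold)
  # degenerate surrogate count still yields a bound, flagged low precision
  expect_message(
    ci2 <- surrogate_ci(meg[1, , drop = FALSE], tag[1, , drop = FALSE],
      fs = fs, time = time, n_shifts = 2, seed = 10
    ),
    "low precision"
  )
  expect_true(ci2$low_precision)
  expect_true(is.finite(ci2$threshold))
  # pointwise option returns one bound per lag
  ci3 <- surrogate_ci(meg, tag,
    fs = fs, time = time, n_shifts = 20, seed = 11,
    statistic = "pointwise"
  )
  expect_length(ci3$threshold, 401)
})

test_that("strongest-channel selection favors the drive-carrying channel", {
  cfg <- sim_config(n_trials = 16, n_channels = 4, seed = 12, snr = 2)
  ep <- epoch(simulate_recording(cfg))
  suppressMessages(
    profs <- cross_plv_channels(ep, n_shifts = 20, seed = 13)
  )
  sel <- select_strongest_channel(profs)
  expect_equal(sel$left$hemisphere, "left")
  expect_equal(sel$right$hemisphere, "right")
  lm <- latency_and_magnitude(sel$left$attended)
  expect_true(isTRUE(lm$reliable))
  expect_lt(abs(lm$latency_ms - 50), 3)
  # empty hemisphere errors
  left_only <- profs[vapply(profs, `[[`, character(1), "hemisphere") == "left"]
  expect_error(select_strongest_channel(left_only), "empty hemisphere")
})

test_that("sub-threshold profiles are flagged unreliable", {
  pr <- structure(
    list(
      lags_ms = -5:5, plv = rep(0.1, 11), peak_plv = 0.1,
      peak_lag_ms = 0, ci99_threshold = 0.5, n_samples_used = 100, n_trials = 1
    ),
    class = "crossplv_profile"
  )
  expect_false(latency_and_magnitude(pr)$reliable)
})
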