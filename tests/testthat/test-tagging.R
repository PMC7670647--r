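# Broadband tagging-signal generation and validation.

test_that("generated signal has the contracted length, range and reproducibility", {
  sig <- generate_tagging_signal(duration = 2, fs = 1000, f_c = 65, seed = 1)
  expect_length(sig$samples, 2000)
  expect_true(all(sig$samples >= -1 & sig$samples <= 1))
  sig2 <- generate_tagging_signal(duration = 2, fs = 1000, f_c = 65, seed = 1)
  expect_identical(sig$samples, sig2$samples)
  # different seeds give different phase draws
  sig3 <- generate_tagging_signal(seed = 2)
  expect_false(identical(sig$samples, sig3$samples))
  # odd durations round to the nearest sample count
  expect_length(generate_tagging_signal(duration = 1.5, seed = 1)$samples, 1500)
})

test_that("fixed-phase waveform equals the closed-form expression", {
  sig <- generate_tagging_signal(
    duration = 1, fs = 1000, f_c = 65,
    phase_offsets = c(0, 0, 0)
  )
  t <- (0:999) / 1000
  expected <- sin(2 * pi * 65 * t + sin(2 * pi * t) + sin(2 * pi * 2 * t) + sin(2 * pi * 3 * t))
  expect_equal(sig$samples, expected, tolerance = 1e-12)
})

test_that("argument validation rejects bad durations, rates and bands", {
  expect_error(generate_tagging_signal(duration = 0), "positive")
  expect_error(generate_tagging_signal(fs = -1), "positive")
  expect_error(generate_tagging_signal(fs = 140, f_c = 65), "aliasing")
  expect_error(band_energy_fraction(generate_tagging_signal(seed = 1), 70, 60), "invalid band")
})

test_that("instantaneous frequency stays within the carrier +/- 6 Hz excursion", {
  for (s in c(1, 7, 42)) {
    sig <- generate_tagging_signal(seed = s)
    ph <- unwrap_phase(instantaneous_phase(sig$samples))
    f_inst <- diff(ph) * sig$fs / (2 * pi)
    core <- 100:1890 # away from Hilbert edge distortion
    expect_gte(min(f_inst[core]), 59)
    expect_lte(max(f_inst[core]), 71)
  }
})

test_that("envelope is constant (pure phase modulation)", {
  sig <- generate_tagging_signal(seed = 3)
  env <- Mod(analytic_signal(sig$samples))
  expect_lt(max(abs(env[100:1900] - 1)), 0.05)
})

test_that("spectral support: peak in the tagged band, >=99% power in 55-75 Hz", {
  seeds <- 1:10
  peaks <- vapply(seeds, function(s) {
    spectral_peak_frequency(generate_tagging_signal(seed = s))
  }, numeric(1))
  expect_true(all(peaks >= 60 & peaks <= 70))
  fracs <- vapply(seeds, function(s) {
    band_energy_fraction(generate_tagging_signal(seed = s), 55, 75)
  }, numeric(1))
  expect_true(all(fracs >= 0.99))
  # the carrier is the peak of the phase-averaged spectrum
  avg_spec <- rowMeans(vapply(1:40, function(s) {
    Mod(stats::fft(generate_tagging_signal(seed = s)$samples))[2:1000]^2
  }, numeric(999)))
  expect_equal(which.max(avg_spec) * 0.5, 65)
})

test_that("band_energy_fraction matches known spectra", {
  t <- (0:1999) / 1000
  pure <- sin(2 * pi * 65 * t)
  expect_gt(band_energy_fraction(pure, 60, 70, fs = 1000), 0.999)
  sig <- generate_tagging_signal(seed = 5)
  expect_lt(band_energy_fraction(sig, 0, 50), 0.01)
})

test_that("luminance map is the affine [0,1] rescaling", {
  expect_equal(luminance_map(c(-1, 0, 1)), c(0, 0.5, 1))
  sig <- generate_tagging_signal(seed = 1)
  lum <- luminance_map(sig)
  expect_true(all(lum >= 0 & lum <= 1))
  expect_equal(lum, (sig$samples + 1) / 2)
  expect_error(luminance_map(c(0, 2)), "\\[-1, 1\\]")
})

test_that("decorrelated pairs honor the correlation contract", {
  pair <- generate_decorrelated_pair(seed = 1)
  expect_lt(abs(stats::cor(pair$left$samples, pair$right$samples)), 0.1)
  expect_gte(attr(pair, "rejections"), 0)
  # vacuously loose threshold: first draw accepted
  easy <- generate_decorrelated_pair(max_abs_corr = 0.999, seed = 2)
  expect_identical(attr(easy, "rejections"), 0L)
  # identical seeds without independent draws are perfectly correlated,
  # which is exactly what the rejection loop exists to prevent
  a <- generate_tagging_signal(seed = 9)
  b <- generate_tagging_signal(seed = 9)
  expect_equal(stats::cor(a$samples, b$samples), 1)
  # an unreachable threshold exhausts the rejection budget
  expect_error(
    generate_decorrelated_pair(max_abs_corr = 1e-6, seed = 3, max_attempts = 5),
    "generation failed"
  )
  expect_error(generate_decorrelated_pair(max_abs_corr = 1.5), "max_abs_corr")
})

test_that("strict printed form uses quarter-radian offsets and stays in range", {
  sig <- generate_tagging_signal(seed = 4, strict_printed_form = TRUE)
  expect_true(all(sig$phase_offsets >= 0 & sig$phase_offsets <= 0.25))
  expect_true(all(abs(sig$samples) <= 1))
})
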