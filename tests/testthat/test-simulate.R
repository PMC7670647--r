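# Synthetic recording generator.

test_that("recording has the contracted shape and exact photodiode copies", {
  cfg <- sim_config(n_trials = 6, n_channels = 5, seed = 1)
  rec <- simulate_recording(cfg)
  expect_equal(dim(rec$sensor_data), c(5, 6, 3500))
  expect_equal(dim(rec$photodiode$left), c(6, 3500))
  expect_equal(nrow(rec$channels), 5)
  expect_true(all(c("left", "right") %in% rec$channels$hemisphere))
  # photodiode is the luminance-mapped drive: in [0,1], flat at 0.5
  # outside the 0-2 s tagging window, zero-delay spectral content in-band
  t <- -1 + (0:3499) / 1000
  act <- t >= 0 & t < 2
  expect_true(all(rec$photodiode$left >= 0 & rec$photodiode$left <= 1))
  expect_true(all(rec$photodiode$left[, !act] == 0.5))
  drive <- 2 * rec$photodiode$right[1, ] - 1
  expect_gt(band_energy_fraction(drive[act], 55, 75, fs = 1000), 0.99)
  # left/right drives of each trial are decorrelated
  corrs <- vapply(1:6, function(k) {
    stats::cor(rec$photodiode$left[k, act], rec$photodiode$right[k, act])
  }, numeric(1))
  expect_true(all(abs(corrs) < 0.1))
  # determinism from the config seed
  rec2 <- simulate_recording(cfg)
  expect_identical(rec$sensor_data, rec2$sensor_data)
})

test_that("trial factors realize the configured copula coupling", {
  set.seed(10)
  f0 <- draw_trial_factors(500, rho = 0)
  expect_lt(abs(stats::cor(f0$tag_gain_factor, f0$alpha_amp_factor, method = "spearman")), 0.1)
  f5 <- draw_trial_factors(500, rho = 0.5)
  rs <- stats::cor(f5$tag_gain_factor, f5$alpha_amp_factor, method = "spearman")
  # rank correlation of a Gaussian copula: (6/pi) asin(rho/2) ~= 0.483
  expect_gt(rs, 0.35)
  expect_lt(rs, 0.6)
  expect_true(all(f5$tag_gain_factor > 0))
})

test_that("noiseless delayed-copy recording recovers the injected latency exactly", {
  for (lat in c(37, 83)) {
    cfg <- sim_config(
      n_trials = 4, n_channels = 2, latency_true = lat, snr = 100,
      tagging_gain_attended = 1, tagging_gain_unattended = 1,
      alpha_amp_ipsi = 0, alpha_amp_contra = 0, gain_sd = 0,
      seed = 20 + lat
    )
    ep <- epoch(simulate_recording(cfg))
    ch <- which(ep$channels$hemisphere == "left" & ep$channels$group == "occipital")[1]
    meg <- matrix(ep$data[ch, , ], nrow = 4)
    pr <- cross_plv(meg, ep$photodiode$right, fs = 1000, time = ep$time)
    expect_equal(pr$peak_lag_ms, lat)
    expect_gt(pr$peak_plv, 0.95)
  }
})

test_that("injected alpha lateralization is recovered with the right sign and size", {
  cfg <- sim_config(n_trials = 80, n_channels = 6, seed = 11)
  ep <- epoch(simulate_recording(cfg))
  alpha_ami <- combine_hemisphere_ami(ami_map(ep, c(8, 13)))
  # injected -10% power modulation, slightly diluted by in-band noise
  expect_lt(alpha_ami, -0.04)
  expect_gt(alpha_ami, -0.15)
  tag_ami <- combine_hemisphere_ami(ami_map(ep, c(55, 75)))
  expect_gt(tag_ami, 0)
})

test_that("artifact injection is a labeled no-op at zero rates", {
  cfg <- sim_config(n_trials = 10, n_channels = 4, seed = 3)
  rec <- simulate_recording(cfg)
  expect_identical(inject_artifacts(rec, list(), seed = 1), rec)
  expect_identical(
    inject_artifacts(rec, list(blink = 0, saccade = 0, sensor = 0), seed = 1),
    rec
  )
  expect_error(inject_artifacts(rec, list(blink = 2)), "rates")
})

test_that("artifact counts follow the configured Bernoulli rates", {
  cfg <- sim_config(n_trials = 120, n_channels = 2, seed = 5)
  rec <- simulate_recording(cfg)
  rec <- inject_artifacts(rec, list(blink = 0.2), seed = 6)
  n_blinks <- sum(rec$labels$type == "blink")
  # Binomial(120, 0.2): mean 24, generous band
  expect_gt(n_blinks, 10)
  expect_lt(n_blinks, 40)
})

test_that("power-table model realizes gains and coupling", {
  tab <- simulate_power_table(2000, coupling_rho = 0, seed = 7)
  expect_true(all(tab$alpha_power > 0))
  # attended gain ratio ~ 1.05/0.95 on average
  expect_equal(
    mean(tab$tag_power_contra) / mean(tab$tag_power_ipsi),
    1.05 / 0.95,
    tolerance = 0.05
  )
  expect_lt(abs(stats::cor(tab$alpha_power, tab$tag_power_contra, method = "spearman")), 0.08)
  tab5 <- simulate_power_table(2000, coupling_rho = 0.5, seed = 8)
  expect_gt(stats::cor(tab5$alpha_power, tab5$tag_power_contra, method = "spearman"), 0.25)
})
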