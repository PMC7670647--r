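# Band power, AMI and the median split.

test_that("band power matches the closed-form Hann single-line value", {
  # unit 10 Hz sinusoid on the 0-2 s window: with a periodic Hann taper
  # the line occupies three bins with |X| = A*N/4, A*N/8, A*N/8 and the
  # normalization 2|X|^2/(sum w)^2 puts 2*(1/16 + 2/64) = 0.75*A^2 in band
  t <- -1 + (0:3499) / 1000
  amps <- c(1, 2)
  for (A in amps) {
    data <- array(0, dim = c(2, 3, 3500))
    for (k in 1:3) data[1, k, ] <- A * sin(2 * pi * 10 * t)
    ep <- make_epoch_set(data)
    pw <- epoch_band_power(ep, c(8, 13))
    expect_equal(unname(pw[1, ]), rep(0.75 * A^2, 3), tolerance = 1e-6)
    # no leakage into the tagging band
    expect_lt(max(epoch_band_power(ep, c(55, 75))[1, ]), 1e-6)
  }
  expect_error(epoch_band_power(make_epoch_set(array(0, c(2, 2, 3500))), c(13, 8)), "invalid band")
})

test_that("AMI arithmetic, bounds and degenerate cases", {
  expect_equal(ami(3, 1), 0.5)
  expect_equal(ami(1, 1), 0)
  expect_equal(ami(1, 0), 1)
  expect_warning(v <- ami(0, 0), "undefined")
  expect_true(is.na(v))
  expect_error(ami(-1, 1), "non-negative")
  # antisymmetry and scale invariance on random inputs
  set.seed(42)
  for (r in 1:20) {
    p <- stats::runif(2, 0.01, 10)
    expect_equal(ami(p[1], p[2]), -ami(p[2], p[1]), tolerance = 1e-12)
    s <- stats::runif(1, 0.1, 100)
    expect_equal(ami(s * p[1], s * p[2]), ami(p[1], p[2]), tolerance = 1e-12)
    expect_lte(abs(ami(p[1], p[2])), 1)
  }
})

test_that("injected 1.1:0.9 power ratio yields AMI 0.1 exactly in the noiseless limit", {
  # identical alpha waveform scaled by sqrt(1.1) on attended trials and
  # sqrt(0.9) on unattended ones, for both hemispheres
  t <- -1 + (0:3499) / 1000
  wave <- sin(2 * pi * 10 * t)
  layout <- channel_layout(2) # one occipital channel per hemisphere
  data <- array(0, dim = c(2, 4, 3500))
  cue <- c("left", "left", "right", "right")
  for (ch in 1:2) {
    att_cue <- if (layout$hemisphere[ch] == "left") "right" else "left"
    for (k in 1:4) {
      scale <- if (cue[k] == att_cue) sqrt(1.1) else sqrt(0.9)
      data[ch, k, ] <- scale * wave
    }
  }
  ep <- make_epoch_set(data, cue_side = cue, layout = layout)
  map <- ami_map(ep, c(8, 13), "alpha")
  expect_equal(map$ami, rep(0.1, 2), tolerance = 1e-9)
  expect_equal(combine_hemisphere_ami(map), 0.1, tolerance = 1e-9)
})

test_that("hemisphere combination averages with aligned signs and demands both sides", {
  map <- data.frame(
    channel = 1:2, label = c("OL1", "OR1"),
    hemisphere = c("left", "right"), group = "occipital",
    band = "alpha", ami = c(0.1, 0.1)
  )
  expect_equal(combine_hemisphere_ami(map), 0.1)
  map$ami <- c(0, 0)
  expect_equal(combine_hemisphere_ami(map), 0)
  expect_error(
    combine_hemisphere_ami(map[map$hemisphere == "left", ]),
    "missing hemisphere: right"
  )
})

test_that("median split bins, tie rule and forced ordering", {
  # perfect coupling: high-alpha bin strictly larger
  a <- c(1, 2, 3, 4, 5, 6)
  ms <- median_split_analysis(a, a, a)
  expect_gt(ms$high_contra, ms$low_contra)
  expect_equal(ms$n_low, 3)
  # odd n: median trial goes to the low bin
  ms_odd <- median_split_analysis(1:5, 1:5, 1:5)
  expect_equal(ms_odd$n_low, 3)
  expect_equal(ms_odd$low_contra, 2) # mean of 1,2,3
  expect_warning(median_split_analysis(rep(1, 4), 1:4, 1:4), "degenerate")
  expect_error(median_split_analysis(1:3, 1:3, 1:3), "n >= 4")
  # independence: split difference is small relative to the power scale
  tab <- simulate_power_table(1000, coupling_rho = 0, seed = 1)
  ms0 <- median_split_analysis(tab$alpha_power, tab$tag_power_contra, tab$tag_power_ipsi)
  expect_lt(abs(ms0$diff_contra) / mean(tab$tag_power_contra), 0.1)
})

test_that("cohort calibration separates coupled from uncoupled regimes", {
  c0 <- median_split_calibration(20, n_subjects = 10, n_trials = 200, coupling_rho = 0, seed = 2)
  expect_lte(c0$sig_rate_contra, 0.2)
  c5 <- median_split_calibration(20, n_subjects = 10, n_trials = 200, coupling_rho = 0.5, seed = 3)
  expect_gte(c5$sig_rate_contra, 0.8)
})
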