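# Synthetic MEG-like recordings of the covert-attention tagging task.
#
# The generative model, per trial:
#   * a fresh decorrelated pair of broadband tagging drives (left/right
#     hemifield stimuli);
#   * occipital sensors of each hemisphere carry the band-limited
#     (55-75 Hz) drive of the contralateral hemifield, delayed by a fixed
#     sensor latency and scaled by an attention gain (attended hemifield
#     -> contralateral hemisphere gets the larger gain) times a trial-wise
#     log-normal gain factor;
#   * posterior sensors carry an ongoing alpha oscillation (frequency
#     drawn in 8-13 Hz) whose amplitude is lateralized with the opposite
#     sign (contralateral-to-attended decreased) times a trial-wise
#     log-normal amplitude factor;
#   * the two trial-wise factors follow a Gaussian-copula bivariate
#     log-normal with correlation `coupling_rho` (0 = the independence
#     structure the median-split analysis tests);
#   * 1/f background noise of unit RMS on every sensor; `snr` scales the
#     tagging component's RMS relative to it;
#   * photodiode channels record the luminance-mapped drives with zero
#     delay; eye channels record fixation noise.

#' Simulation configuration
#'
#' Collects the generative parameters of [simulate_recording()]. Defaults
#' encode the study conditions: +5% attended-vs-unattended power
#' modulation of the tagging response, -10% modulation of alpha power
#' (amplitude factors are square roots of the power factors), a 50 ms
#' sensor latency, 1000 Hz sampling, and independent trial-wise
#' alpha/tagging factors.
#'
#' @param n_trials Number of trials (default 100).
#' @param n_channels Number of sensors (default 12); split half per
#'   hemisphere, ~80% of each half tagged as occipital.
#' @param fs Sampling rate in Hz.
#' @param latency_true Ground-truth drive-to-sensor delay in ms.
#' @param tagging_gain_attended,tagging_gain_unattended Amplitude gains of
#'   the tagging component by attention condition.
#' @param alpha_amp_ipsi,alpha_amp_contra Alpha amplitudes ipsi/contra to
#'   the attended hemifield.
#' @param alpha_band Alpha frequency range (Hz) the per-trial frequency is
#'   drawn from.
#' @param coupling_rho Gaussian-copula correlation between the trial-wise
#'   alpha-amplitude and tagging-gain factors, in `[-1, 1]`.
#' @param gain_sd,alpha_sd Log-scale SDs of the trial-wise factors.
#' @param noise_exponent Slope of the 1/f background power spectrum.
#' @param snr RMS of the unit-gain tagging component relative to the
#'   broadband noise RMS.
#' @param artifact_rates Named list of per-trial probabilities for
#'   `blink`, `saccade`, `sensor` artifacts (used by [inject_artifacts()]).
#' @param epoch_window Epoch support in seconds around flicker onset.
#' @param tagging_window Interval (s) in which the tagging drive is on.
#' @param carrier_hz,max_abs_corr Tagging-signal generation parameters.
#' @param seed Integer seed or `NULL`.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_trials = 100, n_channels = 12, fs = 1000,
                       latency_true = 50,
                       tagging_gain_attended = sqrt(1.05),
                       tagging_gain_unattended = sqrt(0.95),
                       alpha_amp_ipsi = sqrt(1.10),
                       alpha_amp_contra = sqrt(0.90),
                       alpha_band = c(8, 13), coupling_rho = 0,
                       gain_sd = 0.25, alpha_sd = 0.25,
                       noise_exponent = 1, snr = 0.2,
                       artifact_rates = list(blink = 0, saccade = 0, sensor = 0),
                       epoch_window = c(-1.0, 2.5),
                       tagging_window = c(0, 2),
                       carrier_hz = 65, max_abs_corr = 0.1,
                       seed = NULL) {
  stopifnot(
    n_trials >= 1, n_channels >= 2, fs > 0, latency_true >= 0,
    tagging_gain_attended >= 0, tagging_gain_unattended >= 0,
    alpha_amp_ipsi >= 0, alpha_amp_contra >= 0,
    coupling_rho >= -1, coupling_rho <= 1,
    gain_sd >= 0, alpha_sd >= 0, snr >= 0,
    epoch_window[1] < tagging_window[1], tagging_window[2] < epoch_window[2]
  )
  structure(
    list(
      n_trials = n_trials, n_channels = n_channels, fs = fs,
      latency_true = latency_true,
      tagging_gain_attended = tagging_gain_attended,
      tagging_gain_unattended = tagging_gain_unattended,
      alpha_amp_ipsi = alpha_amp_ipsi, alpha_amp_contra = alpha_amp_contra,
      alpha_band = alpha_band, coupling_rho = coupling_rho,
      gain_sd = gain_sd, alpha_sd = alpha_sd,
      noise_exponent = noise_exponent, snr = snr,
      artifact_rates = artifact_rates,
      epoch_window = epoch_window, tagging_window = tagging_window,
      carrier_hz = carrier_hz, max_abs_corr = max_abs_corr, seed = seed
    ),
    class = "sim_config"
  )
}

#' Abstract sensor layout with hemisphere and group tags
#'
#' @param n_channels Total number of channels, split half/half across
#'   hemispheres; about 80% of each hemisphere's channels are tagged
#'   `occipital`, the rest `other`.
#' @return Data frame with `channel`, `label`, `hemisphere`, `group`.
#' @export
channel_layout <- function(n_channels) {
  stopifnot(n_channels >= 2)
  n_left <- ceiling(n_channels / 2)
  hemi <- rep(c("left", "right"), c(n_left, n_channels - n_left))
  layout <- do.call(rbind, lapply(c("left", "right"), function(h) {
    nh <- sum(hemi == h)
    nocc <- max(1L, round(0.8 * nh))
    grp <- rep(c("occipital", "other"), c(nocc, nh - nocc))
    data.frame(hemisphere = h, group = grp, stringsAsFactors = FALSE)
  }))
  layout$channel <- seq_len(n_channels)
  layout$label <- paste0(
    ifelse(layout$group == "occipital", "O", "M"),
    toupper(substr(layout$hemisphere, 1, 1)),
    stats::ave(layout$channel, layout$hemisphere, layout$group, FUN = seq_along)
  )
  layout[, c("channel", "label", "hemisphere", "group")]
}

#' Draw correlated trial-wise gain and amplitude factors
#'
#' Bivariate log-normal factors with unit mean: underlying standard
#' normals with correlation `rho` (Gaussian copula), exponentiated with
#' their log-scale SDs and mean-corrected.
#'
#' @param n Number of trials.
#' @param rho Copula correlation in `[-1, 1]`.
#' @param gain_sd,alpha_sd Log-scale SDs.
#' @return Data frame with `tag_gain_factor`, `alpha_amp_factor`.
#' @export
draw_trial_factors <- function(n, rho = 0, gain_sd = 0.25, alpha_sd = 0.25) {
  stopifnot(n >= 1, rho >= -1, rho <= 1)
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  data.frame(
    tag_gain_factor = exp(gain_sd * z1 - gain_sd^2 / 2),
    alpha_amp_factor = exp(alpha_sd * z2 - alpha_sd^2 / 2)
  )
}

#' Simulate a multichannel recording of the attention task
#'
#' @param config A [sim_config()].
#' @param trials Optional `trial_table`; generated from the config seed
#'   when omitted.
#' @return A `synthetic_recording`: list with `sensor_data`
#'   (channels x trials x time array), `photodiode` (`left`/`right`
#'   trials x time matrices of displayed luminance), `eye` (`x`/`y`
#'   trials x time), `channels` layout, `trials`, `fs`, `epoch_window`,
#'   `tagging_window`, `ground_truth` (config plus realized per-trial
#'   factors), `labels` (artifact labels, empty until
#'   [inject_artifacts()]), and `schema_version`.
#' @export
simulate_recording <- function(config, trials = NULL) {
  stopifnot(inherits(config, "sim_config"))
  fs <- config$fs
  n_time <- round(diff(config$epoch_window) * fs)
  t <- config$epoch_window[1] + (seq_len(n_time) - 1) / fs
  active <- t >= config$tagging_window[1] & t < config$tagging_window[2]
  tag_duration <- diff(config$tagging_window)
  lat_samp <- round(config$latency_true / 1000 * fs)
  layout <- channel_layout(config$n_channels)
  n_tr <- config$n_trials

  with_rng_seed(config$seed, {
    if (is.null(trials)) {
      trials <- make_trial_table(n_tr, seed = NULL, fs = fs)
    }
    stopifnot(nrow(trials) == n_tr)
    factors <- draw_trial_factors(n_tr, config$coupling_rho,
                                  config$gain_sd, config$alpha_sd)
    factors$alpha_freq <- stats::runif(n_tr, config$alpha_band[1], config$alpha_band[2])

    sensor <- array(0, dim = c(config$n_channels, n_tr, n_time))
    pd_left <- matrix(0.5, n_tr, n_time)
    pd_right <- matrix(0.5, n_tr, n_time)
    eye_x <- matrix(stats::rnorm(n_tr * n_time), n_tr, n_time)
    eye_y <- matrix(stats::rnorm(n_tr * n_time), n_tr, n_time)

    for (k in seq_len(n_tr)) {
      pair <- generate_decorrelated_pair(
        duration = tag_duration, fs = fs, f_c = config$carrier_hz,
        max_abs_corr = config$max_abs_corr
      )
      drive <- list(left = numeric(n_time), right = numeric(n_time))
      drive$left[active] <- pair$left$samples
      drive$right[active] <- pair$right$samples
      pd_left[k, ] <- luminance_map(drive$left)
      pd_right[k, ] <- luminance_map(drive$right)

      # band-limited, delayed, RMS-normalized sensor copies of each drive
      sensor_wave <- lapply(drive, function(d) {
        f <- bandpass_zero_phase(d, 55, 75, fs = fs)
        f <- f / sqrt(mean(f[active]^2))
        delay_signal(f, lat_samp)
      })
      cue <- trials$cue_side[k]
      alpha_phase <- stats::runif(2, 0, 2 * pi)
      alpha_wave <- list(
        left = sin(2 * pi * factors$alpha_freq[k] * t + alpha_phase[1]),
        right = sin(2 * pi * factors$alpha_freq[k] * t + alpha_phase[2])
      )
      for (c_idx in seq_len(config$n_channels)) {
        hemi <- layout$hemisphere[c_idx]
        noise <- one_over_f_noise(n_time, config$noise_exponent, rms = 1)
        x <- noise
        if (layout$group[c_idx] == "occipital") {
          drive_side <- if (hemi == "left") "right" else "left"
          gain <- if (cue == drive_side) config$tagging_gain_attended else config$tagging_gain_unattended
          # alpha amplitude: contra-to-attended hemisphere is the one
          # whose drive side is the cue side
          a_amp <- if (cue == drive_side) config$alpha_amp_contra else config$alpha_amp_ipsi
          x <- x +
            config$snr * gain * factors$tag_gain_factor[k] * sensor_wave[[drive_side]] +
            a_amp * factors$alpha_amp_factor[k] * alpha_wave[[hemi]]
        }
        sensor[c_idx, k, ] <- x
      }
    }
    structure(
      list(
        sensor_data = sensor,
        photodiode = list(left = pd_left, right = pd_right),
        eye = list(x = eye_x, y = eye_y),
        channels = layout, trials = trials, fs = fs,
        epoch_window = config$epoch_window,
        tagging_window = config$tagging_window,
        ground_truth = list(config = config, factors = factors),
        labels = data.frame(
          trial_id = integer(), type = character(),
          stringsAsFactors = FALSE
        ),
        schema_version = RECORDING_SCHEMA_VERSION
      ),
      class = "synthetic_recording"
    )
  })
}

RECORDING_SCHEMA_VERSION <- "1"

#' @export
print.synthetic_recording <- function(x, ...) {
  d <- dim(x$sensor_data)
  cat(sprintf(
    "<synthetic_recording> %d channels x %d trials x %d samples @ %g Hz (epoch %g..%g s)\n",
    d[1], d[2], d[3], x$fs, x$epoch_window[1], x$epoch_window[2]
  ))
  invisible(x)
}

#' Inject ground-truth-labeled artifacts into a recording
#'
#' Adds blink transients to the eye channels (well above the 5 SD
#' detection threshold), sustained fixation departures (saccades) of
#' configurable duration, and high-amplitude sensor events, each on an
#' independent Bernoulli draw per trial. Labels are appended to
#' `recording$labels` so detectors can be scored against ground truth.
#'
#' @param recording A `synthetic_recording`.
#' @param rates Named list of per-trial probabilities: `blink`, `saccade`,
#'   `sensor` (missing entries default to 0).
#' @param seed Integer seed or `NULL`.
#' @param blink_amp Blink amplitude in eye-channel SD units (default 8).
#' @param saccade_duration_ms Length of the fixation departure (default
#'   600; departures shorter than the 500 ms criterion are deliberately
#'   possible and must not be flagged by the detector).
#' @param saccade_offset Gaze offset during the departure, in eye-channel
#'   SD units (default 8, keeping the whole departure outside the
#'   detector's fixation radius despite fixation noise).
#' @param sensor_amp Sensor-event amplitude in channel SD units
#'   (default 10).
#' @return The recording with artifacts added and `labels` filled.
#' @export
inject_artifacts <- function(recording, rates = list(), seed = NULL,
                             blink_amp = 8, saccade_duration_ms = 600,
                             saccade_offset = 8, sensor_amp = 10) {
  stopifnot(inherits(recording, "synthetic_recording"))
  get_rate <- function(nm) {
    r <- rates[[nm]]
    if (is.null(r)) 0 else r
  }
  for (nm in c("blink", "saccade", "sensor")) {
    r <- get_rate(nm)
    if (r < 0 || r > 1) stop("artifact rates must be in [0, 1]", call. = FALSE)
  }
  if (all(vapply(c("blink", "saccade", "sensor"), get_rate, numeric(1)) == 0)) {
    return(recording)
  }
  fs <- recording$fs
  n_tr <- nrow(recording$eye$x)
  n_time <- ncol(recording$eye$x)
  with_rng_seed(seed, {
    labels <- recording$labels
    blink_trials <- which(stats::runif(n_tr) < get_rate("blink"))
    for (k in blink_trials) {
      width <- round(0.1 * fs)
      start <- sample.int(n_time - width, 1)
      pulse <- blink_amp * exp(-((seq_len(width) - width / 2)^2) / (2 * (width / 6)^2))
      idx <- start:(start + width - 1L)
      recording$eye$x[k, idx] <- recording$eye$x[k, idx] + pulse
      recording$eye$y[k, idx] <- recording$eye$y[k, idx] + pulse
      labels <- rbind(labels, data.frame(trial_id = recording$trials$trial_id[k], type = "blink"))
    }
    sac_trials <- which(stats::runif(n_tr) < get_rate("saccade"))
    for (k in sac_trials) {
      width <- round(saccade_duration_ms / 1000 * fs)
      if (width >= n_time) width <- n_time - 1L
      start <- sample.int(n_time - width, 1)
      idx <- start:(start + width - 1L)
      recording$eye$x[k, idx] <- recording$eye$x[k, idx] + saccade_offset
      labels <- rbind(labels, data.frame(trial_id = recording$trials$trial_id[k], type = "saccade"))
    }
    sensor_trials <- which(stats::runif(n_tr) < get_rate("sensor"))
    for (k in sensor_trials) {
      ch <- sample.int(dim(recording$sensor_data)[1], 1)
      width <- round(0.05 * fs)
      start <- sample.int(n_time - width, 1)
      idx <- start:(start + width - 1L)
      ch_sd <- stats::sd(recording$sensor_data[ch, , ])
      recording$sensor_data[ch, k, idx] <-
        recording$sensor_data[ch, k, idx] + sensor_amp * ch_sd
      labels <- rbind(labels, data.frame(trial_id = recording$trials$trial_id[k], type = "sensor"))
    }
    recording$labels <- labels
    recording
  })
}

#' Simulate per-trial band powers from the trial-factor model
#'
#' Reduced form of [simulate_recording()] for trial-wise power analyses:
#' draws the same bivariate log-normal alpha-amplitude and tagging-gain
#' factors and maps them to measured per-trial band powers (squared
#' amplitudes times the attention gains, with multiplicative log-normal
#' measurement noise). Used for the median-split calibration at cohort
#' scale, where full sensor-space simulation is unnecessary.
#'
#' @param n_trials Number of trials.
#' @param coupling_rho Copula correlation between the factors.
#' @param gain_sd,alpha_sd Log-scale SDs of the trial factors.
#' @param meas_sd Log-scale SD of the power measurement noise.
#' @param tagging_gain_attended,tagging_gain_unattended Amplitude gains.
#' @param seed Integer seed or `NULL`.
#' @return Data frame with `trial_id`, `alpha_power`, `tag_power_contra`,
#'   `tag_power_ipsi` (contra/ipsi to the attended hemifield).
#' @export
simulate_power_table <- function(n_trials, coupling_rho = 0,
                                 gain_sd = 0.25, alpha_sd = 0.25,
                                 meas_sd = 0.1,
                                 tagging_gain_attended = sqrt(1.05),
                                 tagging_gain_unattended = sqrt(0.95),
                                 seed = NULL) {
  stopifnot(n_trials >= 1)
  with_rng_seed(seed, {
    f <- draw_trial_factors(n_trials, coupling_rho, gain_sd, alpha_sd)
    noise <- function() exp(meas_sd * stats::rnorm(n_trials) - meas_sd^2 / 2)
    data.frame(
      trial_id = seq_len(n_trials),
      alpha_power = (f$alpha_amp_factor)^2 * noise(),
      tag_power_contra = (tagging_gain_attended * f$tag_gain_factor)^2 * noise(),
      tag_power_ipsi = (tagging_gain_unattended * f$tag_gain_factor)^2 * noise()
    )
  })
}
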