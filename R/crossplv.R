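# Cross phase-locking value (cross-PLV) at lags: coupling strength and
# latency between the tagging drive and sensor signals.
#
# Both signals are band-passed 55-75 Hz (fourth-order Butterworth,
# zero-phase, high-pass then low-pass), their instantaneous phases taken
# from the analytic signal, and PLV = |mean(exp(i(x - y)))| evaluated with
# the sensor phase advanced by each lag in -200..200 ms (1 ms steps at
# 1000 Hz). Per-trial profiles are averaged within condition; the profile
# peak gives the response magnitude and its lag the latency. Positive lag
# means the sensor signal FOLLOWS the drive.
#
# Implementation note: over a fixed analysis window the whole lag profile
# of one trial is |circular cross-correlation| of the two unit-phasor
# series, obtained with three FFTs. Circularly shifting the sensor phasor
# by s shifts that correlation sequence by s, so the circular-shift
# surrogate distribution is read off the same per-trial modulus vectors
# without recomputation.

#' Zero-phase Butterworth band-pass filter
#'
#' Fourth-order high-pass at `lo` followed by fourth-order low-pass at
#' `hi`, each applied forward and backward (`signal::filtfilt`), giving
#' zero net group delay and doubled attenuation.
#'
#' @param x Numeric vector.
#' @param lo,hi Cut-off frequencies in Hz.
#' @param fs Sampling rate in Hz.
#' @param order Filter order per pass (default 4).
#' @return Filtered vector, same length.
#' @export
bandpass_zero_phase <- function(x, lo = 55, hi = 75, fs = 1000, order = 4) {
  if (hi >= fs / 2) {
    stop("band edge at or above Nyquist: need hi < fs/2", call. = FALSE)
  }
  if (lo <= 0 || lo >= hi) stop("need 0 < lo < hi", call. = FALSE)
  bh <- signal::butter(order, lo / (fs / 2), type = "high")
  bl <- signal::butter(order, hi / (fs / 2), type = "low")
  signal::filtfilt(bl, signal::filtfilt(bh, x))
}

#' Instantaneous phase of a band-limited signal
#'
#' Argument of the analytic signal, in `(-pi, pi]`. Call after
#' [bandpass_zero_phase()]; the Hilbert transform is only meaningful for
#' band-limited input.
#'
#' @param x Numeric vector.
#' @return Phase sequence in radians.
#' @export
instantaneous_phase <- function(x) {
  Arg(analytic_signal(x))
}

#' Phase-locking value of two phase sequences
#'
#' `PLV = |mean(exp(i * (x - y)))|`, in `[0, 1]`.
#'
#' @param phase_x,phase_y Phase sequences in radians, equal length.
#' @return PLV scalar.
#' @export
plv <- function(phase_x, phase_y) {
  if (length(phase_x) != length(phase_y)) {
    stop("phase sequences must have equal length", call. = FALSE)
  }
  if (length(phase_x) < 1L) stop("need at least one sample", call. = FALSE)
  Mod(mean(exp(1i * (phase_x - phase_y))))
}

# Unit-phasor series of a band-passed signal.
unit_phasor <- function(x, band, fs, order = 4) {
  a <- analytic_signal(bandpass_zero_phase(x, band[1], band[2], fs = fs, order = order))
  m <- Mod(a)
  m[m == 0] <- 1
  a / m
}

# Per-trial circular-correlation modulus matrix (trials x n_time).
# Row t, entry m+1 = |sum_k u_t[(k+m) mod M] * Conj(v_t[k])| / N, where
# v is masked to the analysis window (N samples). Both the observed lag
# profile and every circular-shift surrogate are reads of this matrix.
crossplv_mod_matrix <- function(meg, tag, fs, time, band, window,
                                edge_exclude_ms, order = 4) {
  if (is.vector(meg)) meg <- matrix(meg, nrow = 1)
  if (is.vector(tag)) tag <- matrix(tag, nrow = 1)
  if (nrow(tag) == 1L && nrow(meg) > 1L) {
    tag <- tag[rep(1L, nrow(meg)), , drop = FALSE]
  }
  stopifnot(nrow(meg) == nrow(tag), ncol(meg) == ncol(tag))
  n_time <- ncol(meg)
  stopifnot(length(time) == n_time)
  edge <- edge_exclude_ms / 1000
  win_idx <- which(time >= window[1] + edge - 1e-9 & time < window[2] - edge - 1e-9)
  if (length(win_idx) < 16L) {
    stop("analysis window (after edge exclusion) too short", call. = FALSE)
  }
  mask <- numeric(n_time)
  mask[win_idx] <- 1
  n_used <- length(win_idx)
  out <- matrix(NA_real_, nrow(meg), n_time)
  for (k in seq_len(nrow(meg))) {
    u <- unit_phasor(meg[k, ], band, fs, order)
    v <- unit_phasor(tag[k, ], band, fs, order) * mask
    cc <- stats::fft(stats::fft(u) * Conj(stats::fft(v)), inverse = TRUE)
    out[k, ] <- Mod(cc) / (n_time * n_used)
  }
  attr(out, "n_samples_used") <- n_used
  attr(out, "win_idx") <- win_idx
  out
}

# Map signed lags (samples) to 1-based circular indices of the
# correlation sequence.
lag_index <- function(lags_samp, n_time) {
  (lags_samp %% n_time) + 1L
}

#' Cross-PLV profile over lags
#'
#' Computes the PLV between the tagging drive and the sensor signal with
#' the sensor phase advanced by each lag, per trial, and averages the
#' per-trial profiles. The analysis window is fixed at `window` (default
#' 0-2 s, the tagging interval) with `edge_exclude_ms` trimmed from both
#' ends of the window before the PLV sum, to keep Hilbert edge distortion
#' out of the estimate. Ties in the profile maximum resolve to the
#' smallest lag.
#'
#' @param meg Sensor signal: vector, or trials x time matrix.
#' @param tag Tagging drive, same shape (a single row is recycled across
#'   trials).
#' @param fs Sampling rate in Hz (default 1000; lags step 1 ms requires
#'   1 kHz).
#' @param time Time axis in seconds (length `ncol`); defaults to the
#'   standard epoch `t_start + (0:(n-1))/fs`.
#' @param t_start Epoch start time used when `time` is missing
#'   (default -1).
#' @param lags_ms Integer lags in ms (default -200..200).
#' @param window Analysis window in seconds (default `c(0, 2)`).
#' @param band Filter band in Hz (default `c(55, 75)`).
#' @param edge_exclude_ms Edge trim within the window (default 100).
#' @param order Butterworth order (default 4).
#' @return A `crossplv_profile`: list with `lags_ms`, `plv`, `peak_plv`,
#'   `peak_lag_ms`, `ci99_threshold` (`NA` until [surrogate_ci()]),
#'   `n_samples_used`, `n_trials`.
#' @export
cross_plv <- function(meg, tag, fs = 1000, time = NULL, t_start = -1,
                      lags_ms = -200:200, window = c(0, 2),
                      band = c(55, 75), edge_exclude_ms = 100, order = 4) {
  if (is.vector(meg)) meg <- matrix(meg, nrow = 1)
  if (is.null(time)) time <- t_start + (seq_len(ncol(meg)) - 1) / fs
  lags_samp <- round(lags_ms / 1000 * fs)
  if (any(abs(lags_samp / fs * 1000 - lags_ms) > 1e-9)) {
    stop("lags must be integer multiples of the sample period", call. = FALSE)
  }
  mods <- crossplv_mod_matrix(meg, tag, fs, time, band, window, edge_exclude_ms, order)
  win_idx <- attr(mods, "win_idx")
  if (min(win_idx) - 1L < max(abs(lags_samp)) ||
      ncol(mods) - max(win_idx) < max(abs(lags_samp))) {
    stop("insufficient epoch margin for the requested lags", call. = FALSE)
  }
  prof <- colMeans(mods[, lag_index(lags_samp, ncol(mods)), drop = FALSE])
  peak <- which.max(prof) # first maximum: ties to the smallest lag
  structure(
    list(
      lags_ms = lags_ms, plv = prof,
      peak_plv = prof[peak], peak_lag_ms = lags_ms[peak],
      ci99_threshold = NA_real_,
      n_samples_used = attr(mods, "n_samples_used"),
      n_trials = nrow(mods),
      band = band, window = window
    ),
    class = "crossplv_profile"
  )
}

#' @export
print.crossplv_profile <- function(x, ...) {
  cat(sprintf(
    "<crossplv_profile> %d trials, peak PLV %.3f at %d ms%s\n",
    x$n_trials, x$peak_plv, x$peak_lag_ms,
    if (is.na(x$ci99_threshold)) "" else sprintf(" (99%% bound %.3f)", x$ci99_threshold)
  ))
  invisible(x)
}

#' Circular-shift surrogate confidence bound for cross-PLV
#'
#' Builds the null distribution of the cross-PLV statistic by circularly
#' shifting each trial's sensor phase series at a random time point
#' (shifts uniform over the epoch, excluding shifts smaller than the
#' largest lag) and recomputing the trial-averaged profile for `n_shifts`
#' shift sets. The default statistic is the max over lags, controlling
#' the multiple-lag family; `statistic = "pointwise"` returns per-lag
#' bounds instead. The level-`level` bound is the k-th order statistic
#' with `k = ceiling(level * (n_shifts + 1))`, capped at `n_shifts`; at
#' the default 100 shifts and level 0.99 this is the largest surrogate,
#' with exceedance probability `1/(n_shifts + 1)` under exchangeability.
#'
#' @inheritParams cross_plv
#' @param n_shifts Number of surrogate shift sets (default 100).
#' @param level Confidence level (default 0.99).
#' @param seed Integer seed or `NULL`.
#' @param statistic `"max"` (max-over-lags, scalar bound) or
#'   `"pointwise"` (per-lag bounds).
#' @return List with `threshold` (scalar, or vector for pointwise),
#'   `surrogate_stats`, `n_shifts`, `level`, `statistic`,
#'   `low_precision` (`TRUE` when `n_shifts` is too small to support the
#'   requested level).
#' @export
surrogate_ci <- function(meg, tag, fs = 1000, time = NULL, t_start = -1,
                         lags_ms = -200:200, window = c(0, 2),
                         band = c(55, 75), edge_exclude_ms = 100,
                         order = 4, n_shifts = 100, level = 0.99,
                         seed = NULL, statistic = c("max", "pointwise")) {
  statistic <- match.arg(statistic)
  stopifnot(n_shifts >= 2, level > 0, level < 1)
  if (is.vector(meg)) meg <- matrix(meg, nrow = 1)
  if (is.null(time)) time <- t_start + (seq_len(ncol(meg)) - 1) / fs
  lags_samp <- round(lags_ms / 1000 * fs)
  mods <- crossplv_mod_matrix(meg, tag, fs, time, band, window, edge_exclude_ms, order)
  res <- surrogate_from_mods(mods, lags_samp, n_shifts, level, seed, statistic)
  res
}

# Shared surrogate machinery operating on a precomputed modulus matrix.
surrogate_from_mods <- function(mods, lags_samp, n_shifts, level, seed, statistic) {
  n_time <- ncol(mods)
  n_tr <- nrow(mods)
  max_lag <- max(abs(lags_samp))
  lag_idx0 <- lag_index(lags_samp, n_time)
  k_order <- ceiling(level * (n_shifts + 1))
  low_precision <- k_order > n_shifts
  if (low_precision) {
    k_order <- n_shifts
    message(
      "surrogate_ci: ", n_shifts, " shifts cannot resolve level ", level,
      "; using the maximum surrogate (low precision)"
    )
  }
  with_rng_seed(seed, {
    # independent random shift per trial per surrogate set
    shifts <- matrix(
      sample.int(n_time - 2L * max_lag - 1L, n_shifts * n_tr, replace = TRUE) + max_lag,
      n_shifts, n_tr
    )
    profs <- matrix(0, n_shifts, length(lags_samp))
    for (tr in seq_len(n_tr)) {
      idx <- outer(-shifts[, tr], lag_idx0 - 1L, `+`) %% n_time + 1L
      profs <- profs + matrix(mods[tr, idx], n_shifts, length(lags_samp))
    }
    profs <- profs / n_tr
    if (statistic == "max") {
      stats_v <- apply(profs, 1, max)
      threshold <- sort(stats_v)[k_order]
    } else {
      stats_v <- profs
      threshold <- apply(profs, 2, function(col) sort(col)[k_order])
    }
    list(
      threshold = threshold, surrogate_stats = stats_v,
      n_shifts = n_shifts, level = level, statistic = statistic,
      low_precision = low_precision
    )
  })
}

#' Cross-PLV profiles for all occipital channels of an epoch set
#'
#' For each occipital channel, uses the photodiode trace of the
#' contralateral hemifield as the drive reference and computes one
#' profile per attention condition (attended: cue contralateral to the
#' channel's hemisphere) plus the surrogate bound on the combined-trials
#' profile.
#'
#' @param epochs An `epoch_set`.
#' @param n_shifts,level,seed Surrogate parameters (see [surrogate_ci()]).
#' @param ... Passed to [cross_plv()].
#' @return List of per-channel entries: `channel`, `label`, `hemisphere`,
#'   `attended`, `unattended` (both `crossplv_profile` with
#'   `ci99_threshold` filled), `combined_peak_plv`.
#' @export
cross_plv_channels <- function(epochs, n_shifts = 100, level = 0.99,
                               seed = NULL, ...) {
  stopifnot(inherits(epochs, "epoch_set"))
  occ <- which(epochs$channels$group == "occipital")
  if (length(occ) == 0L) stop("no occipital channels", call. = FALSE)
  cue <- epochs$trials$cue_side
  out <- lapply(seq_along(occ), function(j) {
    ch <- occ[j]
    hemi <- epochs$channels$hemisphere[ch]
    drive_side <- if (hemi == "left") "right" else "left"
    tag <- epochs$photodiode[[drive_side]]
    meg <- matrix(epochs$data[ch, , ], nrow = dim(epochs$data)[2])
    att <- cue == drive_side
    p_att <- cross_plv(meg[att, , drop = FALSE], tag[att, , drop = FALSE],
      fs = epochs$fs, time = epochs$time, ...
    )
    p_un <- cross_plv(meg[!att, , drop = FALSE], tag[!att, , drop = FALSE],
      fs = epochs$fs, time = epochs$time, ...
    )
    ci <- surrogate_ci(meg, tag,
      fs = epochs$fs, time = epochs$time,
      n_shifts = n_shifts, level = level,
      seed = child_seed(seed, ch), ...
    )
    p_att$ci99_threshold <- ci$threshold
    p_un$ci99_threshold <- ci$threshold
    list(
      channel = epochs$channels$channel[ch],
      label = epochs$channels$label[ch],
      hemisphere = hemi,
      attended = p_att, unattended = p_un,
      combined_peak_plv = mean(c(p_att$peak_plv, p_un$peak_plv))
    )
  })
  out
}

#' Select the strongest-responding channel per hemisphere
#'
#' Picks, within each hemisphere, the channel with the largest
#' condition-averaged peak cross-PLV (blind to the condition difference,
#' avoiding selection bias). Ties resolve to the smallest channel index.
#'
#' @param profiles Output of [cross_plv_channels()].
#' @return Named list `left`/`right` of the selected entries.
#' @export
select_strongest_channel <- function(profiles) {
  hemis <- vapply(profiles, `[[`, character(1), "hemisphere")
  out <- lapply(c(left = "left", right = "right"), function(h) {
    idx <- which(hemis == h)
    if (length(idx) == 0L) stop("empty hemisphere: ", h, call. = FALSE)
    strength <- vapply(profiles[idx], `[[`, numeric(1), "combined_peak_plv")
    chans <- vapply(profiles[idx], `[[`, numeric(1), "channel")
    best <- idx[order(-strength, chans)[1]]
    profiles[[best]]
  })
  out
}

#' Peak latency and magnitude of a cross-PLV profile
#'
#' @param profile A `crossplv_profile` (with `ci99_threshold` filled to
#'   assess reliability).
#' @return List with `latency_ms`, `magnitude`, `reliable` (`TRUE` when
#'   the peak exceeds the surrogate bound; `NA` when no bound is set).
#'   The latency is only meaningful when `reliable` is `TRUE`.
#' @export
latency_and_magnitude <- function(profile) {
  stopifnot(inherits(profile, "crossplv_profile"))
  reliable <- if (is.na(profile$ci99_threshold)) {
    NA
  } else {
    profile$peak_plv > profile$ci99_threshold
  }
  list(
    latency_ms = profile$peak_lag_ms,
    magnitude = profile$peak_plv,
    reliable = reliable
  )
}

#' Monte-Carlo calibration of the surrogate null
#'
#' Repeatedly simulates sensor noise that is independent of a fresh
#' tagging pair, computes the trial-averaged max-over-lags cross-PLV and
#' its circular-shift surrogate bound, and reports how often the observed
#' statistic stays below the bound (nominal: `level`).
#'
#' @param n_runs Number of Monte-Carlo runs (default 200).
#' @param n_trials Trials per run (default 30).
#' @param n_shifts Surrogates per run (default 100).
#' @param level Confidence level (default 0.99).
#' @param seed Integer seed or `NULL`.
#' @param fs Sampling rate (default 1000).
#' @param lags_ms,window,band,edge_exclude_ms As in [cross_plv()].
#' @param noise_exponent 1/f slope of the sensor noise.
#' @return List with `coverage` (fraction below the bound), `exceedance`,
#'   `n_runs`, and the per-run observed statistics and thresholds.
#' @export
surrogate_null_calibration <- function(n_runs = 200, n_trials = 30,
                                       n_shifts = 100, level = 0.99,
                                       seed = NULL, fs = 1000,
                                       lags_ms = -200:200, window = c(0, 2),
                                       band = c(55, 75), edge_exclude_ms = 100,
                                       noise_exponent = 1) {
  epoch_window <- c(-1.0, 2.5)
  n_time <- round(diff(epoch_window) * fs)
  time <- epoch_window[1] + (seq_len(n_time) - 1) / fs
  active <- time >= 0 & time < 2
  lags_samp <- round(lags_ms / 1000 * fs)
  lag_idx0 <- lag_index(lags_samp, n_time)
  with_rng_seed(seed, {
    observed <- threshold <- numeric(n_runs)
    for (r in seq_len(n_runs)) {
      meg <- matrix(NA_real_, n_trials, n_time)
      tag <- matrix(0, n_trials, n_time)
      for (k in seq_len(n_trials)) {
        pair <- generate_decorrelated_pair(duration = 2, fs = fs)
        tag[k, active] <- pair$left$samples
        meg[k, ] <- one_over_f_noise(n_time, noise_exponent)
      }
      mods <- crossplv_mod_matrix(meg, tag, fs, time, band, window, edge_exclude_ms)
      prof <- colMeans(mods[, lag_idx0, drop = FALSE])
      observed[r] <- max(prof)
      sur <- surrogate_from_mods(mods, lags_samp, n_shifts, level,
        seed = NULL, statistic = "max"
      )
      threshold[r] <- sur$threshold
    }
    list(
      coverage = mean(observed < threshold),
      exceedance = mean(observed >= threshold),
      n_runs = n_runs, observed = observed, threshold = threshold
    )
  })
}
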