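# Epoching, artifact rejection, and trial-count equalization.
#
# Epochs span -1.0 to 2.5 s around flicker onset (half-open sample
# convention, 3500 samples at 1000 Hz). Rejection thresholds are z-scores
# computed per channel over all epochs of the dataset (global statistics,
# chosen for stability). Every removal carries a reason code and the log
# reconciles: kept + rejected == input.

#' Epoch a recording
#'
#' Cuts (or re-windows) the per-trial data to `window` seconds around
#' flicker onset. Samples follow the half-open convention
#' `[window[1], window[2])`, so the default window holds exactly
#' `3.5 * fs` samples and `t = 0` is the first in-stimulus sample.
#'
#' @param recording A `synthetic_recording`.
#' @param window Epoch window in seconds relative to flicker onset;
#'   must lie within the recording's support.
#' @return An `epoch_set`: list with `data` (channels x trials x samples),
#'   `eye`, `photodiode`, `channels`, `trials`, `fs`, `time` (sample time
#'   axis), `t0_index`, `kept_trial_ids`, `rejection_log`, `labels`.
#' @export
epoch <- function(recording, window = c(-1.0, 2.5)) {
  stopifnot(inherits(recording, "synthetic_recording"))
  if (length(window) != 2L || !is.numeric(window) || window[1] >= window[2]) {
    stop("invalid epoch window: need window[1] < window[2]", call. = FALSE)
  }
  sup <- recording$epoch_window
  if (window[1] < sup[1] - 1e-9 || window[2] > sup[2] + 1e-9) {
    stop(
      sprintf(
        "epoch out of bounds: window [%g, %g] s exceeds the recorded support [%g, %g] s",
        window[1], window[2], sup[1], sup[2]
      ),
      call. = FALSE
    )
  }
  fs <- recording$fs
  full_t <- sup[1] + (seq_len(dim(recording$sensor_data)[3]) - 1) / fs
  keep <- full_t >= window[1] - 1e-9 & full_t < window[2] - 1e-9
  time <- full_t[keep]
  t0 <- which(time >= -1e-9)[1]
  structure(
    list(
      data = recording$sensor_data[, , keep, drop = FALSE],
      eye = list(x = recording$eye$x[, keep, drop = FALSE],
                 y = recording$eye$y[, keep, drop = FALSE]),
      photodiode = list(left = recording$photodiode$left[, keep, drop = FALSE],
                        right = recording$photodiode$right[, keep, drop = FALSE]),
      channels = recording$channels,
      trials = recording$trials,
      fs = fs, time = time, t0_index = t0,
      tagging_window = recording$tagging_window,
      kept_trial_ids = recording$trials$trial_id,
      rejection_log = data.frame(
        trial_id = integer(), reason = character(), stringsAsFactors = FALSE
      ),
      labels = recording$labels,
      ground_truth = recording$ground_truth
    ),
    class = "epoch_set"
  )
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoch_set> %d channels x %d trials x %d samples @ %g Hz (%d rejected)\n",
    d[1], d[2], d[3], x$fs, nrow(x$rejection_log)
  ))
  invisible(x)
}

# Drop trials (by position) from an epoch set, logging a reason code.
drop_trials <- function(epochs, drop_idx, reason) {
  if (length(drop_idx) == 0L) {
    return(epochs)
  }
  ids <- epochs$kept_trial_ids[drop_idx]
  epochs$rejection_log <- rbind(
    epochs$rejection_log,
    data.frame(trial_id = ids, reason = reason, stringsAsFactors = FALSE)
  )
  keep <- setdiff(seq_along(epochs$kept_trial_ids), drop_idx)
  epochs$data <- epochs$data[, keep, , drop = FALSE]
  epochs$eye$x <- epochs$eye$x[keep, , drop = FALSE]
  epochs$eye$y <- epochs$eye$y[keep, , drop = FALSE]
  epochs$photodiode$left <- epochs$photodiode$left[keep, , drop = FALSE]
  epochs$photodiode$right <- epochs$photodiode$right[keep, , drop = FALSE]
  epochs$trials <- epochs$trials[epochs$trials$trial_id %in% epochs$kept_trial_ids[keep], , drop = FALSE]
  if (!is.null(epochs$ground_truth$factors)) {
    epochs$ground_truth$factors <- epochs$ground_truth$factors[keep, , drop = FALSE]
  }
  epochs$kept_trial_ids <- epochs$kept_trial_ids[keep]
  epochs
}

#' Flag trials containing eye blinks
#'
#' A trial is flagged when either eye channel, z-scored with per-channel
#' mean and SD pooled over all epochs, exceeds `threshold_sd` anywhere in
#' the epoch.
#'
#' @param epochs An `epoch_set`.
#' @param threshold_sd Z-score threshold (default 5).
#' @return Logical vector, one flag per kept trial.
#' @export
detect_blinks <- function(epochs, threshold_sd = 5) {
  stopifnot(threshold_sd > 0)
  flag_eye <- function(m) {
    s <- stats::sd(as.vector(m))
    if (s == 0) {
      warning("constant eye channel: nothing flagged", call. = FALSE)
      return(rep(FALSE, nrow(m)))
    }
    z <- abs((m - mean(m)) / s)
    apply(z, 1, max) > threshold_sd
  }
  flag_eye(epochs$eye$x) | flag_eye(epochs$eye$y)
}

#' Flag trials containing saccades (sustained fixation departures)
#'
#' A trial is flagged when gaze distance from the fixation point exceeds
#' `fixation_radius` for more than `min_away_ms` contiguous milliseconds.
#'
#' @param epochs An `epoch_set`.
#' @param fixation_radius Radius in eye-channel units (default 3, i.e.
#'   3 SD of fixation noise).
#' @param min_away_ms Minimum contiguous departure duration (default 500).
#' @return Logical vector, one flag per kept trial.
#' @export
detect_saccades <- function(epochs, fixation_radius = 3, min_away_ms = 500) {
  stopifnot(min_away_ms > 0, fixation_radius > 0)
  min_samples <- min_away_ms / 1000 * epochs$fs
  r <- sqrt(epochs$eye$x^2 + epochs$eye$y^2)
  apply(r > fixation_radius, 1, function(away) {
    if (!any(away)) {
      return(FALSE)
    }
    runs <- rle(away)
    any(runs$lengths[runs$values] > min_samples)
  })
}

#' Remove trials flagged by the eye-channel detectors
#'
#' Convenience wrapper running [detect_blinks()] and [detect_saccades()]
#' and dropping flagged trials with reason codes `blink` / `saccade`.
#'
#' @param epochs An `epoch_set`.
#' @param blink_threshold_sd,fixation_radius,min_away_ms Detector
#'   parameters.
#' @return The pruned `epoch_set`.
#' @export
reject_eye_artifacts <- function(epochs, blink_threshold_sd = 5,
                                 fixation_radius = 3, min_away_ms = 500) {
  blinks <- detect_blinks(epochs, blink_threshold_sd)
  epochs <- drop_trials(epochs, which(blinks), "blink")
  saccades <- detect_saccades(epochs, fixation_radius, min_away_ms)
  drop_trials(epochs, which(saccades), "saccade")
}

#' Reject trials with large-amplitude sensor events
#'
#' Removes trials in which any sensor sample, z-scored per channel over
#' all epochs, exceeds `threshold_sd`. The attached attribute
#' `expected_false_rate` gives the Gaussian-tail probability that a clean
#' trial is falsely rejected at this threshold and epoch size.
#'
#' @param epochs An `epoch_set`.
#' @param threshold_sd Z-score threshold (default 5; `Inf` disables).
#' @return The pruned `epoch_set`.
#' @export
reject_amplitude <- function(epochs, threshold_sd = 5) {
  stopifnot(threshold_sd > 0)
  d <- dim(epochs$data)
  if (is.infinite(threshold_sd)) {
    return(epochs)
  }
  flagged <- rep(FALSE, d[2])
  for (ch in seq_len(d[1])) {
    x <- epochs$data[ch, , , drop = TRUE]
    if (d[2] == 1L) x <- matrix(x, nrow = 1)
    s <- stats::sd(as.vector(x))
    if (s == 0) next
    z <- abs((x - mean(x)) / s)
    flagged <- flagged | (apply(z, 1, max) > threshold_sd)
  }
  if (all(flagged)) {
    stop(
      sprintf(
        "amplitude rejection removed all %d trials at %g SD; check the data scale",
        d[2], threshold_sd
      ),
      call. = FALSE
    )
  }
  out <- drop_trials(epochs, which(flagged), "amplitude")
  attr(out, "expected_false_rate") <-
    1 - (1 - 2 * stats::pnorm(-threshold_sd))^(d[1] * d[3])
  out
}

#' Equalize trial counts across conditions
#'
#' Downsamples every condition, without replacement, to the smallest
#' condition count.
#'
#' @param epochs An `epoch_set`.
#' @param condition_labels Vector of condition labels, one per kept trial
#'   (default: cue side from the trial table).
#' @param seed Integer seed or `NULL`.
#' @return The equalized `epoch_set`.
#' @export
equalize_trials <- function(epochs, condition_labels = NULL, seed = NULL) {
  if (is.null(condition_labels)) {
    condition_labels <- epochs$trials$cue_side
  }
  stopifnot(length(condition_labels) == length(epochs$kept_trial_ids))
  counts <- table(condition_labels)
  if (any(counts == 0) || length(counts) == 0) {
    empty <- names(counts)[counts == 0]
    stop("empty condition: ", paste(empty, collapse = ", "), call. = FALSE)
  }
  n_min <- min(counts)
  with_rng_seed(seed, {
    drop_idx <- unlist(lapply(names(counts), function(cond) {
      idx <- which(condition_labels == cond)
      if (length(idx) > n_min) {
        setdiff(idx, sort(sample(idx, n_min)))
      } else {
        integer()
      }
    }))
    drop_trials(epochs, drop_idx, "equalization")
  })
}
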