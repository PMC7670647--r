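# Band power, the attention modulation index, and the median-split
# independence analysis.
#
# Spectral power uses a single periodic Hann taper on the 0-2 s segment
# (0.5 Hz resolution at 1000 Hz). Band power is the sum over in-band bins
# of 2*|X_k|^2 / (sum w)^2, a one-sided amplitude-squared convention under
# which a unit sinusoid centered in the band contributes 0.75 (carrier bin
# 0.5 plus two Hann side bins of 0.125); doubling the amplitude quadruples
# the power. AMI = (P_att - P_unatt) / (P_att + P_unatt), in [-1, 1].

#' Per-trial band power of every channel
#'
#' Single-Hann-taper Fourier power of the `window` segment of each epoch,
#' summed over the frequency bins inside `band`.
#'
#' @param epochs An `epoch_set`.
#' @param band Frequency band `c(lo, hi)` in Hz.
#' @param window Analysis window in seconds relative to flicker onset
#'   (default `c(0, 2)`, half-open).
#' @return Matrix `channels x trials` of non-negative powers, with the
#'   band as attribute `"band"`.
#' @export
epoch_band_power <- function(epochs, band, window = c(0, 2)) {
  stopifnot(inherits(epochs, "epoch_set"), length(band) == 2L)
  fs <- epochs$fs
  if (band[1] < 0 || band[1] >= band[2] || band[2] > fs / 2) {
    stop("invalid band: need 0 <= lo < hi <= fs/2", call. = FALSE)
  }
  idx <- which(epochs$time >= window[1] - 1e-9 & epochs$time < window[2] - 1e-9)
  if (length(idx) < 4L) {
    stop("analysis window outside the epoch or too short", call. = FALSE)
  }
  n <- length(idx)
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n)) # periodic Hann
  norm <- sum(w)^2
  freqs <- (seq_len(floor(n / 2))) * fs / n
  in_band <- which(freqs >= band[1] & freqs <= band[2]) + 1L # skip DC bin
  d <- dim(epochs$data)
  out <- matrix(NA_real_, d[1], d[2])
  for (ch in seq_len(d[1])) {
    seg <- matrix(epochs$data[ch, , idx], nrow = d[2])
    seg <- sweep(seg, 2, w, `*`)
    sp <- stats::mvfft(t(seg))
    out[ch, ] <- colSums(2 * Mod(sp[in_band, , drop = FALSE])^2) / norm
  }
  dimnames(out) <- list(epochs$channels$label, epochs$kept_trial_ids)
  attr(out, "band") <- band
  out
}

#' Attention modulation index
#'
#' `AMI = (P_attended - P_unattended) / (P_attended + P_unattended)`,
#' vectorized; antisymmetric in its arguments, invariant to a common
#' rescaling, and bounded in `[-1, 1]`. Pairs with zero total power give
#' `NA` with a warning.
#'
#' @param p_attended,p_unattended Non-negative powers (same length).
#' @return AMI values in `[-1, 1]` (or `NA` where undefined).
#' @export
ami <- function(p_attended, p_unattended) {
  stopifnot(length(p_attended) == length(p_unattended))
  if (any(p_attended < 0 | p_unattended < 0, na.rm = TRUE)) {
    stop("powers must be non-negative", call. = FALSE)
  }
  tot <- p_attended + p_unattended
  out <- ifelse(tot > 0, (p_attended - p_unattended) / tot, NA_real_)
  if (any(tot == 0, na.rm = TRUE)) {
    warning("AMI undefined where both powers are zero; returning NA", call. = FALSE)
  }
  out
}

#' Per-channel AMI map for a band
#'
#' For every channel, trials are classed as *attended* when the cue points
#' to the hemifield contralateral to the channel's hemisphere, and the AMI
#' of trial-mean band power is computed.
#'
#' @param epochs An `epoch_set` with hemisphere-tagged channels.
#' @param band Frequency band `c(lo, hi)` in Hz.
#' @param band_name Label stored with the result.
#' @param window Analysis window in seconds.
#' @return An `ami_map` data frame: `channel`, `label`, `hemisphere`,
#'   `group`, `band`, `ami`.
#' @export
ami_map <- function(epochs, band, band_name = paste(band, collapse = "-"),
                    window = c(0, 2)) {
  pw <- epoch_band_power(epochs, band, window)
  cue <- epochs$trials$cue_side
  layout <- epochs$channels
  if (is.null(layout$hemisphere)) stop("channels lack hemisphere tags", call. = FALSE)
  att_cue <- ifelse(layout$hemisphere == "left", "right", "left")
  vals <- vapply(seq_len(nrow(layout)), function(ch) {
    att <- cue == att_cue[ch]
    ami(mean(pw[ch, att]), mean(pw[ch, !att]))
  }, numeric(1))
  out <- data.frame(
    channel = layout$channel, label = layout$label,
    hemisphere = layout$hemisphere, group = layout$group,
    band = band_name, ami = vals, stringsAsFactors = FALSE
  )
  class(out) <- c("ami_map", "data.frame")
  out
}

#' Combine per-channel AMI into a per-subject scalar
#'
#' Averages AMI over occipital channels within each hemisphere (both
#' computed with the contralateral-attended convention, so the canonical
#' attention effect has the same sign in both) and then averages the two
#' hemisphere values into one signed scalar.
#'
#' @param map An `ami_map`.
#' @param group Channel group to combine over (default `"occipital"`).
#' @return Single signed AMI value.
#' @export
combine_hemisphere_ami <- function(map, group = "occipital") {
  stopifnot(inherits(map, "data.frame"))
  m <- map[map$group == group, ]
  hemis <- unique(m$hemisphere)
  if (!all(c("left", "right") %in% hemis)) {
    missing_h <- setdiff(c("left", "right"), hemis)
    stop("missing hemisphere: ", paste(missing_h, collapse = ", "), call. = FALSE)
  }
  per_hemi <- tapply(m$ami, m$hemisphere, mean)
  mean(per_hemi[c("left", "right")])
}

#' Median-split analysis of tagging power by alpha power
#'
#' Splits trials at the median of per-trial alpha power (ties and, for odd
#' counts, the median trial go to the low bin) and returns the mean
#' tagging power per bin for the channel groups ipsi- and contralateral to
#' the attended hemifield, plus the high-minus-low differences that feed
#' the group-level paired test.
#'
#' @param alpha_power Per-trial alpha power.
#' @param tag_power_contra,tag_power_ipsi Per-trial tagging power of the
#'   contra-/ipsilateral (to attention) channel groups.
#' @return A `median_split` list: bin means, `diff_contra`, `diff_ipsi`,
#'   and bin sizes.
#' @export
median_split_analysis <- function(alpha_power, tag_power_contra, tag_power_ipsi) {
  n <- length(alpha_power)
  stopifnot(
    n >= 4, length(tag_power_contra) == n, length(tag_power_ipsi) == n
  )
  if (stats::sd(alpha_power) == 0) {
    warning("degenerate split: all alpha powers identical", call. = FALSE)
  }
  ord <- order(alpha_power, seq_len(n)) # stable: ties to the low bin
  n_low <- ceiling(n / 2)
  low <- ord[seq_len(n_low)]
  high <- ord[(n_low + 1L):n]
  res <- list(
    low_contra = mean(tag_power_contra[low]),
    high_contra = mean(tag_power_contra[high]),
    low_ipsi = mean(tag_power_ipsi[low]),
    high_ipsi = mean(tag_power_ipsi[high]),
    n_low = length(low), n_high = length(high)
  )
  res$diff_contra <- res$high_contra - res$low_contra
  res$diff_ipsi <- res$high_ipsi - res$low_ipsi
  class(res) <- "median_split"
  res
}

#' Cohort-level calibration of the median-split analysis
#'
#' Simulates `n_cohorts` cohorts of `n_subjects` subjects, each subject a
#' trial-factor power table with coupling `coupling_rho`, applies the
#' median split per subject, and tests the per-subject high-minus-low
#' tagging-power differences against zero with a paired (one-sample)
#' t-test. Returns the fraction of cohorts significant at `alpha_level`,
#' separately for the contra- and ipsilateral groups.
#'
#' @param n_cohorts Number of simulated cohorts.
#' @param n_subjects Subjects per cohort (default 18).
#' @param n_trials Trials per subject (default 500).
#' @param coupling_rho Alpha/tagging trial-factor coupling.
#' @param alpha_level Significance level (default 0.05).
#' @param seed Integer seed or `NULL`.
#' @param ... Passed to [simulate_power_table()].
#' @return List with `sig_rate_contra`, `sig_rate_ipsi`, `n_cohorts`.
#' @export
median_split_calibration <- function(n_cohorts, n_subjects = 18,
                                     n_trials = 500, coupling_rho = 0,
                                     alpha_level = 0.05, seed = NULL, ...) {
  with_rng_seed(seed, {
    sig <- matrix(NA, n_cohorts, 2)
    for (cc in seq_len(n_cohorts)) {
      diffs <- vapply(seq_len(n_subjects), function(s) {
        tab <- simulate_power_table(n_trials, coupling_rho, ...)
        ms <- median_split_analysis(tab$alpha_power, tab$tag_power_contra, tab$tag_power_ipsi)
        c(ms$diff_contra, ms$diff_ipsi)
      }, numeric(2))
      sig[cc, 1] <- stats::t.test(diffs[1, ])$p.value < alpha_level
      sig[cc, 2] <- stats::t.test(diffs[2, ])$p.value < alpha_level
    }
    list(
      sig_rate_contra = mean(sig[, 1]), sig_rate_ipsi = mean(sig[, 2]),
      n_cohorts = n_cohorts
    )
  })
}
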