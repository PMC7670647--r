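# Broadband phase-modulated tagging signals.
#
# The luminance drive is a constant-amplitude phase-modulated carrier
#   s(t) = sin(2*pi*f_c*t + sum_{i=1..3} sin(2*pi*i*t + phi_i)),
# with a 65 Hz carrier and modulation tones at 1, 2 and 3 Hz. The
# instantaneous frequency is f_c + sum_i i*cos(2*pi*i*t + phi_i), so the
# excursion is bounded by +/- 6 Hz and the signal occupies roughly
# 60-70 Hz while keeping unit envelope (no amplitude modulation).

#' Generate a broadband phase-modulated tagging signal
#'
#' Produces the luminance-modulation waveform used to frequency-tag one
#' visual stimulus: a sinusoidal carrier at `f_c` whose phase is modulated
#' by `n_tones` low-frequency tones (1..n_tones Hz) with random phase
#' offsets. With the default three tones the instantaneous frequency stays
#' within `f_c` +/- 6 Hz and the envelope is constant.
#'
#' By default the tone phase offsets are drawn uniformly on `[0, 2*pi)`,
#' which is what makes independently generated signals decorrelate (see
#' [generate_decorrelated_pair()]). `strict_printed_form = TRUE` instead
#' draws `r_i` uniform on `[0, 1]` and uses `r_i / 4` as offsets plus a
#' constant `+1` inside the modulation sine; offsets confined to a
#' quarter-radian make independent draws nearly identical, so this mode
#' exists for comparison only.
#'
#' @param duration Signal duration in seconds (default 2).
#' @param fs Sampling rate in Hz (default 1000).
#' @param f_c Carrier frequency in Hz (default 65).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param n_tones Number of phase-modulation tones at 1..n_tones Hz.
#' @param phase_offsets Optional fixed phase offsets (radians), length
#'   `n_tones`; overrides the random draw.
#' @param strict_printed_form Use the quarter-radian phase-offset variant.
#' @return A `tagging_signal` object: list with `samples` (in `[-1, 1]`),
#'   `fs`, `f_c`, `phase_offsets`, `duration`, `seed`.
#' @examples
#' sig <- generate_tagging_signal(seed = 1)
#' length(sig$samples)
#' @export
generate_tagging_signal <- function(duration = 2, fs = 1000, f_c = 65,
                                    seed = NULL, n_tones = 3,
                                    phase_offsets = NULL,
                                    strict_printed_form = FALSE) {
  if (!is.numeric(duration) || duration <= 0) {
    stop("`duration` must be positive", call. = FALSE)
  }
  if (!is.numeric(fs) || fs <= 0) {
    stop("`fs` must be positive", call. = FALSE)
  }
  if (!is.numeric(f_c) || f_c <= 0) {
    stop("`f_c` must be positive", call. = FALSE)
  }
  if (fs <= 2 * (f_c + 2 * n_tones)) {
    stop(
      "`fs` too low for the tagged band: need fs > 2 * (f_c + ",
      2 * n_tones, ") Hz to avoid aliasing",
      call. = FALSE
    )
  }
  offsets <- phase_offsets
  constant <- 0
  if (is.null(offsets)) {
    offsets <- with_rng_seed(seed, {
      if (strict_printed_form) stats::runif(n_tones) / 4 else stats::runif(n_tones, 0, 2 * pi)
    })
  }
  if (length(offsets) != n_tones) {
    stop("`phase_offsets` must have length `n_tones`", call. = FALSE)
  }
  if (strict_printed_form) constant <- 1
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  modulation <- rowSums(vapply(
    seq_len(n_tones),
    function(i) sin(2 * pi * i * t + offsets[i] + constant),
    numeric(n)
  ))
  samples <- sin(2 * pi * f_c * t + modulation)
  structure(
    list(
      samples = samples, fs = fs, f_c = f_c,
      phase_offsets = offsets, duration = duration, seed = seed
    ),
    class = "tagging_signal"
  )
}

#' @export
print.tagging_signal <- function(x, ...) {
  cat(sprintf(
    "<tagging_signal> %.3g s @ %g Hz, carrier %g Hz, %d tones\n",
    x$duration, x$fs, x$f_c, length(x$phase_offsets)
  ))
  invisible(x)
}

#' Generate a decorrelated pair of tagging signals
#'
#' Draws two independent tagging signals (left and right stimulus drives)
#' and redraws the pair until the absolute Pearson correlation of their
#' samples over the full duration is below `max_abs_corr`. The number of
#' rejected draws is attached as attribute `"rejections"`.
#'
#' @inheritParams generate_tagging_signal
#' @param max_abs_corr Acceptance threshold on `|cor|` (default 0.1).
#' @param max_attempts Rejection budget before failing (default 1000).
#' @return List with elements `left` and `right` (both `tagging_signal`),
#'   attribute `rejections`.
#' @examples
#' pair <- generate_decorrelated_pair(seed = 1)
#' abs(cor(pair$left$samples, pair$right$samples)) < 0.1
#' @export
generate_decorrelated_pair <- function(duration = 2, fs = 1000, f_c = 65,
                                       max_abs_corr = 0.1, seed = NULL,
                                       n_tones = 3, max_attempts = 1000) {
  if (!is.numeric(max_abs_corr) || max_abs_corr <= 0 || max_abs_corr >= 1) {
    stop("`max_abs_corr` must be in (0, 1)", call. = FALSE)
  }
  with_rng_seed(seed, {
    rejections <- 0L
    repeat {
      left <- generate_tagging_signal(duration, fs, f_c, seed = NULL, n_tones = n_tones)
      right <- generate_tagging_signal(duration, fs, f_c, seed = NULL, n_tones = n_tones)
      if (abs(stats::cor(left$samples, right$samples)) < max_abs_corr) break
      rejections <- rejections + 1L
      if (rejections >= max_attempts) {
        stop(
          sprintf(
            "tagging-pair generation failed: %d draws rejected at |cor| >= %g",
            rejections, max_abs_corr
          ),
          call. = FALSE
        )
      }
    }
    structure(list(left = left, right = right), rejections = rejections)
  })
}

#' Map a tagging signal to displayable luminance
#'
#' Affine map of the `[-1, 1]` modulation onto `[0, 1]` luminance,
#' `(s + 1) / 2`; this is what the photodiode channels record.
#'
#' @param signal A `tagging_signal`, or a numeric vector in `[-1, 1]`.
#' @return Numeric vector in `[0, 1]`.
#' @export
luminance_map <- function(signal) {
  s <- if (inherits(signal, "tagging_signal")) signal$samples else signal
  if (any(s < -1 - 1e-12 | s > 1 + 1e-12)) {
    stop("samples must lie in [-1, 1]", call. = FALSE)
  }
  (s + 1) / 2
}

#' Fraction of spectral power inside a frequency band
#'
#' Computes the periodogram of the samples and returns the fraction of
#' total non-DC power falling in `[lo, hi]`. Validation helper for the
#' 60-70 Hz spectral-support contract of the tagging signals.
#'
#' @param signal A `tagging_signal`, or a numeric vector (then `fs` is
#'   required).
#' @param lo,hi Band edges in Hz, `0 <= lo < hi <= fs/2`.
#' @param fs Sampling rate, taken from the object when omitted.
#' @return Fraction in `[0, 1]`.
#' @export
band_energy_fraction <- function(signal, lo, hi, fs = NULL) {
  s <- if (inherits(signal, "tagging_signal")) signal$samples else signal
  if (is.null(fs)) {
    if (!inherits(signal, "tagging_signal")) {
      stop("`fs` required for a bare numeric signal", call. = FALSE)
    }
    fs <- signal$fs
  }
  if (!is.numeric(lo) || !is.numeric(hi) || lo < 0 || lo >= hi || hi > fs / 2) {
    stop("invalid band: need 0 <= lo < hi <= fs/2", call. = FALSE)
  }
  n <- length(s)
  pw <- Mod(stats::fft(s))^2
  kmax <- floor(n / 2)
  freqs <- (1:kmax) * fs / n
  pw <- pw[2:(kmax + 1L)]
  sum(pw[freqs >= lo & freqs <= hi]) / sum(pw)
}

#' Frequency of the spectral peak
#'
#' Location (Hz) of the maximum periodogram bin, excluding DC. Frequency
#' resolution is `fs / length(samples)` (0.5 Hz for the default 2 s).
#'
#' @inheritParams band_energy_fraction
#' @return Peak frequency in Hz.
#' @export
spectral_peak_frequency <- function(signal, fs = NULL) {
  s <- if (inherits(signal, "tagging_signal")) signal$samples else signal
  if (is.null(fs)) {
    if (!inherits(signal, "tagging_signal")) {
      stop("`fs` required for a bare numeric signal", call. = FALSE)
    }
    fs <- signal$fs
  }
  n <- length(s)
  pw <- Mod(stats::fft(s))^2
  kmax <- floor(n / 2)
  which.max(pw[2:(kmax + 1L)]) * fs / n
}
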