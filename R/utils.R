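# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded package functions do not
#' disturb the caller's random stream. A `NULL` seed evaluates the
#' expression under the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_rng_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number or NULL", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and an index, kept below 2^31.
child_seed <- function(seed, index) {
  if (is.null(seed)) {
    return(NULL)
  }
  (as.integer(seed) * 1009L + as.integer(index)) %% 2147483647L
}

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' Returns the complex analytic signal `x + i H(x)` of a real series,
#' computed by zeroing negative frequencies of the FFT. The instantaneous
#' phase and envelope used throughout the phase-locking analyses are the
#' argument and modulus of this series.
#'
#' @param x Real numeric vector.
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  if (!is.numeric(x) || length(x) < 2L) {
    stop("`x` must be a numeric vector of length >= 2", call. = FALSE)
  }
  n <- length(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1
    h[n / 2L + 1L] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::fft(stats::fft(x) * h, inverse = TRUE) / n
}

#' Generate 1/f ("pink-like") background noise
#'
#' Spectrally shaped Gaussian noise with amplitude spectrum proportional to
#' `f^(-exponent/2)`, i.e. power ~ `1/f^exponent`, zero DC, scaled to a
#' target RMS. Used as the broadband background of the synthetic sensors.
#'
#' @param n Number of samples.
#' @param exponent Spectral slope of the power spectrum (default 1).
#' @param rms Target root-mean-square amplitude (default 1).
#' @return Numeric vector of length `n`.
#' @export
one_over_f_noise <- function(n, exponent = 1, rms = 1) {
  stopifnot(is.numeric(n), n >= 2, is.numeric(exponent), rms >= 0)
  n <- as.integer(n)
  x <- stats::rnorm(n)
  sp <- stats::fft(x)
  # frequency index of each FFT bin (symmetric for real input)
  k <- c(0L, seq_len(n - 1L))
  k <- pmin(k, n - k)
  scale <- c(0, k[-1L]^(-exponent / 2))
  y <- Re(stats::fft(sp * scale, inverse = TRUE) / n)
  s <- stats::sd(y)
  if (s == 0) {
    return(rep(0, n))
  }
  y * (rms / sqrt(mean(y^2)))
}

# Shift a vector forward by `lag` samples, zero-padding at the start
# (positive lag delays the signal).
delay_signal <- function(x, lag) {
  lag <- as.integer(lag)
  n <- length(x)
  if (lag == 0L) {
    return(x)
  }
  if (lag > 0L) {
    c(numeric(lag), x[seq_len(n - lag)])
  } else {
    c(x[(-lag + 1L):n], numeric(-lag))
  }
}
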