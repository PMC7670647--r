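# Independent reference implementations used as oracles. These are
# deliberately naive (explicit loops, textbook formulas) and must stay
# independent of the package's computational paths.

# PLV by explicit per-sample accumulation.
naive_plv <- function(phase_x, phase_y) {
  acc <- 0 + 0i
  for (k in seq_along(phase_x)) {
    acc <- acc + exp(1i * (phase_x[k] - phase_y[k]))
  }
  Mod(acc / length(phase_x))
}

# Cross-PLV profile by a per-lag loop over precomputed phases.
naive_crossplv_profile <- function(phi_meg, phi_tag, win_idx, lags_samp) {
  vapply(lags_samp, function(L) {
    naive_plv(phi_meg[win_idx + L], phi_tag[win_idx])
  }, numeric(1))
}

# Paired t statistic from the textbook formula.
naive_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  tstat <- m / (s / sqrt(n))
  list(t = tstat, df = n - 1, p = 2 * stats::pt(-abs(tstat), n - 1))
}

# Average ranks with ties, computed by explicit comparison counts.
naive_ranks <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    less <- sum(x < x[i])
    eq <- sum(x == x[i])
    less + (eq + 1) / 2
  }, numeric(1))
}

# Spearman rho as the Pearson correlation of tie-averaged ranks,
# via the raw sum formula.
naive_spearman_rho <- function(x, y) {
  rx <- naive_ranks(x)
  ry <- naive_ranks(y)
  mx <- mean(rx)
  my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# Unwrap a phase sequence (cumulative sum of principal-value increments).
unwrap_phase <- function(p) {
  d <- diff(p)
  d <- (d + pi) %% (2 * pi) - pi
  cumsum(c(p[1], d))
}

# Minimal epoch_set built directly from arrays, for noiseless
# closed-form checks of the spectral operations.
make_epoch_set <- function(data, fs = 1000, t_start = -1,
                           cue_side = NULL, layout = NULL) {
  d <- dim(data)
  if (is.null(layout)) layout <- rifttag::channel_layout(d[1])
  if (is.null(cue_side)) cue_side <- rep(c("left", "right"), length.out = d[2])
  time <- t_start + (seq_len(d[3]) - 1) / fs
  trials <- data.frame(
    trial_id = seq_len(d[2]), cue_side = cue_side,
    stringsAsFactors = FALSE
  )
  structure(
    list(
      data = data,
      eye = list(
        x = matrix(0, d[2], d[3]),
        y = matrix(0, d[2], d[3])
      ),
      photodiode = list(
        left = matrix(0.5, d[2], d[3]),
        right = matrix(0.5, d[2], d[3])
      ),
      channels = layout, trials = trials, fs = fs, time = time,
      t0_index = which(time >= -1e-9)[1],
      tagging_window = c(0, 2),
      kept_trial_ids = seq_len(d[2]),
      rejection_log = data.frame(
        trial_id = integer(), reason = character(),
        stringsAsFactors = FALSE
      ),
      labels = data.frame(
        trial_id = integer(), type = character(),
        stringsAsFactors = FALSE
      ),
      ground_truth = list()
    ),
    class = "epoch_set"
  )
}

# Integer-sample delay with zero padding (positive lag delays x).
delay_signal_for_test <- function(x, lag) {
  n <- length(x)
  if (lag == 0) return(x)
  if (lag > 0) c(numeric(lag), x[seq_len(n - lag)]) else c(x[(-lag + 1):n], numeric(-lag))
}
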