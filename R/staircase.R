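# QUEST adaptive staircase for target-duration control.
#
# A Bayesian staircase over log-duration: the threshold of an assumed
# Weibull psychometric function is given a Gaussian prior on a dB grid
# (dB = 20*log10(duration in ms)), the posterior is updated after every
# response, and the next target duration is placed at the posterior mean,
# clamped to the permitted range. The psychometric is shifted so that the
# probability of a correct response AT threshold equals the accuracy set
# point (0.80), which is where the staircase converges.

#' Initialize a QUEST staircase state
#'
#' @param start_ms First proposed target duration in ms (default 10).
#' @param target_accuracy Accuracy set point the staircase converges to
#'   (default 0.80).
#' @param range_ms Clamp for proposed durations in ms (default `c(2, 30)`).
#' @param grid_ms Support of the threshold grid in ms (default `c(1, 50)`).
#' @param grid_step_db Grid resolution in dB (default 0.1).
#' @param beta Weibull slope of the assumed psychometric (dB units).
#' @param delta Lapse rate.
#' @param gamma Guess rate (0 for a detection task with misses).
#' @param prior_sd_db SD of the Gaussian prior on threshold (dB).
#' @return A `quest_state` object.
#' @export
quest_init <- function(start_ms = 10, target_accuracy = 0.80,
                       range_ms = c(2, 30), grid_ms = c(1, 50),
                       grid_step_db = 0.1, beta = 3.5, delta = 0.01,
                       gamma = 0, prior_sd_db = 5) {
  stopifnot(
    start_ms > 0, target_accuracy > gamma, target_accuracy < 1,
    length(range_ms) == 2L, range_ms[1] > 0, range_ms[1] < range_ms[2],
    length(grid_ms) == 2L, grid_ms[1] > 0, grid_ms[1] < grid_ms[2],
    grid_step_db > 0, beta > 0, delta >= 0, delta < 1, gamma >= 0
  )
  grid_db <- seq(20 * log10(grid_ms[1]), 20 * log10(grid_ms[2]), by = grid_step_db)
  prior_mean_db <- 20 * log10(start_ms)
  log_post <- stats::dnorm(grid_db, prior_mean_db, prior_sd_db, log = TRUE)
  # Shift epsilon so that P(correct | x = threshold) == target_accuracy.
  p_at_eps <- (target_accuracy - delta * gamma) / (1 - delta)
  if (p_at_eps >= 1) stop("target accuracy unattainable for this lapse rate", call. = FALSE)
  epsilon <- 20 / beta * log10(-log((1 - p_at_eps) / (1 - gamma)))
  structure(
    list(
      grid_db = grid_db, log_post = log_post, epsilon = epsilon,
      beta = beta, delta = delta, gamma = gamma,
      target_accuracy = target_accuracy, range_ms = range_ms,
      start_ms = start_ms, last_x_db = NULL, n_updates = 0L
    ),
    class = "quest_state"
  )
}

# Assumed Weibull psychometric on the dB scale.
quest_p_correct <- function(state, x_db, threshold_db) {
  u <- 10^(state$beta * (x_db - threshold_db + state$epsilon) / 20)
  state$delta * state$gamma +
    (1 - state$delta) * (1 - (1 - state$gamma) * exp(-u))
}

#' Advance the QUEST staircase one step
#'
#' Updates the threshold posterior with the outcome of the last presented
#' target (when `last_correct` is not `NULL`) and proposes the next target
#' duration: the posterior-mean threshold mapped back to ms and clamped to
#' the permitted range. Before any response the proposal is the configured
#' starting duration.
#'
#' @param state A `quest_state` from [quest_init()].
#' @param last_correct `TRUE`/`FALSE` outcome of the last proposed target,
#'   or `NULL` before the first response.
#' @return List with `state` (updated) and `duration_ms` (next proposal).
#' @export
quest_staircase_step <- function(state, last_correct = NULL) {
  stopifnot(inherits(state, "quest_state"))
  if (!is.null(last_correct)) {
    if (is.null(state$last_x_db)) {
      stop("no pending proposal to update: call once with last_correct = NULL first",
        call. = FALSE
      )
    }
    p <- quest_p_correct(state, state$last_x_db, state$grid_db)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    state$log_post <- state$log_post + if (isTRUE(last_correct)) log(p) else log(1 - p)
    state$log_post <- state$log_post - max(state$log_post)
    state$n_updates <- state$n_updates + 1L
  }
  if (state$n_updates == 0L) {
    duration <- state$start_ms
  } else {
    w <- exp(state$log_post)
    t_hat_db <- sum(w * state$grid_db) / sum(w)
    duration <- 10^(t_hat_db / 20)
    duration <- min(max(duration, state$range_ms[1]), state$range_ms[2])
  }
  state$last_x_db <- 20 * log10(duration)
  list(state = state, duration_ms = duration)
}

#' Logistic observer in log-duration
#'
#' Returns a function `duration_ms -> TRUE/FALSE` that responds correctly
#' with probability `plogis(slope * (log(d) - log(threshold_ms)))`. Draws
#' from the current RNG stream.
#'
#' @param threshold_ms Duration at 50% correct (default 8 ms).
#' @param slope Logistic slope per log-unit of duration (default 3).
#' @return A function of one argument (duration in ms).
#' @export
make_logistic_observer <- function(threshold_ms = 8, slope = 3) {
  stopifnot(threshold_ms > 0, slope > 0)
  function(duration_ms) {
    p <- stats::plogis(slope * (log(duration_ms) - log(threshold_ms)))
    stats::runif(1) < p
  }
}

#' Run a closed-loop staircase simulation
#'
#' Repeatedly proposes target durations with [quest_staircase_step()],
#' judges each with the observer, and feeds the outcome back.
#'
#' @param n_trials Number of target presentations.
#' @param observer Function `duration_ms -> logical`, e.g. from
#'   [make_logistic_observer()].
#' @param seed Integer seed or `NULL`.
#' @param ... Passed to [quest_init()].
#' @return Data frame with columns `trial`, `duration_ms`, `correct`.
#' @export
run_staircase <- function(n_trials, observer = make_logistic_observer(),
                          seed = NULL, ...) {
  stopifnot(n_trials >= 1)
  with_rng_seed(seed, {
    state <- quest_init(...)
    duration <- numeric(n_trials)
    correct <- logical(n_trials)
    last <- NULL
    for (k in seq_len(n_trials)) {
      step <- quest_staircase_step(state, last)
      state <- step$state
      duration[k] <- step$duration_ms
      correct[k] <- observer(step$duration_ms)
      last <- correct[k]
    }
    data.frame(trial = seq_len(n_trials), duration_ms = duration, correct = correct)
  })
}
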