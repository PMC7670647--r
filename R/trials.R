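# Trial tables and the behavioral observer.
#
# Each trial cues covert attention to the left or right hemifield; both
# hemifields then display a tagged stimulus for 2 s. A brief target occurs
# at the end of 25% of trials: 20% on the cued side (to be reported) and
# 5% on the uncued side (catch trials, to be ignored). Target durations
# are controlled by the QUEST staircase.

#' Build a randomized trial table with exact category counts
#'
#' Category counts (valid-side target, catch target, no target) are fixed
#' by largest-remainder apportionment of the configured proportions, never
#' drawn binomially, so the design fractions hold exactly whenever
#' `n_trials` times each proportion is an integer. Cue sides are balanced
#' 50/50 (largest remainder again for odd counts) and trial order is
#' randomized by `seed`. Onsets are spaced by the 2 s stimulus plus the
#' task's fixation/cue epochs and a jittered 800 +/- 200 ms inter-trial
#' interval.
#'
#' @param n_trials Number of trials.
#' @param p_valid Fraction of trials with a target on the cued side
#'   (default 0.20).
#' @param p_catch Fraction with a target on the uncued side (default 0.05).
#' @param seed Integer seed or `NULL`.
#' @param fs Sampling rate used for `onset_sample` (default 1000).
#' @return A `trial_table` data frame: `trial_id`, `cue_side`,
#'   `target_present`, `target_side`, `valid_cue_target`,
#'   `target_duration_ms` (NA until the observer runs), `response`,
#'   `onset_sample`.
#' @examples
#' tt <- make_trial_table(1000, seed = 1)
#' table(tt$target_side)
#' @export
make_trial_table <- function(n_trials, p_valid = 0.20, p_catch = 0.05,
                             seed = NULL, fs = 1000) {
  stopifnot(n_trials >= 1, p_valid >= 0, p_catch >= 0)
  if (p_valid + p_catch > 1) {
    stop("impossible proportions: p_valid + p_catch > 1", call. = FALSE)
  }
  counts <- largest_remainder(n_trials, c(valid = p_valid, catch = p_catch,
                                          none = 1 - p_valid - p_catch))
  category <- rep(names(counts), counts)
  n_left <- largest_remainder(n_trials, c(left = 0.5, right = 0.5))[["left"]]
  with_rng_seed(seed, {
    category <- sample(category)
    cue_side <- sample(rep(c("left", "right"), c(n_left, n_trials - n_left)))
    target_present <- category != "none"
    target_side <- ifelse(
      category == "valid", cue_side,
      ifelse(category == "catch", ifelse(cue_side == "left", "right", "left"), "none")
    )
    # pre-trial epochs (fix 500 + cue 150 + fix 350), 2 s stimulus, jittered ITI
    iti <- stats::runif(n_trials, 0.6, 1.0)
    gaps <- round((1.0 + 2.5 + iti) * fs)
    onset <- round(1.0 * fs) + c(0L, cumsum(gaps[-n_trials]))
    structure(
      data.frame(
        trial_id = seq_len(n_trials),
        cue_side = cue_side,
        target_present = target_present,
        target_side = target_side,
        valid_cue_target = category == "valid",
        target_duration_ms = NA_real_,
        response = "none",
        onset_sample = as.integer(onset),
        stringsAsFactors = FALSE
      ),
      class = c("trial_table", "data.frame")
    )
  })
}

# Largest-remainder apportionment of n among named proportions.
# Ties on the remainder are broken in the order the proportions are given.
largest_remainder <- function(n, props) {
  exact <- n * props
  base <- floor(exact)
  short <- n - sum(base)
  if (short > 0) {
    rem <- exact - base
    take <- order(-rem, seq_along(rem))[seq_len(short)]
    base[take] <- base[take] + 1
  }
  stats::setNames(as.integer(base), names(props))
}

#' Fill behavioral responses using a staircase-driven observer
#'
#' Walks the trial table in presentation order, proposes a target duration
#' from the QUEST staircase for every target trial, and judges valid-side
#' targets with a logistic observer in log-duration (hit/miss). The
#' staircase is updated only by responses to valid-side targets. Catch
#' trials (target on the uncued side, which must be ignored) elicit a
#' false alarm with probability `fa_rate`, otherwise a correct rejection.
#'
#' @param trials A `trial_table` from [make_trial_table()].
#' @param threshold_ms,slope Observer psychometric parameters; see
#'   [make_logistic_observer()].
#' @param fa_rate Probability of responding on a catch trial (default 0.02).
#' @param seed Integer seed or `NULL`.
#' @param ... Passed to [quest_init()].
#' @return The trial table with `target_duration_ms` and `response` filled.
#' @export
simulate_observer <- function(trials, threshold_ms = 8, slope = 3,
                              fa_rate = 0.02, seed = NULL, ...) {
  stopifnot(inherits(trials, "data.frame"))
  with_rng_seed(seed, {
    observer <- make_logistic_observer(threshold_ms, slope)
    state <- quest_init(...)
    last <- NULL
    for (k in seq_len(nrow(trials))) {
      if (!trials$target_present[k]) {
        trials$response[k] <- "none"
        next
      }
      step <- quest_staircase_step(state, last)
      state <- step$state
      trials$target_duration_ms[k] <- step$duration_ms
      if (trials$valid_cue_target[k]) {
        hit <- observer(step$duration_ms)
        trials$response[k] <- if (hit) "hit" else "miss"
        last <- hit
      } else {
        trials$response[k] <- if (stats::runif(1) < fa_rate) "false_alarm" else "correct_reject"
        # staircase not updated: participants do not respond to catch targets
      }
    }
    trials
  })
}

#' Behavioral summary of a responded trial table
#'
#' @param trials A trial table with responses filled.
#' @return List with `hit_rate` (valid-side targets), `false_alarm_rate`
#'   (catch trials) and trial counts.
#' @export
behavior_summary <- function(trials) {
  valid <- trials$valid_cue_target
  catch <- trials$target_present & !trials$valid_cue_target
  list(
    hit_rate = if (any(valid)) mean(trials$response[valid] == "hit") else NA_real_,
    false_alarm_rate = if (any(catch)) mean(trials$response[catch] == "false_alarm") else NA_real_,
    n_valid = sum(valid), n_catch = sum(catch), n_trials = nrow(trials)
  )
}

#' Write / read a trial table as CSV
#'
#' Plain-CSV round trip preserving the documented column schema and types.
#'
#' @param trials A trial table.
#' @param path File path.
#' @return `read_trial_table` returns the `trial_table` data frame.
#' @export
write_trial_table <- function(trials, path) {
  utils::write.csv(as.data.frame(trials), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  tt <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = c(
    trial_id = "integer", cue_side = "character", target_present = "logical",
    target_side = "character", valid_cue_target = "logical",
    target_duration_ms = "numeric", response = "character",
    onset_sample = "integer"
  ))
  class(tt) <- c("trial_table", "data.frame")
  tt
}
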