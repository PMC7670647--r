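# Epoching and rejection rules.

small_rec <- function(n_trials = 12, n_channels = 4, seed = 1, ...) {
  simulate_recording(sim_config(
    n_trials = n_trials, n_channels = n_channels, seed = seed, ...
  ))
}

test_that("epoching follows the half-open -1.0..2.5 s convention", {
  ep <- epoch(small_rec(4))
  expect_equal(dim(ep$data)[3], 3500)
  expect_equal(ep$time[1], -1)
  expect_equal(ep$time[ep$t0_index], 0)
  expect_lt(max(ep$time), 2.5)
  # narrower window re-cuts consistently
  ep2 <- epoch(small_rec(4), window = c(0, 2))
  expect_equal(dim(ep2$data)[3], 2000)
  expect_error(epoch(small_rec(4), window = c(0, 0)), "invalid epoch window")
  expect_error(epoch(small_rec(4), window = c(-2, 2.5)), "out of bounds")
})

test_that("blink detection is sensitive and specific on labeled data", {
  rec <- inject_artifacts(small_rec(80, 2, seed = 2), list(blink = 0.3), seed = 3)
  ep <- epoch(rec)
  flags <- detect_blinks(ep)
  truth <- ep$trials$trial_id %in% rec$labels$trial_id[rec$labels$type == "blink"]
  expect_gt(sum(truth), 10)
  sens <- sum(flags & truth) / sum(truth)
  fpr <- sum(flags & !truth) / sum(!truth)
  expect_gte(sens, 0.95)
  expect_lte(fpr, 0.05)
  # constant eye channel: warn, flag nothing
  ep$eye$x[] <- 0
  ep$eye$y[] <- 0
  expect_warning(expect_warning(f0 <- detect_blinks(ep), "constant"), "constant")
  expect_false(any(f0))
})

test_that("saccade criterion is the 500 ms sustained departure", {
  rec6 <- inject_artifacts(small_rec(10, 2, seed = 4),
    list(saccade = 1), seed = 5, saccade_duration_ms = 600
  )
  expect_true(all(detect_saccades(epoch(rec6))))
  rec4 <- inject_artifacts(small_rec(10, 2, seed = 4),
    list(saccade = 1), seed = 5, saccade_duration_ms = 400
  )
  expect_false(any(detect_saccades(epoch(rec4))))
  # continuous fixation: nothing flagged
  expect_false(any(detect_saccades(epoch(small_rec(10, 2, seed = 4)))))
})

test_that("amplitude rejection removes spiked trials and reconciles counts", {
  rec <- small_rec(12, 3, seed = 6)
  # 10 SD event in trial 5
  s <- stats::sd(rec$sensor_data[1, , ])
  rec$sensor_data[1, 5, 100:120] <- 10 * s
  ep <- reject_amplitude(epoch(rec), 5)
  expect_false(5 %in% ep$kept_trial_ids)
  expect_true("amplitude" %in% ep$rejection_log$reason)
  expect_equal(length(ep$kept_trial_ids) + nrow(ep$rejection_log), 12)
  expect_gt(attr(ep, "expected_false_rate"), 0)
  expect_lt(attr(ep, "expected_false_rate"), 0.05)
  # infinite threshold is a no-op
  ep_inf <- reject_amplitude(epoch(rec), Inf)
  expect_equal(length(ep_inf$kept_trial_ids), 12)
  # idempotence: re-applying the rule removes nothing new
  ep2 <- reject_amplitude(ep, 5)
  expect_equal(ep2$kept_trial_ids, ep$kept_trial_ids)
  # everything rejected is a hard error
  rec$sensor_data[2, , 50] <- 100 * stats::sd(rec$sensor_data[2, , ])
  expect_error(reject_amplitude(epoch(rec), 5), "all")
})

test_that("equalization downsamples to the minimum condition count", {
  ep <- epoch(small_rec(20, 2, seed = 7))
  labels <- rep(c("attL", "attR"), c(12, 8))
  eq <- equalize_trials(ep, labels, seed = 1)
  kept_labels <- labels[match(eq$kept_trial_ids, ep$kept_trial_ids)]
  expect_equal(unname(table(kept_labels)["attL"]), 8, ignore_attr = TRUE)
  expect_equal(unname(table(kept_labels)["attR"]), 8, ignore_attr = TRUE)
  expect_true(all(eq$rejection_log$reason == "equalization"))
  # equal counts: nothing removed
  eq2 <- equalize_trials(ep, rep(c("a", "b"), 10), seed = 1)
  expect_equal(length(eq2$kept_trial_ids), 20)
  # an empty condition is named in the error
  expect_error(
    equalize_trials(ep, factor(rep("a", 20), levels = c("a", "b")), seed = 1),
    "empty condition: b"
  )
})

test_that("eye-artifact rejection wrapper logs reason codes and reconciles", {
  rec <- inject_artifacts(small_rec(40, 2, seed = 8),
    list(blink = 0.2, saccade = 0.2), seed = 9
  )
  ep <- reject_eye_artifacts(epoch(rec))
  expect_true(all(ep$rejection_log$reason %in% c("blink", "saccade")))
  expect_equal(length(ep$kept_trial_ids) + nrow(ep$rejection_log), 40)
  expect_gt(nrow(ep$rejection_log), 0)
})
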