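#!/usr/bin/env Rscript
# Behavioral simulation: QUEST staircase convergence and the trial-table
# design fractions, with hit and false-alarm rates of the simulated
# observer.

suppressPackageStartupMessages(library(rifttag))
dir.create("results", showWarnings = FALSE)

# staircase convergence across 20 observers
conv <- do.call(rbind, lapply(1:20, function(s) {
  run <- run_staircase(200, make_logistic_observer(threshold_ms = 8, slope = 3), seed = s)
  data.frame(
    seed = s,
    acc_last100 = mean(run$correct[101:200]),
    final_duration = run$duration_ms[200]
  )
}))
write.csv(conv, "results/staircase_convergence.csv", row.names = FALSE)

# full behavioral session
tt <- simulate_observer(make_trial_table(1000, seed = 1), seed = 2)
write_trial_table(tt, "results/trial_table.csv")
bs <- behavior_summary(tt)

cat(sprintf(
  paste0(
    "Staircase: accuracy over last 100 of 200 trials = %.1f%% (set point 80%%)\n",
    "Trial table (n = 1000): %d targets (%d valid, %d catch)\n",
    "Observer: hit rate %.1f%%, catch false-alarm rate %.1f%%\n"
  ),
  100 * mean(conv$acc_last100),
  sum(tt$target_present), sum(tt$valid_cue_target),
  sum(tt$target_present & !tt$valid_cue_target),
  100 * bs$hit_rate, 100 * bs$false_alarm_rate
))
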