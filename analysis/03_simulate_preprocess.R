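#!/usr/bin/env Rscript
# Simulate one subject's recording with artifacts, write it to the
# container, and run the preprocessing chain (epoching, blink/saccade and
# amplitude rejection, condition equalization), reporting the rejection
# bookkeeping.

suppressPackageStartupMessages(library(rifttag))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(n_trials = 120, n_channels = 8, seed = 42)
rec <- simulate_recording(cfg)
rec <- inject_artifacts(rec,
  rates = list(blink = 0.05, saccade = 0.05, sensor = 0.03), seed = 43
)
write_recording(rec, "results/example_recording.rds")

ep <- epoch(rec, c(-1.0, 2.5))
ep <- reject_eye_artifacts(ep)
ep <- reject_amplitude(ep, 5)
ep <- equalize_trials(ep, seed = 44)
write.csv(ep$rejection_log, "results/rejection_log.csv", row.names = FALSE)

injected <- table(rec$labels$type)
removed <- table(ep$rejection_log$reason)
cat(sprintf(
  paste0(
    "Simulated %d trials, %d channels (epoch -1.0..2.5 s, %d samples).\n",
    "Injected artifacts: %s\n",
    "Removed: %s\n",
    "Surviving after equalization: %d trials (%d per cue side)\n"
  ),
  cfg$n_trials, cfg$n_channels, dim(ep$data)[3],
  paste(names(injected), injected, sep = "=", collapse = ", "),
  paste(names(removed), removed, sep = "=", collapse = ", "),
  length(ep$kept_trial_ids), length(ep$kept_trial_ids) / 2
))
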