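#!/usr/bin/env Rscript
# Cross-PLV latency estimation: lag profiles against the photodiode
# reference, surrogate confidence bounds, latency parameter recovery,
# and the null calibration of the surrogate test.

suppressPackageStartupMessages(library(rifttag))
dir.create("results", showWarnings = FALSE)

# lag profile of one subject's strongest channels
cfg <- sim_config(n_trials = 100, n_channels = 6, latency_true = 50, seed = 42)
ep <- epoch(simulate_recording(cfg))
profs <- cross_plv_channels(ep, n_shifts = 100, seed = 1)
sel <- select_strongest_channel(profs)
prof_tab <- do.call(rbind, lapply(c("left", "right"), function(h) {
  e <- sel[[h]]
  rbind(
    data.frame(
      hemisphere = h, condition = "attended", lag_ms = e$attended$lags_ms,
      plv = e$attended$plv, ci99 = e$attended$ci99_threshold
    ),
    data.frame(
      hemisphere = h, condition = "unattended", lag_ms = e$unattended$lags_ms,
      plv = e$unattended$plv, ci99 = e$unattended$ci99_threshold
    )
  )
}))
write.csv(prof_tab, "results/crossplv_profiles.csv", row.names = FALSE)

# latency parameter recovery at three injected delays
recovery <- do.call(rbind, lapply(c(37, 50, 83), function(lat) {
  lags <- vapply(1:10, function(r) {
    c2 <- sim_config(
      n_trials = 100, n_channels = 2, latency_true = lat,
      seed = 500 + 13 * lat + r
    )
    e2 <- epoch(simulate_recording(c2))
    ch <- which(e2$channels$hemisphere == "left")[1]
    meg <- matrix(e2$data[ch, , ], nrow = 100)
    cross_plv(meg, e2$photodiode$right, fs = 1000, time = e2$time)$peak_lag_ms
  }, numeric(1))
  data.frame(
    latency_true = lat, mean_recovered = mean(lags),
    bias = mean(lags) - lat, sd = stats::sd(lags)
  )
}))
write.csv(recovery, "results/latency_recovery.csv", row.names = FALSE)

# null calibration of the surrogate bound (reduced: 100 runs here)
cal <- surrogate_null_calibration(n_runs = 100, n_trials = 30, n_shifts = 100, seed = 9)
write.csv(
  data.frame(observed = cal$observed, threshold = cal$threshold),
  "results/surrogate_null.csv",
  row.names = FALSE
)

lm_l <- latency_and_magnitude(sel$left$attended)
cat(sprintf(
  paste0(
    "Strongest left channel: peak PLV %.3f at %d ms (99%% bound %.3f, reliable: %s)\n",
    "Latency recovery (10 runs each): bias %s ms, SD %s ms\n",
    "Surrogate null calibration: %.1f%% coverage over %d runs (nominal 99%%)\n"
  ),
  lm_l$magnitude, lm_l$latency_ms, sel$left$attended$ci99_threshold, lm_l$reliable,
  paste(sprintf("%+.2f", recovery$bias), collapse = "/"),
  paste(sprintf("%.2f", recovery$sd), collapse = "/"),
  100 * cal$coverage, cal$n_runs
))
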