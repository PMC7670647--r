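#!/usr/bin/env Rscript
# Characterize the broadband tagging-signal generator: spectral support,
# envelope constancy, and left/right pair decorrelation.

suppressPackageStartupMessages(library(rifttag))
dir.create("results", showWarnings = FALSE)

seeds <- 1:50
stats_tab <- do.call(rbind, lapply(seeds, function(s) {
  sig <- generate_tagging_signal(duration = 2, fs = 1000, f_c = 65, seed = s)
  env <- Mod(analytic_signal(sig$samples))
  data.frame(
    seed = s,
    peak_hz = spectral_peak_frequency(sig),
    frac_55_75 = band_energy_fraction(sig, 55, 75),
    frac_60_70 = band_energy_fraction(sig, 60, 70),
    env_dev = max(abs(env[100:1900] - 1))
  )
}))
pairs_tab <- do.call(rbind, lapply(seeds, function(s) {
  pair <- generate_decorrelated_pair(seed = 1000 + s)
  data.frame(
    seed = s,
    abs_corr = abs(stats::cor(pair$left$samples, pair$right$samples)),
    rejections = attr(pair, "rejections")
  )
}))

write.csv(stats_tab, "results/tagging_signal_spectra.csv", row.names = FALSE)
write.csv(pairs_tab, "results/tagging_pair_decorrelation.csv", row.names = FALSE)

cat(sprintf(
  paste0(
    "Tagging signals (n = %d seeds):\n",
    "  periodogram peak: %g-%g Hz (phase-averaged carrier at 65 Hz)\n",
    "  power in 55-75 Hz: min %.4f\n",
    "  envelope deviation: max %.2e (pure phase modulation)\n",
    "Pairs: max |corr| = %.4f, mean rejections/pair = %.2f\n"
  ),
  length(seeds), min(stats_tab$peak_hz), max(stats_tab$peak_hz),
  min(stats_tab$frac_55_75), max(stats_tab$env_dev),
  max(pairs_tab$abs_corr), mean(pairs_tab$rejections)
))
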