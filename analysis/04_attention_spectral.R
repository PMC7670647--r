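#!/usr/bin/env Rscript
# Attention effects on band power: per-channel AMI maps for the alpha
# (8-13 Hz) and tagging (55-75 Hz) bands, and the trial median-split
# test of alpha/tagging independence.

suppressPackageStartupMessages(library(rifttag))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(n_trials = 120, n_channels = 8, seed = 42)
ep <- epoch(simulate_recording(cfg))

maps <- rbind(ami_map(ep, c(8, 13), "alpha"), ami_map(ep, c(55, 75), "tagging"))
write.csv(as.data.frame(maps), "results/ami_maps.csv", row.names = FALSE)

alpha_comb <- combine_hemisphere_ami(maps[maps$band == "alpha", ])
tag_comb <- combine_hemisphere_ami(maps[maps$band == "tagging", ])

# trial-wise powers for the median split
pw_a <- epoch_band_power(ep, c(8, 13))
pw_t <- epoch_band_power(ep, c(55, 75))
occ <- ep$channels$group == "occipital"
contra <- ifelse(ep$trials$cue_side == "left", "right", "left")
alpha_tr <- colMeans(pw_a[occ, , drop = FALSE])
tag_c <- vapply(seq_along(contra), function(k) {
  mean(pw_t[occ & ep$channels$hemisphere == contra[k], k])
}, numeric(1))
tag_i <- vapply(seq_along(contra), function(k) {
  mean(pw_t[occ & ep$channels$hemisphere != contra[k], k])
}, numeric(1))
ms <- median_split_analysis(alpha_tr, tag_c, tag_i)

# cohort-scale calibration of the split under independence and coupling
cal0 <- median_split_calibration(100, 18, 500, coupling_rho = 0, seed = 7)
cal5 <- median_split_calibration(100, 18, 500, coupling_rho = 0.5, seed = 8)
write.csv(
  data.frame(
    coupling_rho = c(0, 0.5),
    sig_rate_contra = c(cal0$sig_rate_contra, cal5$sig_rate_contra),
    sig_rate_ipsi = c(cal0$sig_rate_ipsi, cal5$sig_rate_ipsi)
  ),
  "results/median_split_calibration.csv",
  row.names = FALSE
)

cat(sprintf(
  paste0(
    "Hemisphere-combined AMI: alpha %.3f (injected -10%% power), ",
    "tagging %.3f (injected +5%%, diluted by in-band noise)\n",
    "Median split (this subject): contra diff %.3f, ipsi diff %.3f\n",
    "Cohort calibration (100 cohorts x 18 subjects): significant fraction\n",
    "  rho = 0.0: contra %.2f, ipsi %.2f (nominal 0.05)\n",
    "  rho = 0.5: contra %.2f, ipsi %.2f (power)\n"
  ),
  alpha_comb, tag_comb, ms$diff_contra, ms$diff_ipsi,
  cal0$sig_rate_contra, cal0$sig_rate_ipsi,
  cal5$sig_rate_contra, cal5$sig_rate_ipsi
))
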