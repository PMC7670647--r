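# rifttag

Simulation and analysis of **rapid invisible frequency tagging (RIFT)**
experiments on covert spatial attention.

RIFT drives a visual stimulus's luminance with a broadband signal above
the flicker-fusion threshold (60–70 Hz), so the visual-cortex response
can be identified by its phase locking to the drive without perceptible
flicker. In a task with one tagged stimulus per hemifield, attention is
expected to (a) suppress posterior alpha power (8–13 Hz) contralateral to
the attended side, (b) enhance the contralateral tagging response, with
trial-by-trial alpha power and tagging power nevertheless independent,
and (c) modulate the *magnitude* but not the *latency* of the tagged
response. This package is for researchers who want a fully
ground-truth-controlled testbed for that analysis chain: it generates the
stimuli, behavior, and MEG-like recordings, and implements the complete
sensor-level analysis with calibration suites.

## What is inside

* **Tagging signals** — constant-envelope phase-modulated drives,
  `s(t) = sin(2π f_c t + Σ_{i=1..3} sin(2π i t + φ_i))` with `f_c = 65`
  Hz, and left/right pairs rejected until `|corr| < 0.1` over the 2 s
  stimulus.
* **Behavior** — exact-proportion trial tables (25% targets: 20% valid,
  5% catch), a QUEST staircase (start 10 ms, clamp 2–30 ms, 80% set
  point), and a logistic observer.
* **Recordings** — channels × trials × time epochs (−1.0..2.5 s,
  1000 Hz): contralateral band-limited drives delayed by a ground-truth
  latency and scaled by attention gains, lateralized alpha with the
  opposite attention sign, configurable trial-wise alpha/tagging coupling
  (Gaussian copula), 1/f noise, photodiode and eye channels, labeled
  artifacts.
* **Preprocessing** — epoching, 5 SD blink and amplitude rejection,
  500 ms saccade criterion, seeded condition equalization, full
  rejection bookkeeping.
* **Spectral** — Hann-taper band power,
  `AMI = (P_att − P_unatt)/(P_att + P_unatt)` per channel and combined
  per subject, and the alpha median-split test of tagging power.
* **Cross-PLV** — `PLV(ℓ) = |mean exp(i(x_{t+ℓ} − y_t))|` over lags
  −200..200 ms against the photodiode reference, peak magnitude and
  latency, and a circular-shift surrogate 99% bound (max-over-lags
  statistic).
* **Group level** — paired t-tests (PLV, latency, median split),
  Spearman AMI correlations, and a one-call cohort pipeline
  (`run_pipeline()`) that is bit-reproducible from its config.

## Worked example

```r
library(rifttag)

cfg <- sim_config(n_trials = 60, n_channels = 4, latency_true = 50, seed = 1)
rec <- simulate_recording(cfg)
ep  <- epoch(rec)

# attention modulation of band power (hemisphere-combined, per subject)
alpha <- combine_hemisphere_ami(ami_map(ep, c(8, 13), "alpha"))
tagg  <- combine_hemisphere_ami(ami_map(ep, c(55, 75), "tagging"))
cat(sprintf("alpha AMI: %+.3f   tagging AMI: %+.3f\n", alpha, tagg))
#> alpha AMI: -0.091   tagging AMI: +0.021

# latency of the tagged response on one left-hemisphere channel
ch  <- which(ep$channels$hemisphere == "left" & ep$channels$group == "occipital")[1]
meg <- matrix(ep$data[ch, , ], nrow = 60)
prof <- cross_plv(meg, ep$photodiode$right, fs = 1000, time = ep$time)
ci <- surrogate_ci(meg, ep$photodiode$right, fs = 1000, time = ep$time,
                   n_shifts = 100, seed = 2)
prof$ci99_threshold <- ci$threshold
print(prof)
#> <crossplv_profile> 60 trials, peak PLV 0.633 at 50 ms (99% bound 0.217)
```

Reading the numbers: the generator injected a −10% alpha power
modulation (measured −0.091 here), a +5% tagging-component modulation
(measured +0.021 — band power includes in-band noise, which dilutes the
index), and a 50 ms sensor latency, which the cross-PLV peak recovers
exactly; the peak (0.633) is far above the surrogate 99% bound (0.217),
so the latency estimate is flagged reliable.

## Analysis workflow

The `analysis/` scripts are narrative drivers over the package, each
writing tables under `results/`:

1. `01_tagging_signals.R` — spectral support, envelope, pair decorrelation
2. `02_behavior_staircase.R` — staircase convergence, trial table, hit/FA rates
3. `03_simulate_preprocess.R` — recording with artifacts, rejection chain
4. `04_attention_spectral.R` — AMI maps, median-split calibration
5. `05_latency_crossplv.R` — lag profiles, latency recovery, surrogate null
6. `06_group_stats.R` — full cohort pipeline and group report

Run them from the repository root, e.g.
`Rscript analysis/05_latency_crossplv.R`.

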