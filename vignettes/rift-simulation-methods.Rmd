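---
title: "Methods: simulating and analyzing rapid invisible frequency tagging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analyzing rapid invisible frequency tagging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rifttag)
```

## The problem

Rapid invisible frequency tagging (RIFT) drives a visual stimulus's
luminance with a known temporal signal above the flicker-fusion threshold
(> 60 Hz), so the visual-cortex response can be identified by its phase
locking to the drive without the flicker being consciously perceived or
perturbing ongoing low-frequency rhythms. In a covert spatial-attention
task with one tagged stimulus per hemifield, three sensor-level questions
arise: does attention modulate posterior alpha power (8–13 Hz) and the
tagging response (55–75 Hz) with opposite lateralization; does attention
change the magnitude and/or the latency of the tagged response; and are
trial-by-trial alpha power and tagging power coupled or independent?

With no public recordings available, this package answers those questions
on synthetic data whose generative structure is fully known, so every
estimator can be scored against ground truth. The package supplies the
generator, the full analysis chain, and the calibration suites that show
the chain recovers what was injected — and rejects what was not.

## Tagging-signal generation

The luminance drive is a constant-amplitude phase-modulated carrier

$$s(t) = \sin\!\Big(2\pi f_c t + \sum_{i=1}^{3} \sin(2\pi i\, t + \varphi_i)\Big),$$

with carrier $f_c = 65$ Hz and modulation tones at 1, 2, 3 Hz. The
instantaneous frequency is $f_c + \sum_i i\cos(2\pi i t + \varphi_i)$,
bounded within $65 \pm 6$ Hz, which is what makes the signal "broadband
60–70 Hz" while keeping a strictly constant envelope (all information is
in phase, none in amplitude — the property that justifies a pure
phase-locking analysis downstream).

Two design points deserve emphasis:

* **Phase offsets.** `generate_tagging_signal()` draws $\varphi_i$
  uniformly on $[0, 2\pi)$. A variant that confines offsets to a quarter
  radian (`strict_printed_form = TRUE`) is retained for comparison, but
  offsets that small make independently drawn signals nearly identical,
  defeating the decorrelation requirement below; the full-circle draw is
  the only reading consistent with that requirement.
* **Pair decorrelation.** The left and right stimuli must be analyzed
  independently, so `generate_decorrelated_pair()` redraws a pair until
  the Pearson correlation of the two waveforms over the full 2 s is
  below 0.1 (rejection budget 1000; typical cost is a handful of
  rejections because two narrowband signals sharing a 65 Hz carrier are
  often substantially correlated by chance).

One property worth knowing when validating spectra: because the
modulation index is 1 rad per tone, individual 2 s periodograms have
their maximum anywhere within about $65 \pm 2$ Hz depending on the phase
draw; the *phase-averaged* spectrum peaks exactly at the carrier. Tests
therefore check per-realization peaks against the tagged band and the
averaged spectrum against 65 Hz exactly.

## Behavioral simulation

The task design fixes the trial composition: 25% of trials end with a
brief target — 20% on the cued side (to be reported) and 5% on the uncued
side (catch trials, to be ignored). `make_trial_table()` apportions these
counts by largest remainder, never binomially, so design fractions are
exact; cue sides are balanced 50/50 and order is randomized.

Target duration is controlled by a QUEST staircase
(`quest_init()`/`quest_staircase_step()`): a Bayesian posterior over the
threshold of an assumed Weibull psychometric on a dB grid
($20\log_{10}$ of duration in ms; grid 1–50 ms, 0.1 dB steps), updated
after every response, with the next duration placed at the posterior
mean, clamped to 2–30 ms, starting at 10 ms, and the psychometric shifted
so accuracy at threshold is the 0.80 set point. The simulated observer is
logistic in log-duration (default threshold 8 ms, slope 3); the set-point
property is robust to this slope mismatch, which costs efficiency, not
the asymptote. Because a single 100-trial tail has binomial SD ≈ 4
percentage points, convergence is asserted on accuracy averaged over 20
seeded runs.

Catch-trial responses (false alarms) occur at a configured 2% rate and do
not update the staircase, mirroring a task in which participants must not
respond to the uncued side.

## The generative model of the recordings

`simulate_recording()` builds epochs of −1.0 to 2.5 s around flicker
onset (half-open sample convention; 3500 samples at 1000 Hz; tagging on
during 0–2 s only). Per trial:

1. a fresh decorrelated tagging pair;
2. occipital channels of each hemisphere receive the *contralateral*
   hemifield's drive, band-limited to 55–75 Hz, delayed by the
   ground-truth latency (default 50 ms), RMS-normalized, and scaled by
   `snr` × an attention gain × a trial-wise gain factor;
3. the same posterior channels receive an ongoing alpha oscillation
   (frequency drawn per trial in 8–13 Hz) whose amplitude is lateralized
   the opposite way (decreased contralateral to attention) × a trial-wise
   amplitude factor;
4. 1/f background noise of unit RMS on every channel;
5. photodiode channels record the luminance-mapped drives with zero
   delay (the latency reference), and eye channels record unit-variance
   fixation noise.

Key defaults, chosen once as the study conditions:

| parameter | default | rationale |
|---|---|---|
| attention gains (amplitude) | $\sqrt{1.05}, \sqrt{0.95}$ | +5% power modulation of the tagging response |
| alpha amplitudes (contra/ipsi) | $\sqrt{0.90}, \sqrt{1.10}$ | −10% power modulation, opposite sign |
| sensor latency | 50 ms | the reported ~50 ms visual-drive-to-cortex delay regime |
| `snr` | 0.2 | per-trial cross-PLV sits mid-range (~0.6) instead of saturating near 1, so gain effects remain visible, while latency recovery stays sharp |
| trial factors | log-normal, $\sigma = 0.25$, unit mean | positive-support trial-to-trial variability |
| `coupling_rho` | 0 | trial-wise alpha/tagging independence (the headline structure); a Gaussian copula on the underlying normals implements any coupling in $[-1, 1]$ |
| 1/f exponent | 1 | generic electrophysiological background |

Attention gain is multiplicative on the drive and alpha is additive,
the simplest structure in which the two AMI signs are independent
dials. Note one measurement consequence: band power in 55–75 Hz contains
in-band 1/f noise, so the *measured* tagging AMI is diluted below the
injected +5% component modulation (roughly by the component's share of
band power at `snr = 0.2`). The alpha band is signal-dominated, so the
measured alpha AMI sits close to −10%. No test asserts the diluted
tagging-AMI magnitude; the AMI recovery checks use noiseless
closed-form constructions instead.

Artifacts (`inject_artifacts()`) are Bernoulli per trial and ground-truth
labeled: blink transients of 8 SD on both eye channels, sustained gaze
departures of configurable duration (default 600 ms at 8 SD offset — an
8 SD offset keeps the whole departure outside the detector's 3 SD
fixation radius despite fixation noise, so the 500 ms duration criterion,
not amplitude chance, decides detection), and 50 ms high-amplitude sensor
events.

## Preprocessing conventions

* Epochs use half-open windows; $t=0$ is the first in-stimulus sample.
* All rejection thresholds are z-scores with per-channel statistics
  pooled **globally** over all epochs of the dataset (the per-trial vs
  global choice is open in the underlying description; global is more
  stable at these epoch counts and makes rejection idempotent).
* Blinks: any eye-channel sample beyond 5 SD flags the trial. Saccades:
  gaze outside the fixation radius for more than 500 ms *contiguous*.
  Amplitude: any sensor sample beyond 5 SD; the expected Gaussian
  false-rejection rate for a clean trial is attached to the result so
  the cost of the rule is explicit.
* Condition counts are equalized by seeded downsampling to the minimum;
  every removal carries a reason code and kept + rejected always equals
  the input count.

## Spectral analysis and AMI

Band power uses a single periodic Hann taper on the 0–2 s segment
(0.5 Hz resolution) with the one-sided convention
$P = \sum_{k \in \text{band}} 2|X_k|^2 / (\sum_n w_n)^2$: a unit-amplitude
sinusoid centered in the band contributes exactly 0.75 (carrier bin 0.5
plus two Hann side bins of 0.125), and power scales quadratically with
amplitude. A multitaper estimator would only matter for the source-space
analyses that are out of scope here.

$\mathrm{AMI} = (P_\text{att} - P_\text{unatt})/(P_\text{att} + P_\text{unatt})$
is computed per channel with the contralateral-attended convention, then
combined into one subject scalar by averaging occipital channels within
each hemisphere and averaging the two hemispheres — both already share
the same sign convention, so the canonical attention effect survives the
average with its sign. The exact cross-sensor combination rule is
under-specified in the source description; this convention is isolated in
`combine_hemisphere_ami()` so it can be swapped without touching anything
else.

The median-split analysis sorts trials by pooled-posterior alpha power;
ties and, for odd counts, the median trial go to the low bin. The mean
tagging power per bin is computed separately for channel groups ipsi- and
contralateral to attention, and the per-subject high-minus-low
differences feed a one-sample t-test at cohort level. Calibration runs
this at cohort scale on `simulate_power_table()` — the same bivariate
log-normal factor model that drives the full recordings, reduced to
per-trial powers — because 100 cohorts × 18 subjects × 500 trials of full
sensor simulation would add nothing to what is being tested (the split
logic and the test), only hours of runtime. The factor model's coupling
is cross-validated against full recordings in the unit tests.

## Cross-PLV and latency

Both signals are filtered with a fourth-order Butterworth zero-phase
filter (high-pass 55 Hz then low-pass 75 Hz, each forward–backward),
deliberately wider than the 60–70 Hz signal band. Note that zero-phase
filtering squares the magnitude response: the analytic double-pass gain
at 65 Hz with these cutoffs is ≈ 0.60 — irrelevant for phase estimates,
but worth knowing when eyeballing filtered amplitudes. Instantaneous
phase is the argument of the FFT-based analytic signal.

The cross-PLV profile evaluates
$\mathrm{PLV}(\ell) = \big|\tfrac{1}{N}\sum_{t \in W} e^{i(x_{t+\ell} - y_t)}\big|$
over lags $\ell = -200..200$ ms (1 ms steps), window $W$ fixed at 0–2 s
with the first and last 100 ms excluded from the sum (Hilbert edge
distortion), per trial, then averages profiles across trials within
condition. Positive lag means the sensor follows the drive; profile-peak
ties resolve to the smallest lag. Implementation: over a fixed window the
whole profile is the modulus of a circular cross-correlation of the two
unit-phasor series — three FFTs per trial — and the test suite verifies
this path against a naive per-lag loop to 1e-10.

**Surrogate bound.** The null distribution comes from circularly
shifting each trial's sensor phasor at a random time point (shifts at
least one maximal lag away from zero) and recomputing the trial-averaged
profile; because a circular shift of the sensor series shifts the
correlation sequence, each surrogate is a shifted read of the same
per-trial modulus vectors. Whether the bound should be pointwise per lag
or on the max over lags was an open choice: the default is the
**max-over-lags** statistic, which controls the 401-lag family (a
pointwise option exists). With $n$ surrogates the level-$q$ bound is the
$\lceil q(n+1)\rceil$-th order statistic capped at the maximum; at the
default $n = 100$, $q = 0.99$ this is the largest surrogate, whose
exceedance probability under exchangeability is exactly
$1/(n+1) \approx 1\%$ — the property the 200-run Monte-Carlo calibration
checks. Latencies are reported as reliable only when the observed peak
exceeds the bound.

Channel selection for the attention contrast takes, per hemisphere, the
channel with the largest condition-*averaged* peak PLV, so selection is
blind to the condition difference being tested.

## Group level

A cohort is built by giving each subject a log-normal attention-strength
factor that scales the tagging modulation (+) and the alpha modulation
(−) together, plus a Gaussian subject latency (50 ± 4 ms). This shared
factor is what produces the negative over-subject rank correlation
between alpha AMI and tagging AMI; latency varies independently of
attention strength, so the AMI–latency correlation has no built-in
structure. Group inference uses two-sided paired t-tests (df = n − 1) and
Spearman correlations with tie-averaged ranks (asymptotic p by default, a
permutation option for small cohorts). Degenerate inputs (zero-variance
differences, constant vectors) are flagged rather than silently
propagated, and no multiple-testing correction is applied — the report
carries raw p-values. Every reported statistic is reproducible
bit-for-bit from the pipeline config: all stage seeds derive
deterministically from the one global seed.

## Problem sizes

The shipped calibration suites use sizes chosen to make each property
measurable without waste: 50 pairs for decorrelation; 20 staircase runs
of 200 trials; 200 Monte-Carlo runs × 30 trials × 100 surrogates for the
null calibration; 10 recovery runs × 100 trials at each of three injected
latencies (37/50/83 ms); 100 cohorts × 18 subjects × 500 trials (factor
model) for the median-split power calibration; and a 12-subject
full-pipeline cohort in the analysis scripts. Anything smaller makes the
binomial bands uninformative; anything larger changes no conclusion.

## What the generator does not emulate

Synthetic channels are abstract hemisphere/group-tagged sensors: no head
geometry, forward model, or planar-gradiometer physics, hence no
source-space analyses (beamforming is out of scope by design). Noise is
stationary 1/f without physiological structure (no heartbeat, no muscle
spectra, no slow drifts); alpha is a pure tone per trial rather than a
bursty rhythm; eye channels are Gaussian fixation plus injected events,
not a vendor eye-tracker stream. Passing tests therefore demonstrate
that the *analysis chain* is correct and calibrated under the stated
generative assumptions — not that real MEG satisfies those assumptions.
The one place this matters most is the surrogate calibration, which
inherits the stationarity of the synthetic noise; on real data the
circular shift remains valid insofar as the recording is stationary over
the epoch.

## Known limitations

* The measured tagging-band AMI is noise-diluted (see above); comparing
  its magnitude across `snr` settings requires accounting for that.
* Latency resolution is the 1 ms lag grid; sub-millisecond recovery is
  out of scope.
* The QUEST implementation fixes the Weibull family; any staircase
  reaching the 80% set point with the same start and clamp would satisfy
  the same contracts.
* `strict_printed_form` reproduces the quarter-radian phase variant for
  completeness, but pairs generated that way will essentially never pass
  the decorrelation gate.
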