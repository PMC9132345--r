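# spiketypes

Classification of extracellular unit types and analysis of their temporal
codes, for auditory-cortex-style single-unit recordings.

Cortical recordings mix physiologically distinct classes: broad-spiking
**regular-spiking (RS)** cells, narrow-spiking **fast-spiking (FS)**
interneurons, and **bursting (Bu)** cells that fire stereotyped 2-3 spike
bursts at intraburst intervals of 1-4 ms, both spontaneously and when
driven. These classes encode sound differently -- bursting onset units lock
with millisecond precision to envelope transients, RS units carry slower,
rate-dominated codes -- so separating them is a prerequisite for any claim
about temporal coding. `spiketypes` is for electrophysiologists who want
that whole chain in one tested package:

* **Spike-timing features.** ISI histograms (0.2 ms linear bins or 0.1-wide
  natural-log-ms bins), the truncated log-ISI peak, the `logISIdrop` burst
  score (Savitzky-Golay-smoothed log-ISI histogram: max over 1-5 ms vs mean
  over 10-16 ms), the autocorrelogram metric
  `ACM = (R̄(0,8) − R̄(35,80)) / (R̄(0,8) + R̄(35,80))`, intraburst
  frequency, burst-run statistics, refractory period, and Hartigans' dip
  test.
* **Waveform features.** Zero-phase FIR filtering, alignment on the largest
  voltage change, trough-to-peak time t_TTP, spline-interpolated
  half-amplitude width, and the spectral width f50 (high-side 50% roll-off
  of the baseline-subtracted spike spectrum).
* **Classification.** Consensus criteria (Bu: ISI peak < 10 ms, ACM > 0.5,
  logISIdrop > 0.2, all three required; FS/RS: 2-of-3 rules on t_TTP, f50
  and spontaneous rate; PBu from prestimulus intervals alone; Bu1/Bu2 split
  at 500 Hz intraburst frequency) and an unsupervised route
  (8 standardized features → 3 PCs → full-covariance Gaussian mixture,
  best of 20 random starts by AIC, assignment only at a 2× posterior
  margin), with an agreement matrix between the two.
* **Temporal-coding metrics.** Smoothed PSTHs, duration-corrected
  responsiveness tests, adaptation index
  `AI = (r_early − r_late)/(r_early + r_late)`, vector strength with the
  Rayleigh criterion `2NVS² > 13.8`, f_max and temporal best modulation
  frequency, and the shuffled-autocorrelogram correlation index
  `CI(ω) = N_c / (M(M−1) r² ω D)` with CI_max per unit.
* **Decoding.** The Victor-Purpura spike metric (exact dynamic program, in
  C++), leave-one-out classification with the z = −3 power mean and
  transmitted information across a cost sweep with a label-shuffle null;
  pseudopopulation time-binned decoding (maximum-correlation and
  shrinkage-LDA decoders) with rate/time averaging manipulations and
  bin-width sweeps.
* **A synthetic benchmark generator.** Seeded, labeled sessions whose RS /
  FS / Bu1 / Bu2 units reproduce the statistical structure the analyses
  assume, so the entire pipeline is testable end to end without any data
  download.

## Worked example

Generate a labeled benchmark session, compute features, classify by
criteria and by the Gaussian mixture, and compare:

```r
library(spiketypes)

ses  <- generate_benchmark_session(
  c(RS = 16, FS = 10, Bu1 = 7, Bu2 = 9), seed = 42)
ses
#> <spike_session> 42 units, 44 stimuli, 266457 spikes, 42 waveform blocks

fx   <- unit_features(ses)
labs <- classify_criteria(fx)
table(truth = fx$truth_type, label = labs$label)
#>      label
#> truth Bu1 Bu2 FS RS
#>   Bu1   7   0  0  0
#>   Bu2   0   9  0  0
#>   FS    0   0 10  0
#>   RS    0   0  0 16
```

Every unit recovers its generating class (units with fewer than 50
interspike intervals would instead be left unclassifiable rather than
guessed). The unsupervised route agrees:

```r
fm  <- build_feature_matrix(fx)
fit <- fit_pca_gmm(fm, k_range = 1:5, n_seeds = 10, n_splits = 10, seed = 3)
glance(fit)
#> # A tibble: 1 × 3
#>   best_k n_complete pc_var_3
#>    <int>      <int>    <dbl>
#> 1      4         42        0.901

g <- assign_types_gmm(fit, fm)
agreement_matrix(labs, g)$agreement
#> [1] 1
```

The first 3 principal components carry 90% of the feature variance, and the
3-component assignment matches the criteria labels for every unit labeled
by both methods (on only 42 tightly clustered units the BIC curve itself is
an unreliable guide to the component count -- see the vignette). Temporal-coding contrasts come out as the classes were
built to show; for one bursting onset unit:

```r
u <- labs$unit_id[labs$label == "Bu1"][1]
vs <- vs_profile(ses, u)
sam_summary(vs)
#> # A tibble: 1 × 6
#>   f_max_hz tbmf_hz sync_4 sync_16 unsynchronized excluded
#>      <dbl>   <dbl> <lgl>  <lgl>   <lgl>          <lgl>
#> 1     125.    29.3 TRUE   TRUE    FALSE          FALSE
```

The unit synchronizes out to ~125 Hz with a temporal best modulation
frequency near 29 Hz, and its reported vector strength peaks well above the
RS units' -- the bandpass, rising-phase-locked signature of the Bu1 class.
`autoplot()` methods exist for PSTHs, VS profiles, CI curves, confusion
matrices and the mixture-model selection curves.

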