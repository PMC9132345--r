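---
title: "Classifying cortical unit types and measuring their temporal codes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cortical unit types and measuring their temporal codes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiketypes)
```

## Scope

Extracellular recordings from sensory cortex mix several physiological cell
classes -- broad-spiking regular-spiking (RS) cells, narrow-spiking
fast-spiking (FS) interneurons, and intrinsically bursting (Bu) cells that
fire stereotyped 2-3 spike bursts at millisecond intervals. These classes
carry stimulus information differently: bursting onset units time-lock
precisely to envelope transients, while RS units carry slower,
rate-dominated codes. `spiketypes` implements the full analysis chain needed
to (1) classify units from spike timing and waveform shape, by explicit
criteria and by unsupervised clustering, (2) quantify temporal coding with
adaptation, phase-locking and cross-trial coincidence metrics, and (3)
decode stimulus identity from single units (spike-metric space) and
pseudopopulations (time-binned responses). A seeded synthetic-session
generator provides labeled benchmark data so every stage can be verified in
closed loop.

## Data model

A `spike_session` holds a long spike table (`unit_id`, `protocol`,
`stimulus_id`, `repetition`, `time_s`), a stimulus table, a unit table and
per-unit waveform snippet matrices. Spike times are in seconds with
stimulus onset at zero; each trial spans `[-0.2 s, duration + 0.35 s]`, the
200 ms prestimulus epoch serving as the spontaneous reference. All windows
are half-open `[t0, t1)`, which makes count conservation under window
partitions exact and defines bin-edge ownership everywhere. Sessions
round-trip to plain text (CSV + JSON manifest) with spike times quantized
to 1 microsecond -- finer than the 41 microsecond sample period, and exact
under re-reading.

## Spike-timing features

Interspike-interval (ISI) histograms use 0.2 ms linear bins or 0.1-wide
bins in natural-log milliseconds. The log scale is what separates bursting
from fast Poisson-like firing: a Poisson unit at rate $\lambda$ has a
log-ISI mode at $\ln(1000/\lambda)$ ms (about 3 at 50 spk/s, about 7 at
1 spk/s), whereas intraburst intervals produce a distinct mode below
$\ln 2$. Features:

* **ISI peak** -- mode of the log-ISI histogram truncated below 80 ms (the
  truncation avoids spurious long-interval modes from the log transform and
  the ~770 ms trial repetition period); ties break toward shorter
  intervals, the conservative choice for burst detection.
* **logISIdrop** -- the histogram is smoothed with a Savitzky-Golay filter
  (span 5, degree 3) and the maximum over 1-5 ms is contrasted with the
  mean over the 5 bins spanning 10-16 ms as $(\max - \bar y)/(\max + \bar
  y)$. The score lies in $[-1, 1]$ up to smoothing overshoot, which can
  push it slightly outside when the polynomial fit goes negative.
* **Autocorrelogram metric (ACM)** -- with $\bar R(a,b)$ the mean
  autocorrelogram count over lags $[a, b)$ ms (0.2 ms bins, positive lags,
  pairs never crossing trial boundaries), $\mathrm{ACM} = (\bar R(0,8) -
  \bar R(35,80)) / (\bar R(0,8) + \bar R(35,80))$. The 35-80 ms reference
  band sits above any gamma-band peak. Band means are simple bin means over
  the stated ranges, with no padding correction at long lags.
* **Intraburst frequency** -- inverse of the linear ISI-histogram peak;
  769 Hz corresponds to a 1.3 ms intraburst interval, and 500 Hz (2 ms) is
  the Bu1/Bu2 boundary.
* **Burst statistics** -- a burst is a maximal run of consecutive ISIs
  within 0.5-1.5x the ISI peak (a single qualifying ISI is a 2-spike
  burst); the percentage of ISIs below 5 ms is also reported normalized by
  the Poisson expectation $100(1 - e^{-r\cdot 0.005})$ with the rate
  estimated as $1/\overline{\mathrm{ISI}}$ -- a window-free estimate
  matching the "same mean rate" normalization. Regularity is the variance
  of $\mathrm{ISI}_n / (\mathrm{ISI}_n + \mathrm{ISI}_{n+1})$.

Histogram-based features require at least 50 intervals; units below that
threshold are left uncomputed rather than noisily estimated. The dip test
of unimodality (used to document bimodal feature distributions such as
spike width) is computed in-package: the dip statistic is half the sup-norm
distance from the empirical cdf to the nearest unimodal cdf, found by
minimizing over candidate modes the larger of the left-limb convexity and
right-limb concavity deficiencies; p-values come from a seeded bootstrap of
uniform null samples, the conventional conservative null.

## Waveform features

Snippets are zero-phase filtered (256th-order FIR, 1 Hz-10 kHz, forward
and reverse), aligned on the largest absolute one-sample voltage change
(ties to the earliest sample) and averaged; at least 5 isolated spikes
(no neighbor from 5 ms before to 6 ms after) are required. The
trough-to-peak time $t_\mathrm{TTP}$ runs from the largest downward peak to
the next upward peak; the half-amplitude width is measured at 50% of trough
depth relative to a 1 ms pre-trough baseline (offset by a 0.5 ms guard) on
a 10x cubic-spline interpolation. The spectral width $f_{50}$ subtracts the
amplitude spectrum of a 5 ms pre-spike baseline segment from a 5 ms
spike-spanning segment (Hann window, 1024-point FFT), finds the peak above
400 Hz and reports the high-side 50% crossing by linear interpolation. The
5 ms segment length and window/FFT choices are package defaults -- they fit
inside the 10 ms isolation window, and are validated through the
monotonicity of $f_{50}$ in spike width and the inverse
$t_\mathrm{TTP}$-$f_{50}$ association rather than against fixed constants.

## Classification

The criteria route is sequential. Bursting first: a unit is Bu only if all
three hold -- ISI peak < 10 ms, ACM > 0.5, logISIdrop > 0.2; exactly two of
three leaves the unit unclassified, one or none marks it nonbursting.
Prestimulus-only bursting (PBu) thresholds the logISIdrop of pooled 200 ms
prestimulus segments at 0.3; a PBu unit not labeled Bu is flagged
bursting-ambiguous and excluded from RS/FS assignment. Nonbursting units
are FS with at least 2 of {$t_\mathrm{TTP} < 0.5$ ms, $f_{50} > 2$ kHz,
spontaneous rate > 5 spk/s} and RS with at least 2 of the mirrored
conditions (> 0.5 ms, < 2 kHz, < 3 spk/s); meeting both or neither quorum
leaves the unit unclassified. Bursting units split into Bu1/Bu2 at 500 Hz
intraburst frequency, or by a 2-component mixture on intraburst frequency,
logISIdrop and latency.

The unsupervised route standardizes 8 features (ACM, ISI peak, logISIdrop,
% ISI < 5 ms, spontaneous rate, $f_{50}$, max burst length, max firing
rate), log-transforming columns whose sample skewness exceeds 2 in absolute
value (adding half the minimum positive value when zeros are present).
"Strongly skewed" has no published numeric criterion; $|g_1| > 2$ is the
package's operationalization and is exposed as a parameter. Complete rows
are projected onto the first 3 principal components and a full-covariance
Gaussian mixture is fit by EM, taking the best of 20 random soft-assignment
initializations by AIC; model-selection diagnostics are AIC, BIC and the
mean held-out negative log-likelihood over 50 half/half splits for 1-7
components. Components map to types by centroid heuristics -- highest-ACM
centroid is Bu, highest spontaneous rate among the rest is FS -- because an
unsupervised fit has no visual correspondence to lean on. A unit is
assigned only when its maximum posterior is at least twice each other
posterior. Complete-case analysis is the default arbiter for missing
features; rows with missing values simply keep `NA` labels.

## Response metrics

PSTHs use 1 ms bins convolved with a Gaussian ($\sigma$ = 5 ms) with
truncated-kernel renormalization at window edges, so smoothing conserves
integrated counts. The response window runs from 10 ms after onset to 50 ms
after offset (150 ms for vocalizations). Rate responsiveness requires the
driven rate to exceed the prestimulus mean plus 3 standard errors with the
prestimulus variance scaled by $T_\mathrm{pre}/T_\mathrm{resp}$ -- rate
variance scales inversely with window duration -- and divided by the number
of repetitions. PSTH responsiveness aggregates 5 ms bins across
repetitions, fits a Poisson mean to the spontaneous bins (floored at 0.5
expected counts when the spontaneous period is silent, to avoid degenerate
p-values) and Bonferroni-corrects the tail probability of the maximum
response bin at 0.01. Only excitatory responses are flagged.

The adaptation index compares the first and last 100 ms of the response to
a 200 ms stimulus, $(r_\mathrm{early} - r_\mathrm{late}) / (r_\mathrm{early}
+ r_\mathrm{late})$. Vector strength over SAM stimuli excludes the first
50 ms so onset responses do not masquerade as synchrony; significance uses
the Rayleigh statistic $2NV\!S^2$ with a strict > 13.8 cutoff (the 0.999
null quantile; $-2\ln 0.001 = 13.8$), and nonsignificant values are
reported as zero. `f_max` interpolates the Rayleigh statistic against
$\log_2$ frequency between the highest significant rate and the next tested
rate -- the tested rates are octave-spaced, so interpolation is performed in
log frequency. The temporal best modulation frequency is a geometric mean
of the peak-VS rate and significant immediate neighbors weighted by the
reported VS values (the weighting scheme is the package's choice; each
neighbor qualifies independently). Onset latency -- for which no standard
algorithm exists -- is defined here as the first smoothed-PSTH time at or
after onset exceeding the spontaneous mean plus 3 spontaneous SDs,
minimized over responsive stimuli.

## Correlation index

The shuffled autocorrelogram tallies all-order spike-time differences
between distinct repetitions at 50 microsecond resolution, bypassing
refractoriness. The correlation index normalizes coincidences as
$\mathrm{CI}(\omega) = N_c(\omega) / (M(M-1) r^2 \omega D)$ with
coincidences counted as ordered cross-trial pairs within $|\Delta t| \le
\omega/2$, $r$ estimated from the analyzed window itself, and $D$ the
window duration. This convention is anchored by calibration: independent
Poisson trains give CI = 1 at any window. The window grid is
$10^{k/10}$ ms spanning 0.05-5 ms; the per-stimulus CI averages the 5 grid
points flanking 0.5 ms, and `ci_max` is the maximum over stimuli with an
excitatory response. No edge correction is applied for lags near $D$, as
$\omega \ll D$ throughout.

## Decoding

The Victor-Purpura distance (insert/delete cost 1, shift cost $q|\Delta
t|$) is computed by the exact dynamic program, in C++ for the pairwise
sweeps. Responses to variable-length vocalizations are first cropped to the
shortest stimulus duration, centered on the peak of a Gaussian kernel
density estimate of the pooled response ($\sigma$ = 20 ms -- the bandwidth
is a package default, checked for insensitivity in the tests); empty
responses anchor at onset. Leave-one-out classification assigns each train
to the stimulus minimizing the $z = -3$ power mean of its distances to the
other repetitions; any zero distance forces that class mean to zero (the
transform's documented distortion), and ties tally $1/k$. Decoding quality
is the transmitted information of the confusion matrix, with chance
calibrated by 100 label shuffles at the best $q$ (the null is evaluated at
the best $q$ only; per-$q$ nulls would multiply the cost without changing
the inclusion decision in our benchmarks).

Population decoding bins each unit's response in 10 ms bins over the
shortest-stimulus-plus-300 ms crop (short stimuli zero-pad naturally),
assembles pseudopopulations by sampling units and, independently per unit,
one left-out repetition per draw, and decodes each stimulus's test vector
against per-unit mean templates from the remaining repetitions -- by
maximum Pearson correlation (MCC) or by LDA with a uniform prior and a
diagonal-shrinkage pooled covariance. Feature order is fixed by sorted unit
id; ties and zero-variance vectors resolve by seeded uniform choice.
Manipulations: `avg_time` collapses each unit to its mean rate, `avg_units`
collapses each time bin to its population mean. Accuracy is the diagonal
mass of the aggregate confusion matrix. Mixture pseudopopulations draw RS
and Bu units at a 2:1 prevalence by default.

## The synthetic benchmark

The generator emulates exactly the statistical structure the analyses
assume, and its defaults are the study conditions for the package's
closed-loop tests:

* Trial structure: 200 ms prestimulus, 10 interleaved repetitions,
  protocols for tuning (5 tones, 200 ms), durations (12.5-400 ms,
  octave-spaced), onset ramps (5-100 ms), SAM (2-512 Hz, octave-spaced,
  100% depth, 1 s) and a vocalization list (5 call-type families x 4
  exemplars; exemplars share an event skeleton and differ mainly in event
  timing, ~12 ms onset jitter, with only slight level differences).
* RS: Poisson spiking, spontaneous ~1.8 spk/s, driven ~45 spk/s following
  the stimulus envelope smoothed over 8 ms with a small onset kick, strong
  stimulus selectivity, broad waveform (0.7 ms trough-to-peak), ~16 ms
  latency.
* FS: spontaneous ~12 spk/s, driven ~45 spk/s, sustained (adaptation floor
  0.8), weakly selective, narrow waveform (0.3 ms).
* Bu1: two-stage burst process -- events from an inhomogeneous Poisson
  process driven by the rectified envelope derivative (hence onset bursts
  for flat tones, rising-phase locking for SAM and event-locking for
  vocalizations), bursts of 2-4 spikes at 1.3 ms intraburst interval with
  85% burst probability, spontaneous events ~2.2/s so bursting persists in
  prestimulus epochs, ~1.5 ms event jitter, 0.5 ms waveform.
* Bu2: mixed amplitude/derivative drive, 2.6 ms intraburst interval,
  moderate sustain.
* Shared machinery: thinning with a 0.8 ms absolute dead time within and
  between bursts; per-unit lognormal scatter of rates, time constants and
  latencies; a per-unit-per-stimulus smooth "response field" (lognormal
  control points every ~80 ms) emulating heterogeneous receptive fields;
  multiplicative per-trial gain noise (lognormal, sd 0.3). Everything is
  deterministic given the seed.

Driven-rate magnitudes are not prescribed anywhere as exact numbers; the
defaults above were chosen once so that each class satisfies its own label
definition (e.g., generated Bu units pass the three bursting criteria, FS
spontaneous rates exceed 5 spk/s) and were then left alone. The generator
emulates envelope-locked point processes only: no membrane biophysics, no
acoustic waveforms, no across-unit noise correlations (pseudopopulations
are assembled from independent draws, as with non-simultaneously recorded
units), and within-burst spike amplitudes do not attenuate. Passing
closed-loop tests on this benchmark therefore demonstrates the internal
consistency of the pipeline -- that each analysis measures what it claims
on data with the assumed structure -- not performance on any particular
real recording.

## Numerical choices and degenerate inputs

Seeds thread through every stochastic function and restore the caller's
RNG state. Histogram bins are half-open everywhere. Degenerate cases
return explicit markers rather than guesses: empty interval lists give
empty histograms; an autocorrelogram with both band means zero, a
waveform with no post-trough peak, a flat waveform's $f_{50}$, and a
zero-rate unit's CI are all `NA`; fewer than 50 ISIs, fewer than 5
snippets and single-repetition stimuli raise typed errors or warnings as
documented. EM fits that fail to converge for every random start are
dropped from the model-selection table rather than silently replaced.

## Problem sizes used by the tests

The packaged checks run a 42-unit benchmark session (16 RS, 10 FS, 7 Bu1,
9 Bu2) with the full protocol set, about 1.5e5 spikes; Monte-Carlo
calibrations use 1e6 draws for the Rayleigh null, 1e5 intervals for the
log-ISI anchors, 100 simulated 10-repetition units for the CI calibration,
and 1000 random train pairs/triples for the spike-metric oracle. These
sizes keep every stochastic assertion far from its tolerance while staying
desk-scale; population-decoding checks use 8 pseudopopulation draws of up
to 12 units, which is enough to order the compositions and manipulations
reliably at the generator's effect sizes.

## Known limitations

The dip test p-value is bootstrap-based and so itself stochastic (seeded).
The latency rule and the KDE bandwidth for response centering are
documented stand-ins where no standard exists. The GMM's cross-validation
diagnostic is informative only when the number of complete rows comfortably
exceeds the per-component parameter count; on small sessions BIC should be
read with that in mind. The waveform synthesizer produces single-channel
biphasic spikes only -- multi-channel probe geometry and spike-sorting
artifacts are out of scope.
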