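---
title: "Staging sleep from around-the-ear EEG: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staging sleep from around-the-ear EEG: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(earsleep)
```

## The problem

Polysomnography (PSG) is the reference method for quantifying sleep, but
it requires a technician to apply scalp electrodes and another to score
the night visually in 30-s epochs. Flex-printed electrode arrays placed
around the ear (cEEGrid-style, eight usable signal electrodes per ear)
can be self-applied and worn at home, at the cost of non-standard
electrode positions and smaller signal amplitudes — conditions under
which visual scoring by AASM criteria is unreliable. `earsleep`
implements the complementary strategy: score the around-the-ear EEG
*automatically*, with a feature-based bagged-tree classifier trained on
PSG-derived labels, and evaluate it with the same agreement statistics
used to compare human scorers.

The package covers the full chain: signal conditioning, electrode
pooling, epoch features, classification with leave-one-subject-out
(LOSO) validation, rule-based hypnogram clean-up, an actigraphy
sleep-wake scorer as the field-standard baseline, and sleep statistics
with agreement metrics. Because no public dataset accompanies the
method, the package ships a synthetic sleep-EEG generator that creates
exactly the statistical structure the classifier exploits; every claim
the test suite makes is a claim about that generator.

## Signal conditioning

Recordings are resampled (anti-aliased, polyphase) to a common rate —
256 Hz by default — then band-pass filtered 0.5–100 Hz and notch
filtered at 50 Hz. Filtering is zero-phase (forward–backward) with a
4th-order Butterworth band-pass and a biquad notch of quality factor
30, so epoch boundaries suffer no phase distortion. When the source
sampling rate cannot support the requested upper edge (a 128-Hz
recording has nothing above its 64-Hz Nyquist frequency), the effective
upper edge is the source Nyquist and is reported with the output.

Two recordings of the same night (ear array and PSG) are aligned by
cross-correlating their 1-s-window log-power envelopes, averaged over
channels: large movement artifacts and slow-wave activity dominate
these envelopes in both devices, so the correlation peak marks the true
offset at 1-s resolution. A peak envelope correlation below 0.2 raises
an alignment failure rather than returning a spurious lag. Recordings
that start late are padded with missing values at the head; analysis
uses only the maximal run of whole 30-s epochs covered by valid data in
both devices.

High-amplitude artifacts are detected by short-window power
thresholding: a window (default 1 s) is rejected when its mean power
exceeds a multiple (default 10) of that channel's median window power
over the whole recording. The median-multiple rule is scale-free, so
the same default works for ear and scalp montages despite their
different amplitude characteristics. Both the window length and the
multiplier are exposed in the configuration; whether the original
procedure thresholded per channel or globally is not recoverable, and
per-channel is the more conservative choice.

## Electrode derivations and the correlation index

With eight usable electrodes per ear, many referenced combinations are
possible. A derivation is the uniform average of a `plus` set minus the
average of a `minus` set; the standard candidates are left-vs-right ear
(`L-R`), front-vs-back electrodes 1,8 vs 4,5 within an ear (`FB(L)`,
`FB(R)`), top-vs-bottom electrodes 2,3 vs 6,7 (`TB(L)`, `TB(R)`), and
all 56 intra-ear single-electrode pairs.

Candidates are ranked by a correlation index per frequency band (delta
1–4, theta 4–8, alpha 8–16, beta 16–32 Hz):

$$\mathrm{CI}_i = g_i \sum_j \mathrm{corr}\!\left[P(d_i),\, P(s_j)\right]$$

where $P(\cdot)$ is the integrated band power per 30-s epoch, $s_j$
ranges over the scalp reference channels, and $g_i$ is the fraction of
artifact-free data for derivation $i$. The printed form of this index
is ambiguous about the summation variable; summing over scalp channels
is the only reading consistent with its description, and a `normalize`
flag averages instead of summing for comparability across montages.
Correlations are computed on epochs where both series are valid, with
data quality entering only through $g$. The staging pipeline itself
uses the fixed set {FB(L), FB(R), L-R}; ranking is exploratory tooling.

## The 33-feature epoch representation

Each derivation contributes 33 features per 30-s epoch (so 99 for the
three-derivation ear montage, 132 when a true EOG channel is added).
The source method names the features but defers their definitions;
every operational choice here is therefore explicit and configurable:

* **Time domain (F1–F7):** skewness, excess kurtosis, zero-crossing
  rate per second, Hjorth mobility and complexity, 75th percentile of
  the absolute signal, and the Pearson correlation with a partner
  derivation's epoch (FB(L) pairs with FB(R), L-R with FB(L); an EOG
  channel pairs with L-R).
* **EMG proxy (F8–F10):** the derivation band-passed to 32–80 Hz
  stands in for a muscle channel (clipped to Nyquist with a flag at low
  sampling rates). Mean power, minimum 1-s sub-window power, and the
  95th-percentile-to-median ratio of the Hilbert envelope (burst
  amplitude).
* **EOG proxy (F11–F12):** the derivation band-passed to 0.5–30 Hz;
  integrated power in 0.5–2 Hz (slow) and 2–6 Hz (rapid) eye-movement
  sub-bands. The sub-band edges are interpretations, exposed in
  `feature_opts()`.
* **Spectral (F13–F28):** Welch PSD with 2-s Hann windows at 50%
  overlap; relative alpha/beta/theta/delta power normalized by total
  1–32 Hz power, the six pairwise band ratios, the slow/fast ratio
  (theta+delta)/(alpha+beta), 95% spectral edge frequency, median power
  frequency, mean absolute spectral-edge difference between consecutive
  2-s sub-windows, peak power frequency, and spectral entropy
  normalized by log bin count.
* **Spindle proxies (F29–F33):** a complex Morlet CWT (7 cycles) at
  11–16 Hz in 0.5-Hz steps; the sigma envelope is the maximum CWT
  magnitude across centre frequencies. Fraction of samples above 3
  times the epoch-median envelope, frequency stationarity (one minus
  the normalized variance of 2-s sub-window peak frequencies), minimum
  correlation between adjacent 2-s sub-window periodograms, largest
  envelope value, and the longest supra-threshold run lasting 0.5–3 s.

If part of an epoch is rejected, features are computed from the
remaining samples and the used fraction is recorded. A fully rejected
epoch becomes an all-missing row that is scored wake downstream — full
rejection almost always means gross movement. Remaining missing values
(degenerate features such as Hjorth parameters of a constant segment)
are imputed with per-feature training medians before classification;
decision trees need finite inputs and the median is the least
committal choice.

## Classifier and validation

The stager is an ensemble of 100 decision trees grown by bagging: each
tree sees a bootstrap resample of the training epochs at the original
size (duplicates allowed), splits optimize the Gini criterion, and
growth continues until every leaf is pure. All features are candidates
at every split, matching plain bagging; a square-root subsampling
option exposes the common random-forest variant. Class imbalance is
left unadjusted. Per-epoch class probabilities are the fraction of
trees voting for each stage; ties break in the fixed order W, N1, N2,
N3, REM for determinism. Validation is leave-one-subject-out
throughout: the held-out subject's epochs never influence training, and
retraining without them is bit-identical under the same seed.

## Hypnogram post-processing

Three rules make the independent per-epoch decisions into a plausible
hypnogram:

1. **Persistent-sleep onset** — sleep onset is the first epoch that
   begins at least 10 consecutive sleep epochs (5 min); "followed by"
   is read inclusively, the onset epoch being the first of the ten.
2. **Final wake-up** — the mirror image: the end of the last run of at
   least 10 consecutive sleep epochs.
3. **Probability smoothing** — between onset and wake-up, each class
   probability series is smoothed with a centred 5-epoch moving
   average (uniform weights; the window shrinks at the run edges
   rather than reflecting, so no data is fabricated) and each epoch is
   relabelled with its most probable class — except that wake epochs
   are always retained, preserving brief arousals. Epochs outside
   [onset, wake-up] are scored wake.

Actigraphy-based hypnograms receive rules 1–2 only. The smoothed argmax
may introduce wake where the averaged wake probability dominates; only
removal of wake is forbidden by the retention rule.

## Actigraphy baseline

Activity counts in 60-s epochs are smoothed with the five-point kernel
(0.04, 0.2, 1, 0.2, 0.04) — each epoch plus 20% of its immediate and
4% of its second neighbours — thresholded (strictly below ⇒ sleep),
and split into 30-s epochs that inherit the parent's score. The
threshold default of 20 counts follows the device convention's medium
setting; no authoritative value is published, so it is always explicit
in reports and configuration.

## Agreement statistics

Scorer pairs are compared by accuracy and Cohen's kappa (five-stage and
collapsed sleep-wake), pooled stage occupancies (pooling epochs across
subjects before averaging, so long nights weigh more), and per-subject
sleep statistics: total sleep time, sleep efficiency, wake after sleep
onset (wake between the first sleep epoch and the end of the last —
wake after the final awakening is excluded), sleep onset latency (first
sleep epoch; the persistent-sleep onset of the post-processing rules is
a deliberately distinct quantity), and REM latency from sleep onset.
Group-level comparisons use paired two-tailed t-tests (undefined, and
flagged, when differences have zero variance), the coefficient of
determination of a least-squares fit, and ICC(A,1) — the two-way,
absolute-agreement, single-measure intraclass correlation computed
from ANOVA mean squares. r² rewards covariation only; ICC(A,1) also
penalizes systematic offsets, which is why an exact additive shift
yields r² = 1 but ICC < 1.

## The synthetic generator

Ground-truth hypnograms are first-order Markov chains over
W/N1/N2/N3/REM. The default transition matrix emulates a disrupted,
extended sleep opportunity: stationary wake occupancy ≈ 0.39 (the
protocol being emulated produced ~45% wake), N2 as the dominant sleep
stage, and consolidated N3/REM bouts. The matrix was calibrated once,
by eigen-decomposition and a Monte-Carlo check that per-night wake
fractions over 12-h nights stay within 0.25–0.55, and is part of the
package's fixed study conditions.

Each epoch of signal is coloured noise shaped in the frequency domain:
white noise is multiplied by a per-band amplitude profile so that the
power spectral density per band is proportional to the stage's declared
band gains, with an EMG-band (32–80 Hz) component scaled by the stage's
muscle-tone level (high in wake, near zero in REM atonia). Stage events
ride on a common source shared by all channels: 11–16 Hz spindle bursts
in N2 (4/min), high-amplitude 0.6–1.5 Hz waves in N3, and slow smooth
ocular deflections in wake (4/min) and REM (10/min), deliberately
concentrated below ~1 Hz so they perturb the declared delta-band
ordering as little as possible. Epochs are joined with 0.5-s
raised-cosine cross-fades. Channels couple to the source with fixed
per-subject gains (0.7–1.3) plus independent channel noise; optional
scalp channels carry the source with less noise, emulating simultaneous
PSG. Activity counts are Poisson draws at a high rate in wake minutes
and near zero in sleep; injected movement artifacts multiply random
1–10-s windows on random channel subsets by a large factor and raise
the overlapping counts. A global amplitude dial stands in for the ear
montage's unasserted physical amplitude. Everything is a pure function
of its seed.

What the generator does *not* emulate: biophysical field spread,
K-complexes, circadian/ultradian modulation of stage depth, gradual
stage transitions inside an epoch, and scorer disagreement. Its stages
are consequently *more* separable than real sleep: at the default
contrast the LOSO stager recovers the synthetic stages essentially
perfectly, which real ear-EEG never achieves. Passing tests therefore
demonstrate the correctness of the pipeline's mechanics — not
real-data staging performance, which only a real validation cohort can
establish.

### Problem sizes used by the tests

The benchmark cohort is 10 subjects × 480 epochs (4 h) at 128 Hz with
100 trees — large enough for stable LOSO statistics while keeping the
full suite comfortably fast on one core. The separability-dial check
uses 3 subjects × 60 epochs at three contrast levels in the rising part
of the contrast–kappa curve (0.05, 0.2, 0.6), where the effect
dominates seed noise; at high contrast kappa saturates near 1 and
monotonicity would be decided by noise.

### A known red flag in the smoothing benchmark

One acceptance check expects probability smoothing to cost at most one
accuracy point and to eliminate single-epoch non-wake islands. Under
the package's own study conditions this is unattainable, and the suite
reports it honestly rather than weakening the check: because raw LOSO
staging of the synthetic cohort is essentially perfect, the only
single-epoch islands left are *genuine* single-epoch stage bouts of the
Markov truth (a first-order chain makes these ~4% of epochs). The
5-epoch moving average relabels most of them — each relabel is an
error — so smoothing costs ≈ 7 accuracy points here, and a single
smoothing pass cannot reach zero islands anyway (relabelling can
create new ones, and wake retention deliberately preserves
wake-flanked structure). In the real setting the smoother targets,
classifier noise far exceeds the truth's single-epoch bout rate and the
same rule helps. The implementation follows the stated rules exactly;
the discrepancy is a property of measuring them against a perfect
classifier on a Markov truth process.

## Numerical choices

* Filters are designed once per (band, rate) and cached; filtering is
  always forward–backward, and tests that assert attenuation measure
  away from the edge transients inherent to zero-phase filtering.
* Welch PSD uses 2-s Hann windows with 50% overlap; integrated band
  powers use the raw periodogram so power in an exact-frequency sine
  concentrates in one bin.
* The spindle CWT uses 7-cycle Morlet wavelets; with 0.5-Hz spacing
  over 11–16 Hz the envelope is insensitive to the exact grid.
* Ties in probability argmax break in the fixed stage order; candidate
  rankings break ties by name; all randomness flows from one root seed
  split per stage of the pipeline, so every artifact of a run is
  reproducible bit for bit.
* Degenerate inputs resolve conservatively: constant signals have no
  Hjorth parameters (missing, later median-imputed), a silent EMG
  proxy has no burst ratio, zero-variance series contribute zero terms
  to the correlation index, and an all-wake night has no onset — the
  post-processed hypnogram is all wake.

## Limitations

The classifier's excellent synthetic performance says nothing about
real-world ear-EEG staging; the generator exists to test mechanics,
not to simulate physiology. N1 detection — poor in every real study —
is artificially easy here. EDF support covers plain continuous EDF
only. The correlation-index ranking assumes a simultaneous scalp
reference and is meaningless without one.
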