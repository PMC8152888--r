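---
title: "meterlab: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{meterlab: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meterlab)
```

This vignette explains the models and procedures the package implements,
the parameters that matter and their defaults, the decisions taken where
the design was genuinely open, and the limits of what the synthetic-data
tests can show.

## Rhythmic pattern space and syncopation scoring

A rhythmic pattern is a cyclic grid of 12 events of 200 ms, 8 filled with
a sound and 4 silent. Two patterns that are rotations of one another are
the same cyclic rhythm, so the space is the set of binary necklaces with
4 zeros: 43 of the 495 raw arrangements survive deduplication (the count
is independently confirmed in the tests by brute-force deduplication and
by the orbit-counting formula). Each necklace is represented by its
lexicographically smallest rotation and ids are assigned in sorted order,
so references are stable across runs.

A metric template with nested pulse periods {2, 4, 12} (in events) assigns
each grid position an integer weight: 0 on the position shared by all
pulses, minus one unit for each pulse level (slowest first) whose grid
misses the position, giving `0 -3 -2 -3 -1 -3 -2 -3 -1 -3 -2 -3`.
Syncopation is scored by the weight-difference rule: every silence is
paired with the most recent sounded event (scanning backwards through the
cyclic pattern) and contributes `w(rest) − w(note)`.

Three summation variants are provided because published implementations
differ in how they treat alignments without syncopation:

- `lhl` (default): sum of the non-negative pair values; if *every* pair is
  negative — each silence sits on a weaker position than the note before
  it, a fully anti-syncopated alignment — the score is −1.
- `positive`: plain sum of strictly positive pair values.
- `signed`: sum of all pair values.

The default was calibrated against three construction facts that hold
simultaneously only under this rule: exactly one of the 43 patterns
attains the maximal syncopation range of 9, the remaining 42 patterns fall
into 8 non-empty groups with ranges 8..1, and the per-group target score
−1 used during sequence construction is attainable. The plain
positive-only rule caps ranges at 8 and makes −1 unreachable; the signed
rule inflates the maximal range to 16 and spreads patterns over 10 range
values. Since the score range across the 12 template alignments is the
package's measure of meter phase-stability, these facts pin the variant
down, and the flag remains available for sensitivity analyses.

## Sequence construction

A sequence concatenates 24 patterns: 3 drawn uniformly with replacement
from each range group, walking the groups from range 8 (phase-stable,
"regular") down to 1 (ambiguous, "degraded"). For each drawn pattern the
rotation whose score is closest to the group target ({1, −1, 0, 1, 2, 3,
4, 4} from the highest group down) is used; exact matches are taken when
they exist, and ties among equally close rotations are broken by a seeded
uniform draw. When a pattern cannot realize its target exactly the nearest
achievable score is accepted rather than re-drawing the pattern — the
groups are small enough that re-drawing could loop, and the nearest-score
rule keeps the syncopation trajectory monotone in expectation. Targets are
constant within a group; the per-group reading of the target list is the
natural one given one target value per range group.

Each sequence gets its own RNG stream seeded by `derive_seed(master, i)`,
so any trial can be rebuilt in isolation. Two sound events pad each end
(292 events, 58.4 s total); analyses drop them via the 0.4-s epoch offset.
The degraded-to-regular twin is the exact time reversal of the core with
padding re-applied; reversal leaves DFT magnitudes untouched, which the
tests verify bin by bin at 1e-9 relative tolerance.

Per-segment syncopation uses the {2, 4} template (the construction meter
without its 12-event pulse, since patterns are not looped) on seven
72-event windows with 50% overlap, taking the minimum score over window
shifts of −2..+2 events; windows are half-open in event units, and the
shifts at the sequence edges index into the padding events. The same
machinery evaluates the {3, 6} and {2, 6} interpretations to confirm that
degrading sequences do not converge onto a different meter.

## Audio rendering

Sound events carry a 440-Hz pure tone with 10-ms linear onset and offset
ramps at a default rate of 44.1 kHz; the carrier restarts at zero phase
each event, so all sound events are identical and the per-event envelope
is time-symmetric. The spectral-identity diagnostics use the ideal
rectangular event gate rather than the rendered carrier: the sampled gate
of the reversed event sequence is exactly the sample-wise reversal of the
original gate, so the identity is exact rather than approximate. Sampling
rates must make a 200-ms event an integer number of samples.

## Auditory periphery

The peripheral model is a gammatone filterbank with 100 ERB-spaced centre
frequencies (50–8000 Hz; the range and count are configuration fields
since no canonical values exist for this stimulus set) followed by a
hair-cell stage, with the per-channel activation block-averaged down to
512 samples/s so the periphery path feeds the same spectral engine as the
EEG. Two hair-cell stages are provided:

- `meddis`: the reservoir hair-cell model implemented from its published
  constants (permeability, replenishment, loss, re-uptake and
  re-processing rates). This is the model on which the low-level control
  analysis is defined.
- `rca` (default for interactive use): half-wave rectification, power-law
  compression (exponent 0.3) and a divisive adaptation loop (strength 5,
  time constant 75 ms). It is several times cheaper and adequate wherever
  only envelope-following non-negative activation matters.

A caveat discovered during validation: the divisive adaptation of the
`rca` stage is causal and asymmetric enough to produce a small systematic
direction difference (about 0.01 z-units, concentrated in the middle
segments) between a sequence and its time inversion — the very middle
segments where the stimuli themselves carry small aligned-segment
syncopation asymmetries. The reservoir model shows no such bias (its mean
paired direction difference stays within two standard errors of zero over
20 sequence pairs), so the periphery null-control test runs with
`haircell = "meddis"`, and results from the `rca` stand-in should not be
used to argue about direction effects at the 0.01 z-unit scale.

## The frequency-tagging engine

Signals are segmented into seven 14.4-s windows with 50% overlap (window
and hop rounded to the nearest sample), averaged across trials in the time
domain per direction/segment cell, and transformed with a plain FFT:
rectangular window, no zero padding, no detrending beyond the upstream
high-pass — the simplest choices consistent with steady-state analysis.
Amplitudes are scaled so a unit sinusoid at an exact bin reads 1.

Broadband background is removed by subtracting, at each bin, the average
of the second neighbouring bin on each side (`k−2`, `k+2`; boundary bins
use the single available neighbour). The literal two-bin reading keeps the
operation linear, zeroes flat spectra, and leaves an isolated peak intact
at its own bin.

The target frequencies are the harmonics of the 12-event (5/12 Hz) and
16-event (5/16 Hz) cycles up to the 5-Hz event rate. The reproducible
union rule yields 24 distinct frequencies, 16 of which are bin-exact at
the 1/14.4-Hz resolution; amplitudes at non-exact frequencies are taken as
the maximum of the two bracketing bins. Published analyses of this
paradigm sometimes quote 21 frequencies with 14 exact bins; no
deduplication rule stated in text reproduces those counts, so the package
keeps the 24-frequency union as the default and accepts an explicit
frequency list through `build_target_frequencies(frequencies = ...)` for
exact replication when a curated set is available. The meter-related
subset is {1.25, 2.5, 5} Hz.

z-scoring uses the sample (n−1) standard deviation across the target set
— the convention is pinned by the documented toy example
(`{1, 2, 3} → {−1, 0, 1}`) — and the mean z over the meter subset is the
summary measure. Because z-scores are invariant to overall gain, the
measure compares frequency *profiles*, not response sizes; the
periphery-vs-response difference score is reported as periphery minus
response. Channel handling follows the order: noise-subtract per channel,
average spectra across channels, then extract.

For the degraded-to-regular direction every table carries both the raw
segment index and `segment_aligned = 8 − segment`, so rows with equal
aligned index always refer to identical stimulus-envelope content across
directions.

## EEG pipeline

Preprocessing is a zero-phase (forward-backward) 4th-order Butterworth
high-pass at 0.1 Hz — phase distortion would corrupt time-domain trial
averaging, at the cost of doubling the effective order, which is recorded
here as a deliberate choice. Epochs of 57.6 s start 0.4 s after each trial
onset, aligned to the nearest sample without sub-sample interpolation, and
are rereferenced to the common average. Trials are paired across
directions by stimulus seed; excluding a trial silently excludes its twin
so direction averages always contain matched material, and unpaired
manifest rows are dropped with a warning. Artifact removal (ICA, channel
interpolation) is out of scope; `preprocess_eeg()` exposes a `hooks` list
where such steps can be plugged in.

## Tapping analysis

Tap onsets are samples where the signal rises (strictly positive first
difference), crosses the threshold from below, and falls at least the
refractory period (default 100 ms) after the previous onset. The default
threshold is 5 times the median absolute amplitude — a robust noise-floor
multiple standing in for the per-participant manual settings used with
real sensors — with a fallback to half the peak for noiseless sparse
signals.

Percent differences use the candidate period as denominator
(`100·|ITI − P| / P`), fixed by the worked examples: a 500-ms median ITI
is 25% from the {2,4}-meter (closest period 400 ms), and alternating
380/420-ms intervals give a 5% ITI-error. ITIs longer than 2 s count as
pauses and are removed before scoring. The ITI-error is invariant to
global time shifts (robust to tapping-phase changes) but rises when the
tapping period switches inside a window; the spectral meter prominence is
the complement — period switches move energy only among meter-related
frequencies, while phase resets lower it. Tapping spectra default to
time-domain trial averaging before the FFT, matching the EEG path; a
`freq_domain_average` flag averages magnitude spectra across trials
instead, since the order of those operations is ambiguous in prose
descriptions of the paradigm. One estimator property worth knowing: under
pure noise (e.g. uniformly random tap times) the meter-related mean z sits
slightly below zero rather than at zero, because the max-of-two-closest
rule positively biases the non-exact bins — all of which are
meter-unrelated — while the bin-exact meter frequencies are unbiased. The
measure therefore errs against, not towards, spurious meter prominence.

## Synthetic data and what the tests show

Synthetic EEG trials are sums of cosines at the target frequencies with
per-(direction, segment) amplitudes, cross-faded between overlapping
segments with triangular weights summing to one, mixed into 4 channels
with a fixed profile, plus independent 1/f noise per channel (generated at
a power-of-two length for FFT speed and truncated). Phases are drawn once
per participant and reused across trials, so time-domain averaging
preserves the deterministic component exactly while the noise shrinks as
1/sqrt(trials). A degraded-to-regular trial is the time reversal of its
proto-core built on the aligned segment grid, mirroring the inverted
stimuli: in the null world, direction-aligned segments are then exactly
identical in magnitude, and the whole-pipeline type-I error can be checked
against zero.

The context effect is injected as a multiplicative gain on the
meter-subset amplitudes (default cell: regular-to-degraded, aligned
segment 4) rather than an additive offset, so recovering it through the
gain-free z measure is a non-trivial test. Because the analysis windows
overlap by 50%, a gain confined to one segment necessarily bleeds into its
two neighbours at roughly half strength; the recovery tests therefore
require the flagged segment to carry the maximal and clearly positive
difference and the non-adjacent segments to stay near zero, rather than
demanding exact zeros next door.

Synthetic tapping is an impulse train (damped 20-ms pulse per tap) with
Gaussian motor jitter (default SD 10 ms), per-7.2-s-boundary Bernoulli
phase resets and period switches, and per-tap misses.

What passing these tests does *not* show: the generator contains no
volume conduction, no alpha or other oscillatory structure beyond 1/f, no
artifacts, no inter-individual variability in spectral shape, and its
"context effect" is injected directly at the target frequencies. The
tests validate that the pipeline measures what it claims to measure and
recovers known ground truth — not that real EEG satisfies the generator's
assumptions.

## Numerical choices and problem sizes

- Sampling grids: deterministic unit tests run at 500 samples/s, where
  200-ms events, 14.4-s windows and 7.2-s hops are integer sample counts
  and 16 of the 24 target frequencies are bin-exact; cohort-level tests
  run at the realistic 512 samples/s, where windows are rounded to 7373
  samples and bin misalignment adds per-segment variability that averages
  out across participants.
- Audio for periphery runs is rendered at 18 kHz (integer 200-ms events,
  Nyquist above the 8-kHz top centre frequency); stimulus WAVs default to
  44.1 kHz.
- Validation problem sizes: 100 seeds for sequence-construction checks,
  20 seed pairs for the inversion identity and the periphery null control,
  a 16-participant × 15-trial-pair cohort for the context-gain recovery
  and the null-world calibration, and 4–8 replicate simulations for the
  tapping dissociations.
- Seeds are fixed in tests; all randomness flows through
  `derive_seed(master, index)` streams, keeping every derived seed below
  2^31.

## Known limitations

- The syncopation scorer supports any strictly nested template on any
  cycle, but not non-nested or additive meters, and no other syncopation
  indices.
- The EDF reader/writer covers continuous equal-record files as produced
  by the package (and common acquisition systems), not annotations or
  discontinuous recordings.
- Group-level inferential statistics (mixed models, Bayes factors) are
  intentionally absent; the output tables are tidy inputs for `lme4` or
  similar.
- The `rca` hair cell's small direction asymmetry (above) makes it
  unsuitable for fine-grained direction-difference control analyses; use
  `haircell = "meddis"` there.
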