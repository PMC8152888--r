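# meterlab

Tools for frequency-tagging studies of rhythm and meter processing:
stimulus construction for sequences that morph between metrically regular
and degraded rhythms, and the full analysis chain for the EEG, tapping and
auditory-model signals such experiments produce.

## The scientific problem

When people listen to rhythmic sequences they often perceive a *meter* — a
nested set of periodic pulses (here at 5, 2.5 and 1.25 Hz over a 5-Hz tone
stream). Frequency-tagging experiments test how strongly the brain (or
tapping behaviour, or a cochlear model) locks onto these meter
periodicities by measuring narrow spectral peaks at meter-related
frequencies relative to the full set of stimulus-related frequencies. To
study how *recent context* shapes this meter representation, stimuli are
built so that acoustic cues to the meter fade gradually (regular to
degraded), and each sequence is paired with its exact time inversion
(degraded to regular) — the two have bin-for-bin identical envelope
magnitude spectra, so any difference between direction-matched segments in
a response must reflect stimulus history rather than stimulus content.

The package implements:

- **Pattern space** — all 43 cyclic arrangements (binary necklaces) of 12
  200-ms events with 8 sounds and 4 silences, scored for syncopation
  against a nested metric template by weight-difference scoring: each
  silence is paired with the most recent sounded event and contributes
  `w(rest) − w(note)`; non-negative pair values are summed, and a fully
  anti-syncopated alignment scores −1. The score *range* across the 12
  template phases (max − min) measures meter phase-stability: exactly one
  pattern attains the maximal range of 9, and the remaining 42 fall into 8
  groups with ranges 8..1.
- **Sequence construction** — seeded 57.6-s sequences of 24 patterns (3
  per range group, from range 8 down to 1), with each pattern's rotation
  chosen so the syncopation score tracks the per-group targets
  {1, −1, 0, 1, 2, 3, 4, 4}; time inversion; audio rendering (440-Hz tone,
  10-ms linear ramps); per-segment syncopation under {2,4}, {3,6} and
  {2,6} templates (minimum over −2..+2 event shifts).
- **Auditory periphery** — gammatone ERB filterbank (100 channels,
  50–8000 Hz) with either a reservoir hair-cell model or a fast
  rectify-compress-adapt stage, as a control for low-level nonlinear
  explanations.
- **Frequency-tagging engine** — 7 overlapping 14.4-s segments (50%
  overlap), time-domain trial averaging, FFT magnitude spectra,
  second-neighbour-bin noise subtraction, extraction at 24 target
  frequencies (harmonics of 12- and 16-event cycles up to 5 Hz), z-scoring
  across the target set, and the mean z at meter frequencies
  (1.25/2.5/5 Hz) as a gain-free prominence measure.
- **EEG pipeline** — 0.1-Hz zero-phase Butterworth high-pass, epoching at
  0.4 s past trial onset, common-average reference, per-participant
  summaries with direction-matched trial pairing.
- **Tapping analysis** — rising-edge tap detection with threshold and
  refractory period, median-ITI meter matching, the ITI-error index (with
  2-s pause exclusion), and tapping spectra through the same engine.
- **Synthetic data** — EEG-like cohorts (target-frequency cosines with a
  controllable meter gain in chosen direction/segment cells, 1/f noise)
  and tapping trains (jitter, phase resets, period switches, misses) with
  known ground truth, so the whole pipeline is testable end to end.

## Worked example

```r
library(meterlab)

pats <- enumerate_patterns()
nrow(pats)
#> [1] 43

tpl <- metric_template(c(2, 4, 12))
tpl$weights
#>  [1]  0 -3 -2 -3 -1 -3 -2 -3 -1 -3 -2 -3

groups <- categorize_patterns(pats, tpl)
groups$max_range
#> [1] 9
groups$working_ranges
#> [1] 8 7 6 5 4 3 2 1

s <- build_sequence(seed = 1)
s
#> Rhythm sequence (regular_to_degraded, seed 1)
#>   24 placements, 288 core events (57.6 s), 292 padded events (58.4 s)
#>   group order: 8 8 8 7 7 7 6 6 6 5 5 5 4 4 4 3 3 3 2 2 2 1 1 1
#>   achieved scores: 1 1 1 -1 -1 -1 0 0 0 1 1 1 2 2 2 3 3 3 4 4 4 4 4 4

segment_syncopation(s)$per_segment
#>  1  2  3  4  5  6  7
#>  1 -1  3  9 11 11 15
```

The 43 patterns split by syncopation range; sequences walk the groups from
phase-stable (range 8) to ambiguous (range 1) while the achieved
syncopation scores follow the targets; the per-segment syncopation of the
built sequence rises as the rhythm degrades.

## Command line

```sh
Rscript -e 'meterlab::meterlab_cli()' patterns --template 2,4,12
Rscript -e 'meterlab::meterlab_cli()' build --n-sequences 15 --seed 1 --out stim/
Rscript -e 'meterlab::meterlab_cli()' synth --out data/ --participants 2 --trials 2
Rscript -e 'meterlab::meterlab_cli()' freqtag --manifest data/eeg_manifest.tsv --in data/ --origin eeg --out results/
Rscript -e 'meterlab::meterlab_cli()' tap --manifest data/tap_manifest.tsv --in data/ --out results/
```

See the methods vignette (`vignettes/meterlab-methods.Rmd`) for the model
assumptions, parameter choices and known limitations.
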