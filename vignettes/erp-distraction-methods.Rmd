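---
title: "Methods: simulating and measuring distraction ERPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring distraction ERPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpdistract)
```

## The problem this package addresses

In auditory-visual distraction paradigms, listeners ignore a tone stream
(70% standard tones, 15% deviant tones, 15% unique environmental "novel"
sounds) while categorizing visual stimuli (Go: numbers and letters; NoGo:
triangles) that follow each sound at a 300-ms onset-to-onset lag. Rare
sounds capture attention involuntarily, which shows up behaviorally as a
reaction-time cost on the following Go response and electrophysiologically
as a cascade of difference-wave components: the mismatch negativity (MMN,
automatic change detection, 100-250 ms), an early and a late P3a phase
(orienting and subsequent evaluation, 280-400 and 350-500 ms), and the
reorienting negativity (RON, return of attention to the task, 400-700 ms).
All four are measured on the novel-minus-standard (N-S) and
deviant-minus-standard (D-S) difference waveforms. Aging studies in this
paradigm compare component amplitudes and latencies across Young,
Middle-aged, and Old groups.

The original recordings behind such group tables are generally not
deposited. This package therefore pairs the complete measurement pipeline
with a synthetic-data generator whose defaults *are* the published group
parameter table, so that every stage — signal chain, peak measurement,
topography, statistics — can be validated by parameter recovery: simulate
EEG with known embedded components, run the pipeline, and check that the
known parameters come back.

## The generator

### Task and behavior

`task_config()` encodes the session: 500 A-V pairs in 2 blocks, exact
stratified counts (350/75/75 sounds; 165/165/170 visual stimuli with the
NoGo triangles absorbing rounding), 150-ms sounds, 300-ms SOA, 2000 ms
between pair onsets. `generate_timeline()` realizes the counts exactly and
shuffles per seed.

Trial RTs follow `rt_model()`: group base mean (467/612/623 ms for
Young/Middle-aged/Old) + condition offset + Gaussian trial noise truncated
at 100 ms. The condition offsets derive from the emulated condition means
(556/560/587 ms for Standard/Deviant/Novel) by centering to zero sum, so
the unweighted mean of a subject's three condition means equals the group
base mean *exactly* in the noiseless model. That aggregation — condition
means first, then their average — is also what the RT ANOVA uses; a
trial-weighted mean would not recover the base mean because the three
conditions contribute unequal trial counts. Trial SD defaults to 100 ms
and the miss probability to 2% (plausible values; the emulated study
reports only means and between-subject SDs).

### Waveforms

Each component is a raised-cosine (Hann) bump with compact support
(half-width 55 ms), scaled per channel by a topography interpolated from
anchor amplitudes at Fz/Cz/Pz and tapered to zero at a 90-degree arc from
the vertex. The default anchors and peak latencies are the published group
means, shipped as a versioned CSV
(`inst/extdata/component_templates_default.csv`). Two conventions matter:

* **Compact support.** The smallest latency gap between adjacent
  components anywhere in the default table is 71 ms (Middle-aged N-S
  e-P3a at 380 ms to l-P3a at 451 ms), which exceeds the 55-ms half-width,
  so no kernel contributes signal at another kernel's peak.
  `render_difference_wave()` verifies this and errors otherwise. The
  payoff is that parameter recovery is *exact*, not tolerance-based.
* **One sign correction.** One published cell (Old group, D-S RON at Cz)
  is printed as +2.9 uV, against the component's defining negative
  polarity and every neighboring cell; the shipped table stores -2.9 and
  marks the cell in its `flag` column. With the printed sign the cell
  would be unmeasurable under the component's definition (no negative
  peak to find), so the value is treated as a typographical sign error
  rather than a group-level polarity reversal; the flag preserves the
  discrepancy rather than silently resolving it.
* **Off-grid latencies.** Several published latencies (163, 297, 527 ...)
  are odd numbers of ms and therefore fall between samples of the 500-Hz
  (2-ms) epoch grid. Clean difference waves are rendered on a 1-ms grid
  by default, where recovery is exact; the full recording path is sampled
  at 500 Hz and recovers latencies to within one sample.

Table cells the table does not contain (MMN at Fz/Pz, RON at Pz) get
synthetic anchors as fixed fractions of the Cz value reflecting the
components' fronto-central distributions; they shape the topography only
and are never measured against the table.

`render_recording()` builds continuous EEG: a common auditory (N1/P2) and
visual (P1/N1) evoked response on every trial — identical across
conditions, so it cancels exactly in the difference waves — plus the
group's D-S/N-S composite on deviant/novel trials, plus noise:
spatially correlated 1/f background (10 uV RMS, correlation length 40
degrees), a posterior 10-Hz alpha oscillation (3 uV), and stereotyped
blinks (5/min, 150 uV at the upper vertical EOG electrode, projected to
the scalp with a steep frontal gradient). Trial-level latency jitter is
available but defaults to 0 (no published value exists; the default keeps
the generator's calibration property exact).

`generate_cohort()` draws per-subject parameters around the table means
with the table SDs (latencies clamped to their search windows and to the
55-ms gap constraint; amplitudes clamped away from zero with the correct
polarity), using child seeds `master_seed * 1000 + subject index` so any
subject is reproducible in isolation. Recordings are large, so a
`process` callback lets callers stream the cohort subject by subject.

### What the generator does not emulate

Real EEG has non-Gaussian artifacts, drifting alpha, heteroscedastic
trial noise, component shapes that are neither symmetric nor constant
across trials, and latency/amplitude correlations across components.
Passing recovery tests here demonstrates that the *pipeline* is correct
and unbiased under the stated model; it does not certify performance on
arbitrary real recordings.

## The measurement pipeline

The chain runs in a fixed order: ocular regression -> epoching ->
zero-phase band-pass -> baseline correction -> rejection -> averaging ->
differences.

* **Ocular correction** regresses each scalp channel on the centered
  bipolar vertical and horizontal EOG derivations. Regression is the
  era-typical choice; `ocular = "none"` disables it.
* **Epoching** takes [-150, 1300] ms around each auditory onset (both
  endpoints on the grid; 726 samples at 500 Hz), Go-paired events only.
* **Filtering** realizes the 0.1-30 Hz, 24 dB/octave band as 4th-order
  Butterworth high- and low-pass sections applied forward and backward
  (zero phase), with even-reflect padding of three settling lengths
  (capped at the segment length). Zero-phase application is chosen so
  that peak latencies are unbiased; the squared-magnitude response still
  satisfies the design targets (DC < 1e-3, 10 Hz >= 0.95, 60 Hz > 12 dB
  down). Filtering after segmentation follows the documented stage order
  of the emulated protocol; rejection happens post-filter.
* **Baseline** subtracts the mean over [-150, 0) ms per epoch and channel.
* **Rejection** drops epochs exceeding +-100 uV on any *scalp* channel
  (EOG channels routinely exceed that and are not tested) and the first
  five A-V pairs of each block, regardless of condition. Membership
  changes; data never do.

### Peak measurement

Amplitude is the signed value at the peak sample ("peak to baseline",
which is zero after baseline correction); latency is read at Cz, where
these components are maximal. `find_window_peak()` returns the local
extremum of the requested polarity with the largest magnitude inside the
window. Local extrema are assessed on the full trace, so a window
boundary counts only when the signal genuinely turns there; ties break
toward the earlier sample; a component with no extremum of its polarity
in its window is "not identifiable", and cohort analyses exclude such
subjects per component (mirroring the per-component analysis-sample
attrition such studies report).

The e-P3a (280-400 ms) and l-P3a (350-500 ms) windows overlap. Because
the two phases are consecutive, the l-P3a search is restricted to
latencies strictly later than the e-P3a peak found at Cz; without this
rule the l-P3a measure would simply re-detect a late, large e-P3a (for
the Middle-aged N-S defaults: 380 ms / 12.9 uV would be returned twice
instead of 380/12.9 followed by 451 ms / 11.7 uV).

### Topographies

`voltage_map()` reads the instantaneous scalp map at the nearest sample.
`csd_map()` computes the current source density as the negative surface
Laplacian of a spherical-spline interpolation (flexibility m = 4, ridge
regularization 1e-5, 50 Legendre terms — the field-standard
parameterization). The transform is linear and reference-free (adding a
constant to all electrodes changes nothing), and with zero
regularization the interpolation passes through the data. Maps are taken
at the grand-average difference wave's measured peak latencies.

## Statistics

`mixed_anova()` implements the classical univariate mixed-model analysis:
subjects nested in groups, within effects tested against their own
subject-interaction strata, Type III sums of squares with unweighted cell
means for the unbalanced between factor (18/20/15), Greenhouse-Geisser
epsilon from the pooled within-group covariance of orthonormal contrast
scores, applied to every within effect with more than two levels
(epsilon = 1 exactly for two levels), and partial eta squared
SS_effect / (SS_effect + SS_error). The implementation is validated in
the test suite against `aov` error strata on balanced designs and
against `car::Anova` (type III, multivariate-to-univariate with GG
correction) on unbalanced ones, to 1e-8.

Post-hoc comparisons are all pairwise t-tests within the decomposed
factor's family (pooled-variance two-sample for between, paired for
within), with p multiplied by the family size and capped at 1. Cohen's d
uses the two-group convention of common power-analysis software,
|m1 - m2| / sqrt((sd1^2 + sd2^2)/2), which reproduces the emulated
study's printed Old-vs-Young RT effect size from its printed summary
statistics to +-0.01; for within designs d = |mean difference| / SD of
differences.

RT analysis includes correct Go responses with RT in [100, 1500] ms
(the source protocol does not state its inclusion rule; both bounds are
configurable), aggregates to subject x condition means, and runs the
Group x Condition ANOVA with both post-hoc families.

## Numerical choices and edge cases

* All-identical data: an effect with zero sum of squares reports F = 0
  (the wide score matrix is grand-mean centered first so that this holds
  exactly in floating point).
* Zero-variance post-hoc contrasts (possible in noiseless simulations)
  report the limiting values: p = 1 and t = 0 for a zero difference,
  p = 0 and infinite t otherwise, with d undefined (NA).
* Epochs whose window would cross the recording edge are dropped with a
  logged count. Rejection reasons are recorded per epoch
  (`amplitude` / `initial` / `ok`).
* The recording container stores the data matrix as raw little-endian
  doubles plus CSV/JSON sidecars; round trips are bit-exact.
* Latency precision under noise is curvature-limited: for a raised
  cosine of height A and half-width 55 ms under 1-uV band-limited noise
  the median absolute peak shift is about one sample for A near 19 uV
  and a few samples for A near 13 uV. The robustness test asserts these
  curvature-scaled bounds.

## Problem sizes used in the tests

The shipped tests run the full pipeline at reduced scale chosen for quick
iteration: cohorts of 2-6 subjects at 16-120 pairs for end-to-end checks,
the full 53-subject structure for behavioral-only analyses (no EEG
rendering), 200 replicates for the distraction-ordering and
latency-robustness Monte-Carlos, and 2000 replicates (3 groups x 10
subjects, three-level within factor) for the type-I-error calibration of
the ANOVA engine. Clean-waveform parameter recovery is exact and runs at
full resolution.

## Known limitations

* The 49-electrode label set is a documented default (the published
  montage lists only its size and system); any montage containing
  Fz/Cz/Pz works.
* The visual P3b that follows Go stimuli is deliberately not modeled or
  measured.
* No ICA, channel interpolation, or re-referencing; import of vendor EEG
  formats is out of scope (use the documented container).
* The Greenhouse-Geisser correction is applied unconditionally (no
  Mauchly gate), and epsilon is always reported for >2-level factors.
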