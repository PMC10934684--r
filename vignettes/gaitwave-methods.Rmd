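---
title: "Gait-phase-locked EEG analysis with gaitwave: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait-phase-locked EEG analysis with gaitwave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitwave)
```

## The problem

During walking, cortical activity is modulated within each stride. To study
it with mobile EEG, recordings are cut into gait cycles (initial contact to
initial contact of the same leg), each cycle is normalized to a common
0–100% phase axis, and amplitudes are averaged across cycles and subjects.
Group differences are then tested at every phase point, which creates a
multiple-comparisons problem over a smooth 1-D continuum; statistical
non-parametric mapping (SnPM) solves it with permutation max-statistics.

`gaitwave` implements this chain for a 2 × 2 mixed design — walking surface
group (O = overground, T = treadmill; between subjects) crossed with speed
control condition (sSC = self-selected, SC = metronome-paced; within
subjects) — together with a synthetic-data generator that makes every stage
testable without laboratory recordings.

## Acquisition model

Recordings pair 32-channel EEG (10-20 montage, 512 Hz) with a right-thigh
flexion angle from an IMU (200 Hz), synchronized by shared markers (sample
1 of both streams is time 0). Thirty electrodes are analyzed; CPz serves as
online reference, AFz as ground, and the mastoids are recorded but not
analyzed, so every analysis matrix has 30 rows.

## Filtering

Each analysis band uses two zero-phase 4th-order Butterworth stages around
the ICA step:

| band  | pre-ICA band-pass | post-ICA low-pass |
|-------|-------------------|-------------------|
| delta | 0.5–100 Hz        | 4 Hz              |
| theta | 4.5–100 Hz        | 7.5 Hz            |
| alpha | 8–100 Hz          | 12 Hz             |
| beta  | 13–100 Hz         | 30 Hz             |

plus a 50 Hz band-stop (49–51 Hz, 4th order) for mains interference. The
wide pre-band keeps broadband structure for the ICA; the post low-pass
restricts the cleaned signal to the band of interest. Filters are applied
forward–backward: gait-phase alignment cannot tolerate group delay, so the
effective magnitude response is the design's squared, |H(f)|², and the
phase response is zero. Whether to filter causally instead is exposed as an
option (`zero_phase = FALSE`). Edges are handled with odd-symmetric signal
extension plus steady-state initial conditions; the band-stop half-width
(1 Hz) is a design choice, as only the center frequency and order are
standard.

One consequence worth knowing: at metronome-paced slow walking (68 strides
per 3 min), the stride fundamental is 0.38 Hz — *below* the 0.5 Hz delta
edge — so a smooth once-per-cycle waveform is strongly attenuated and the
delta-band cycle matrices of such recordings are dominated by narrower
gait-locked transients and residual background activity. Faster cadences
(≈1 stride/s) put the fundamental inside the band.

## fastICA and artifact removal

The decomposition follows the staged fixed-point procedure: per-channel
mean removal, covariance eigendecomposition, retention of the leading
`n_components` principal components (default 5), whitening, then symmetric
fixed-point iteration with the tanh contrast (tolerance 1e-4, at most 1000
iterations, seed mandatory — there is no hidden RNG). Symmetric (parallel)
orthogonalization is the default for determinism and robustness; deflation
is available.

Five components out of 30 channels is deliberately aggressive: in walking
EEG the large-variance subspace is dominated by ocular, glossokinetic and
muscle activity, so the retained components are typically all artifacts and
the cortical signal survives in the residual outside the top-5 subspace.
Both behaviors are reachable: `clean_artifacts(remove = "non_brain")`
(default) drops only components classified as artifact, `remove = "all"`
analyzes the residual unconditionally.

Classification is rule-based on each component's scalp map and spectrum:

* **ocular** — squared-weight share on Fp1/Fp2/Fpz above 0.35 *and* more
  than half the power below 4 Hz (captures blinks and slow horizontal eye
  movements);
* **muscle** — more than 40% of power above 20 Hz;
* **glossokinetic** — low-frequency dominance with at least 45% of squared
  weight on the inferior-frontal/temporal ring (Fp1, Fp2, Fpz, F7, F8, T7,
  T8, M1, M2);
* otherwise **brain**.

Thresholds are configurable; the defaults were calibrated on the
generator's source topographies so each rule separates its intended source
class with margin. They are heuristics, not a learned classifier, and on
real data they should be audited via the returned score table.

## Gait segmentation

Initial contact is the maximum of the right-thigh flexion angle; each cycle
runs between successive contacts and splits into stance and swing at the
in-cycle angle minimum. Detection finds strict local maxima (plateau ties
resolve to the first sample), prunes them greedily from the highest down
with a minimum separation (`min_period`, default 0.5 s — safe for the slow
walking this pipeline targets), and applies a walk-out prominence test
(default 5°; at a record edge the intact flank alone is judged so the first
and last part-cycles are not lost).

A raw argmax locates a smooth ~20°-amplitude peak only to within tens of
milliseconds once degree-scale noise is present, because the peak's
curvature is shallow. `detect_initial_contacts(refine = TRUE)` therefore
adds a matched-filter step: the angle around every peak is averaged into a
cycle template — each window's left and right halves scaled by that cycle's
own neighboring stride durations, so stride-time variability does not smear
the template — and each contact shifts to the lag minimizing the squared
mismatch. On noise-free traces this is a no-op (timing is exact to the
sample); at 1° added noise it reduces timing error from ≈50 ms to a few
milliseconds RMS, with the first/last contacts retaining argmax precision.
Sub-sample accuracy at that noise level is not attainable by any estimator
here: the Cramér–Rao bound for this waveform at 200 Hz is itself ≈2 ms.

Cycles with durations outside [0.5, 1.5] × median are invalidated by the
default policy (`"none"` keeps all). Events map to EEG samples as
`round(time × eeg_rate)` with half-open `[start, end)` ranges, so adjacent
cycles share the boundary sample exactly once. Stride *tables* count
initial contacts (strides initiated in the walk, matching how cohort stride
counts are reported); the stricter count of validated complete cycles is
carried separately.

## Epoching and normalization

Per cycle and per electrode, the trace is divided by its own maximum
absolute amplitude (the "local peak"; a global-across-electrodes option
exists) and then linearly resampled to 100 points spanning [0%, 100%) —
normalization first, then time normalization. The half-open grid means a
length-100 segment maps onto itself exactly and the next contact's sample
is never double-counted. Cycle traces average into a subject's 30 × 100
cycle matrix; subjects average into per-cell group maps (mean and sample
SD). Matrices are in normalized arbitrary units by default; microvolt
(non-amplitude-normalized) matrices are available via
`amplitude_normalize = FALSE`, since summaries in both units are
conventional.

## SnPM inference

At each of the 100 phase points a classical 2 (between) × 2 (within)
mixed-design ANOVA is computed: the group effect is tested against the
subject-within-group mean square, condition and interaction against the
condition × subject-within-group mean square. The implementation is
vectorized sums-of-squares algebra over per-subject condition sums and
differences; tests verify it against both a naive textbook oracle and
`aov()` error-strata fits to 1e-8.

Family-wise inference over the continuum uses the permutation distribution
of the maximum F across the 100 points. Permutation schemes respect
exchangeability under each null:

* **group** — permute group labels across subjects (subjects stay whole);
* **condition** — swap the two condition labels independently per subject;
* **interaction** — condition swaps composed with group-label permutation
  (the standard scheme for mixed designs; approximate, as documented in
  the SnPM literature).

All distinct permutations are enumerated when there are no more than
`n_perm` (default 10,000); otherwise Monte Carlo sampling with the identity
permutation always included. F\* is the (1−α) empirical quantile of the
max-F sample; requesting an α finer than the permutation resolution is an
error. Suprathreshold clusters (runs of F ≥ F\*) get p-values from the
permutation distribution of the largest suprathreshold run length (add-one
corrected), with endpoints reported in percent of gait cycle, linearly
interpolated at threshold crossings. Zero-variance timepoints are excluded
from the max statistic with a warning.

Electrode-wise analyses are *not* corrected across electrodes by default
(mirroring electrode-wise reporting conventions); `fwe_electrodes = TRUE`
Bonferroni-adjusts α by the electrode count. Post hoc contrasts — OSC vs
OsSC and TSC vs TsSC (paired), OSC vs TSC and OsSC vs TsSC (unpaired) — use
max-|t| permutation tests over the full cycle (running them inside
significant windows only is a plausible alternative; full-cycle is the
default because the windows are themselves data-dependent), Bonferroni
multiplied by the number of executed comparisons. A Shapiro–Wilk screen of
cell-centered residuals is computed as advisory output only; the pipeline
always proceeds to permutation inference, which does not assume normality.

## The synthetic generator

`generate_subject()` emulates one subject-condition walk:

* **Gait timing** — stride durations 1/rate × (1 + cv·N(0,1)), truncated to
  [0.5, 1.5] × the base period. The record starts mid-swing so the first
  contact is a detectable peak. Stance fraction defaults to 60% — the
  conventional stance share; it is a convention, not an empirical value.
* **Thigh angle** — per cycle a piecewise cosine with its unique maximum at
  the contact and unique minimum at the stance→swing transition (amplitude
  20°, offset 10°).
* **Cortical component** — a stereotyped waveform (fundamental + weaker
  second harmonic, `gait_template()`), time-warped to each cycle and mixed
  to the scalp with a fronto-central Gaussian topography, 4 µV at its peak
  electrode.
* **Artifacts** — blinks (0.25/s, 100 µV, frontal), slow horizontal eye
  movements (left–right frontal dipole), glossokinetic activity (0.5–2 Hz,
  30 µV, inferior-frontal/temporal) and two EMG sources (20–80 Hz, 15 µV,
  left/right temporal). Topographies are fixed anatomical Gaussian profiles
  on 10-20 coordinates — smooth, distinct scalp patterns that make source
  recovery well-posed and keep the classification rules meaningful.
* **Background** — 1/f-shaped Gaussian noise, 2 µV per channel; a spectral
  shape, not a claim of physiological fidelity.
* **Effects** — `effect_spec()` adds a raised-cosine bump (peak
  `amplitude_delta` µV) inside a stated percent-phase window at stated
  electrodes, only in the named design cells. `amplitude_delta` is defined
  on the *recording* (per-cycle) scale; ensemble averaging over a subject's
  cycles then raises the subject-level signal-to-noise ratio exactly as it
  does in real data.

Cohort cadences mimic the 3-min protocol: sSC stride counts drawn from
N(116.7, 17.0) for treadmill and N(88.4, 16.0) for overground subjects, SC
counts from N(68, 0.75) for both (metronome lock). The packaged
`stride_counts.csv` fixture holds the 24-subject table these models are
calibrated to.

What the generator does *not* emulate: biomechanically realistic joint
kinematics, treadmill-vs-overground physiological differences beyond the
injected effect, electrode impedance drift, clock drift between streams, or
non-stationary artifact statistics. Passing tests therefore demonstrate
that the machinery is correct and calibrated on data with known structure,
not that real recordings satisfy the generator's assumptions.

## Statistical simulations and problem sizes

Large simulation studies run at the epoched (cycle-matrix) level via
`simulate_matrix_cohort()`: per subject and condition, the electrode's
template (subject gain SD 0.1, condition-level gain SD 0.05) plus smooth
noise whose SD is the per-cycle noise (0.5 a.u.) divided by √(stride
count), i.e., what cycle averaging leaves behind. This makes a 200-cohort
calibration study take seconds while exercising the identical inference
code; the full recording → matrix chain is validated end-to-end separately.
Package tests use these sizes: type-I error over 200 null cohorts
(n = 12/group, 1000 permutations, expecting a rate in a binomial band
around 0.05); power over 50 cohorts with a 1.5 × per-cycle-noise-SD
interaction injected at Fz over 3–8% of the cycle; and one full-pipeline
recovery run at n = 6/group with 90-s walks and a 20 µV injection (short
metronome-cadence walks average few cycles, so the desk-scale run needs a
strong effect; the study-scale power property is established at the matrix
level).

## Numerical choices

* Rounding of stride summaries: half-away-from-zero at one decimal; SDs use
  the n−1 denominator (this reproduces the calibration table's printed
  values; the population SD does not).
* EDF storage is 16-bit with per-channel linear scaling; round-trips are
  exact to the quantization step (channel range / 65535).
* Permutation p-values use add-one correction and can never be 0; F\* uses
  the ceiling-index empirical quantile.
* Flat (all-zero) electrode-cycles are an error naming the electrode;
  zero-variance timepoints in permutation tests are excluded from the max
  statistic with a warning; 0/0 F statistics are flagged degenerate.
* Plateau ties in peak/trough detection resolve to the first sample, for
  determinism.

## Known limitations

Classification thresholds are tuned to the generator's topographies and
should be reviewed on real data. The interaction permutation scheme is
approximate (as is standard). The vendor's Kalman smoothing of IMU angles
is treated as upstream: the module accepts smoothed angles and offers only
a simple moving-average pre-smoother. The IMU axis sign convention is not
standardized across vendors; `flip_sign` handles inverted conventions.
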