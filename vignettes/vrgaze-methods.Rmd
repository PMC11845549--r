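---
title: "Classifying VR gaze data and deriving fixation-onset EEG measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying VR gaze data and deriving fixation-onset EEG measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(vrgaze)
library(dplyr)
```

## The problem

Mobile virtual-reality experiments record eye tracking while the observer
*walks*. Classical velocity-based saccade detection assumes a stationary
eye: it thresholds the angular velocity of the gaze direction. When the
observer translates, two things break. First, keeping the eyes on a fixed
object while walking requires continuous compensatory eye rotation — real
angular velocity with no oculomotor event of interest. Second, the same
allocentric eye direction sweeps across the scene as the observer moves, so
"no rotation" does not mean "no gaze shift". Both errors scale with
translation speed and inverse viewing distance.

`vrgaze` classifies such data by working in *scene space* instead. The VR
engine reports, per sample, where the gaze ray hits the scene (the *hit
point*). The package computes the velocity a stationary eye would have
needed to produce the observed hit-point motion, classifies gaze events
(fixations and smooth pursuit, pooled) and saccades with a robust adaptive
threshold, aligns the eye-tracking clock with a co-recorded EEG clock, and
derives fixation-onset event-related potentials (fERPs) and spectral
perturbations (fERSPs) from the classified gaze onsets.

## Movement-corrected angular velocity

For consecutive samples at $t_1 < t_2$ with hit points $h_1, h_2$, eye
position $o_1$ and unit viewing direction $d_1$ (both at $t_1$):

1. hit shift: $v = h_2 - h_1$. If the viewed point did not move, $v = 0$
   and stays zero through every later step — walking past a fixated object
   produces exactly zero velocity.
2. in-plane component: $v_\perp = v - \langle v, d_1\rangle\, d_1$, the
   orthogonal rejection from the viewing direction. The parallel component
   is a change of viewing *distance*, not of direction.
3. angular velocity:
   $\omega = \dfrac{\operatorname{atan2}\!\big(\lVert v_\perp\rVert,\; \lVert o_1 - h_1 \rVert\big)}{t_2 - t_1}$
   in degrees/second.

`atan2` takes the in-plane displacement over the viewing distance, so
$\omega \to 0$ as the displacement vanishes; the angle is evaluated from
the $t_1$ viewpoint. Conversely, pure observer translation with a *fixed*
allocentric eye direction makes the hit point slide along surfaces and is
correctly read as eye movement in scene space.

Velocities are clipped at 1000°/s (a biological ceiling; faster apparent
motion is measurement error) and optionally smoothed by a Savitzky–Golay
filter applied within maximal valid runs.

### Why the default Savitzky–Golay window is 3 samples

At 90 Hz a saccade spans 3–5 frames. A 5-point quadratic window smears each
saccade boundary by about one frame per side and inflates saccade durations
by ~40% of their median, which destroys sub-frame onset accuracy — the one
thing fixation-onset EEG needs. The default window is therefore 3 samples
at order 2, which is an exact polynomial fit, i.e. no additional smoothing
beyond the 5-point *median* filter already applied to positions and hit
points (median filters suppress impulse noise without moving edges). Both
`sg_window` and `sg_order` are arguments of `condition_velocity()` /
`classify_gaze()` for data that needs real smoothing.

## Adaptive classification

A single global threshold fails on long free-exploration recordings because
noise is non-stationary. The classifier therefore:

1. computes a **global** robust threshold
   $\theta = \mathrm{median}(\omega) + k\cdot\mathrm{MAD}(\omega)$ with the
   raw (unscaled) median absolute deviation and $k = 3$ by default;
2. segments the recording, either **data-driven** — maximal suprathreshold
   runs are ranked by their summed velocity and the top
   $K = \mathrm{round}(2\,\mathrm{Hz} \times \mathrm{duration})$ runs
   donate one boundary each at their peak-velocity sample, so boundaries
   bisect large saccades rather than fixations — or as fixed **10-s
   intervals**;
3. recomputes the MAD threshold **within each segment** and labels
   intervals above it `saccade`, valid ones below `gaze`, and unmeasurable
   ones `invalid`.

Event repair follows: maximal same-label runs become events; biologically
implausible events (saccades < 20 ms, gazes < 40 ms) are absorbed into
their predecessor iteratively to a fixed point; implausibly *long* events
(duration > median + 3.5·MAD of their kind, pooled across all supplied
recordings) are relabeled `outlier_gaze`/`outlier_saccade`; each gaze gets
the modal hit object (ties to the first seen) and the centroid of its hit
points; each saccade flanked by two gazes gets an amplitude — the same
scene-space angle construction applied to the two centroids from the
saccade-onset viewpoint, *not* divided by time. Finally, events overlapping
invalid data that interpolation did not repair are rejected.

Numerical tie-breaks worth knowing:

* `classify_samples()` applies a threshold floor (`min_threshold`, default
  10⁻³ °/s). It matters only when a segment's velocity spread is exactly
  zero — synthetic noise-free fixations — where `median + k·MAD` collapses
  to ~0 and floating-point dust in ray-cast hit points would otherwise read
  as saccadic. Real data never hits it.
* Thresholding is strict (`>`), so an all-constant segment is all gaze.
* With zero MAD but unequal durations, the long-event rejection flags
  everything strictly above the median; with all-equal durations it flags
  nothing.

## Validity handling

Blinks and tracking losses arrive as invalid samples. Runs longer than
20 ms are expanded by 23 ms on each side (eyelid transients corrupt the
neighbouring samples); runs shorter than 250 ms are then filled by linear
interpolation of positions, directions and hit points (flagged
`provenance = "interpolated"`), while longer runs stay invalid. Hit-object
identity is categorical and never interpolated. Dropped frames are repaired
by `regularize_et_timestamps()`, which inserts evenly spaced stamps into
gaps exceeding 1.5 nominal periods; inserted stamps carry no data, and gaze
onsets landing on them are disqualified as EEG trial onsets.

## Two-clock alignment

Eye tracker and EEG run on different computers whose clocks drift apart
linearly (tens of milliseconds over half an hour — about an EEG epoch's
worth of misalignment if ignored). The `clock_model` is affine: the offset
is removed by subtracting the first EEG timestamp, and the endpoint method
spreads the difference between the two streams' total durations linearly
over the eye-tracking timeline, using the time axes only. A `least_squares`
method accepts shared marker pairs when endpoint stamps are unreliable.
Drift estimation is exact (to float precision) when the true drift is
linear; `map_onsets_to_eeg()` then rounds mapped onsets to the nearest EEG
sample (ties to even).

## Fixation-onset EEG

Trials are EEG segments from −200 to +500 ms around each usable gaze onset
(half-open rounded index windows, so sample counts are unambiguous). The
fERP is the plain trial mean — deliberately **no baseline correction**,
because continuous free viewing has no neutral pre-stimulus interval; slow
drift is the recording high-pass's job.

The fERSP uses complex Morlet wavelets of 3 cycles (time resolution over
frequency resolution, since the question is the *timing* of gaze-locked
activity) at 2–45 Hz in 0.5-Hz steps. Epochs for time-frequency work are
cut wider (−875 to +1175 ms, a three-cycles-of-8-Hz buffer) and cropped
after convolution. Wavelets are normalized to unit gain at their centre
frequency: a tone of amplitude $A$ yields power $A^2/4$ in its own bin,
doubling amplitude quadruples power, and — a consequence to keep in mind —
white noise shows power growing proportionally to frequency because the
analysis bandwidth does. Trial-averaged power is converted to dB against
the mean over −500 to −200 ms per frequency; that window ends before the
saccade leading into the gaze, keeping saccadic activity out of the
reference.

The **shift-correlation** analysis quantifies how sensitive each measure is
to onset-timing errors: every single trial, re-extracted at onsets shifted
by −1, 0, +1 eye-tracking samples (±11 ms at 90 Hz), is Pearson-correlated
with the unshifted trial average (ERP time course, or ERSP
frequency×time plane flattened over −200..500 ms). Data are high-passed at
5 Hz first (zero-phase windowed-sinc FIR, Hamming window, transition band
25% of the cutoff) since slow drift is not the question. ERPs show the
no-shift median strictly highest; ERSPs, being power-based and smooth at
the wavelet scale, barely change — which is why they are the more robust
choice when onsets carry frame-level uncertainty.

## The simulator

`simulate_scanpath()` + `corrupt_recording()` + `simulate_eeg()` are the
package's ground-truth oracle; every end-to-end claim in the test suite is
measured against them. The defaults describe the recording situation the
classifier is built for:

| parameter | default | rationale |
|---|---|---|
| eye-tracking rate | 90 Hz | consumer VR headset frame rate |
| fixation duration | gamma, mean 0.20 s, shape 4 | median ≈ 0.18 s, typical of free exploration |
| saccade amplitude | log-normal, median 8°, σ = 0.6 | wide-field VR viewing |
| main sequence | duration = 2.2·A° + 21 ms | amplitude–duration law; raised-cosine velocity profile (peak 2A/D) |
| head translation | random walk, sd 0.15 u/√s, bounded area | slow wandering inside a 12×12 walkable area |
| direction noise | 0 (clean) / 0.5° per sample | tracker angular noise; hit points re-ray-cast |
| blinks | 3/min, gamma mean 150 ms | marked invalid with eye data removed |
| frame drops | p = 0.002/sample | repaired by timestamp regularization |
| EEG | 512 Hz, 1/f background, Gaussian evoked template (latency 100 ms, width 60 ms, 5 µV), 10-Hz oscillation with post-onset gain | P100-like gaze-locked response; alpha modulation |
| clock drift | 53 ms per recording | a realistic two-computer drift magnitude |

During fixations the simulated eye tracks a *fixed scene point* from the
moving head — precisely the geometry the movement correction must null out.
The scene is a ring of boxes around the walkable area with nothing inside
it, so a fixated point can never be occluded mid-fixation; real scenes do
produce such parallax jumps (and real data shows hit-point changes without
saccades), which is one reason the recovery targets below are stated for
the simulator's idealized geometry, not for arbitrary scenes.

What passing the recovery tests shows — and what it does not: the simulator
emulates main-sequence kinematics, translation, sensor noise, blinks,
frame drops and clock drift, but not smooth pursuit targets, post-saccadic
oscillations, vergence/binocular depth, pupil dynamics, or EEG artifacts
(ocular ICA components, muscle noise, channel loss). Agreement numbers on
synthetic data are an upper bound on real-data performance.

### Comparing classifier output against a reference

Classifier events claim whole frames; ground truth (or hand labels with
finer timing) has sub-frame boundaries. `compare_labels()` therefore labels
each frame by overlap with priority invalid > saccade > outlier > gaze — a
frame during which a saccade was in flight is a saccade frame — and
`snap_events_to_frames()` quantizes a continuous-time reference to the
frame grid before duration statistics are compared (a 90-Hz instrument
cannot observe sub-frame durations). `label_agreement()` folds the
`outlier_*` labels back into their base kinds by default: outlier rejection
is a data-cleaning step for the EEG analysis, not a classification claim,
and ground truth has no outlier class. The 4-class confusion matrix of
`compare_labels()` keeps outliers separate, matching how one compares
against hand-labeled data (where the same long-event rejection is applied
to the reference labels first).

Problem sizes used by the automated checks: 10-minute recordings for
classification recovery, a 30-minute stream for drift recovery, 500 trials
for fERP/dB recovery, and 200 trials for the shift-correlation contrast —
large enough that every quoted margin is limited by the method, not by
sampling noise.

## A short worked example

```{r pipeline}
cfg <- sim_config(duration = 60, seed = 7, dir_noise_sd = 0.3,
                  blink_rate_per_min = 3)
sp  <- simulate_scanpath(cfg)
rec <- corrupt_recording(sp$rec, cfg) |>
  regularize_et_timestamps() |>
  preprocess_gaze()
events <- classify_gaze(rec)
glance(events)
```

```{r validation}
ref <- snap_events_to_frames(truth_event_seq(sp$truth), rec)
label_agreement(events, ref, rec)
main_sequence(events)
```

```{r eeg}
se  <- simulate_eeg(sp$truth, cfg)
mdl <- estimate_clock_drift(rec$t, se$eeg_span)
tidy(mdl)
on  <- map_onsets_to_eeg(gaze_onsets(events), mdl, cfg$eeg_rate,
                         ncol(se$eeg$data))
erp <- average_erp(extract_epochs(se$eeg, on$sample[on$in_range]))
plot_erp(erp)
```

## Known limitations

* Gazes pool fixations and smooth pursuit; no pursuit/fixation split is
  attempted (at 90 Hz with scene-space velocities the two are not reliably
  separable).
* Post-saccadic oscillations blur the saccade/gaze boundary and are not
  modeled; onset estimates carry up to one frame of systematic earliness.
* Successive fixation responses overlap within an epoch; no deconvolution
  or overlap correction is applied to fERPs/fERSPs.
* EEG artifact handling (channel rejection, ICA, re-referencing) is
  expected upstream; the package consumes a clean channels×time matrix.
* The endpoint drift model is affine; piecewise or nonlinear clock
  behaviour is out of scope (the `least_squares` method with markers is the
  escape hatch).
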