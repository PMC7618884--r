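---
title: "Quantifying turning from 3D skeleton sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying turning from 3D skeleton sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turnmetry)
```

## The measurement model

A turn is a rotation of the body about the vertical axis. Given a 3D
skeleton time series (`T` frames, 17 joints in the common motion-capture
keypoint layout), the facing direction at each frame is read off the
left-minus-right vectors of paired joints — hips, knees, shoulders —
projected onto the ground plane. The turning angle of a clip accumulates
the angle between consecutive projections of each selected pair vector,
averaged with equal weights over the selected pairs (hip + knee by
default), and summed over all frame pairs:

$$\theta \;=\; \frac{1}{|P|}\sum_{p \in P}\;\sum_{t=0}^{T-2}
  \sin^{-1}\!\left(\frac{\lVert v^p_t \times v^p_{t+1}\rVert}
                        {\lVert v^p_t\rVert\,\lVert v^p_{t+1}\rVert}\right)$$

Three derived quantities follow: the mean angular speed
$\omega = \theta / d$ for clip duration $d$; the maximum angular velocity
$w_{max} = \max_t(\theta_t)/dt$ with $dt = 1/\mathrm{fps}$, a
turning-speed biomarker; and the quantised bin, the nearest multiple of
45° (clinician raters cannot resolve finer gradations from video, so the
label set is 45°-spaced by construction).

**Assumptions.** The subject is roughly upright (the pair vectors lie in
the frontal plane and their ground-plane projections are meaningful); the
vertical axis is known (z-up internally; y-up files are rotated at load
time); and per-step rotations stay below 90°, which at ordinary video
frame rates they do by two orders of magnitude.

**Properties.** All outputs are invariant to translation, uniform scaling
and global rotation about the vertical axis, since only directions of
differences of coordinates enter. Coordinates are therefore unit-agnostic
(millimetres, metres, normalised — anything uniform).

## Numerical and design choices

*Unsigned versus signed increments.* The arcsin-of-cross-norm increment is
unsigned and aliases rotations beyond 90° in a single step
($\sin^{-1}(\sin 100^\circ) = 80^\circ$); it is the package default
(`mode = "faithful"`) because it defines the headline angle measure. A
signed `atan2`-based mode is provided for direction-aware work (turn
detection uses it internally): on a noisy but net-stationary signal the
unsigned sum drifts upward (noise rectification) while the signed sum
cancels. This is also why unsigned $\theta$ on a static noisy skeleton
grows with noise amplitude — a property the test suite checks rather than
hides.

*Dimensional convention for $w_{max}$.* A per-frame increment $\theta_t$
(degrees per frame) is converted to degrees per second by dividing by the
frame interval $dt$, i.e. multiplying by fps. `max_angular_velocity()`
implements exactly this, keeping $w_{max}$ in the same °/s units as
$\omega$ and guaranteeing $w_{max} \ge \omega$ for every clip.

*Degenerate frames.* A pair vector is unusable when a joint is masked
(occlusion, missing detection) or when its norm falls below
$10^{-9}\times$ the coordinate scale. Such frames are carried forward from
the last valid frame — their increments contribute zero — with a warning
and a per-clip `skipped_frames` count. Hard failure is reserved for the
pathological case of a pair with *no* valid frame. Free-living recordings
make some occlusion unavoidable, so a usable default matters more than
strictness.

*Duration.* When no annotation supplies start/end times, $d = T/\mathrm{fps}$
(the clip is assumed trimmed to the turn). Explicit `duration_s` overrides.

*Quantisation ties.* 112.5° is equidistant between 90° and 135°; ties
round half up (to the larger bin), a deterministic documented rule.
Sub-threshold angles (below the smallest bin minus half a bin width) are
clamped to the smallest bin by default — evaluation against label sets
whose smallest label is 90° should not silently drop estimates — with
`clamp = FALSE` available to flag them instead.

## Turn detection from continuous streams

Annotated datasets define a turning episode as running from the initiation
of pelvis rotation to the completion of the movement. `detect_turns()`
operationalises this with hysteresis thresholding of the signed hip-vector
angular velocity: a candidate opens when $|\dot\psi|$ reaches
`omega_start` (25 °/s default), continues while it stays above
`omega_stop` (10 °/s), tolerating up to `max_gap_frames` (fps/4) below,
and its boundaries are then refined outward to the surrounding
angular-velocity floor (`omega_floor`, 1 °/s) so that slow initiation and
termination ramps — prominent in smooth, bell-shaped velocity profiles —
are not clipped off the accumulated angle. Segments whose net rotation
falls below `threshold_deg` (45°, one bin width: the minimum rotation that
counts as a turn) are discarded. Detection is hip-only, because the pelvis
defines the episode; estimation can still use any joint set on the
extracted clip. The hysteresis parameters are tunables of this package's
own operationalisation, not quantities with independent clinical
authority; the 45° threshold is the one value carried over from the
labelling convention.

## Evaluation metrics

Accuracy is the percentage of quantised predictions landing in the
annotated bin. MAE compares the *continuous* prediction to the *discrete*
label, so up to 22.5° of label quantisation error is part of the metric by
design — a deliberate caveat, not a bug. Weighted precision (WPrec)
averages per-bin precision with weights proportional to each bin's
true-label count; a bin with true labels that is never predicted
contributes precision 0 with its full weight by default
(`zero_support = "zero"`, penalising missed bins), with the alternative
convention — renormalising over predicted bins — available as
`zero_support = "drop"`. Both conventions are unit-tested; with two
equally prevalent bins and all predictions in one of them they yield 25%
and 50% respectively, which is the cleanest way to see the difference.
Cohen's kappa is provided for annotation quality control between raters,
with the constant-identical-raters corner defined as 1.

Grouped reports print one row per group plus two distinct summary rows:
`Avg.`, the unweighted mean of per-group metrics (the convention of
grouped results tables, where small groups count as much as large ones),
and `Overall`, the pooled evaluation — they differ whenever group sizes
differ, and conflating them misreads such tables.

## Cohort comparison

Turns from one subject are correlated, so the group analysis first reduces
each subject to one mean value per measure (`per_subject_means()`), then
applies a two-tailed independent-samples t-test across subjects. The
default is pooled-variance Student's t (df $= n_a + n_b - 2$) with Welch
available by flag; published reports rarely state which variant was used,
so both are exposed and neither is asserted as canonical. Cohen's d uses
the pooled SD. `compare_groups_summary()` recomputes the full comparison
(t, p, 95% CI, d) from printed group means, SDs and sizes, so published
tables can be checked without raw data; note that t-statistics recomputed
from rounded summaries can differ in the second decimal from values
computed on unrounded data, while the mean difference and d are exact in
the inputs. The bundled `reference_cohort_summary()` (12 PD vs 12 control,
free-living home monitoring) reproduces a mean turning-angle difference of
−11.10° (d = −0.74) and a max-angular-velocity difference of −32.33°/s
(d = −0.97).

## What the synthetic generator does and does not emulate

`simulate_turn()` builds an articulated 17-joint body: hips, knees and
ankles rotating with a parameterised pelvis yaw profile (constant,
trapezoidal or sigmoid rate), sinusoidal knee/ankle swing emulating gait
oscillation, a shoulder girdle that can lag the pelvis by a configurable
delay (zero lag = rigid en-bloc torso), i.i.d. Gaussian coordinate noise
scaled to hip width, and random per-joint occlusion masking. Body segment
lengths (hip width 0.3, shoulder width 0.4, arbitrary units) are fixture
conventions — angles are scale-invariant. `simulate_stream()` concatenates
idle standing and turning episodes with a continuous yaw, recording every
injected event; `simulate_cohort()` draws per-subject mean angle and
$w_{max}$ from group-level normal distributions (defaults matching the
reference cohort summaries) and individual turns around them.

What it deliberately does not model: temporally correlated pose-estimator
error (real 2D→3D lifting errors are strongly autocorrelated and
depth-ambiguity driven), translation of the body through the room,
biomechanically realistic gait, and freezing episodes. Passing tests on
synthetic data therefore validate the *geometry and statistics* of the
pipeline — that the estimator recovers known rotations, that the detector
finds known events, that the group test is calibrated — not the accuracy
of any upstream pose estimator on real video.

## Validation problem sizes

The test suite exercises: exact recovery (error < 10⁻⁶ degrees) on
noise-free turns of 45°–315° across all three profiles and frame rates of
25/30/50 fps; invariance of $\theta$, $\omega$, $w_{max}$ under
translation, scaling and vertical-axis rotation; brute-force oracle
equivalence of weighted precision and kappa on 1,000 random
prediction/label vectors; detector recall 1 with segment-angle error
< 2° on a noise-free stream of six injected turns (55°–315°); quantisation
conformance on an exhaustive 0.1° grid of [0°, 382.5°]; and calibration of
the cohort test over 500 simulated 12-vs-12 cohorts (empirical type-I
error at nominal 0.05, unbiased mean-difference recovery). These sizes
were chosen as the smallest that make each property statistically
unambiguous.

## Known limitations

The faithful angle is unsigned: clips containing genuine back-and-forth
rotation accumulate total rotation, not net heading change (use signed
mode for net change). Quantisation-label MAE saturates near 22.5° for an
unbiased estimator by construction. The detector's hysteresis defaults
were chosen for indoor walking speeds and may need retuning for very slow
parkinsonian turns near 10 °/s. And the package starts where pose
estimation ends: garbage skeletons in, garbage angles out — the validity
mask and skipped-frame accounting make that visible but cannot repair it.
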