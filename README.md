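# turnmetry

Quantifying **turning movements** from 3D human pose time series.

Turning is one of the most informative components of gait for monitoring
Parkinson's disease: people with PD turn more slowly, with smaller angles and
with reduced axial dissociation ("en bloc" turning), and these changes appear
early and progress. Video-based 3D pose estimation makes it possible to
measure turning passively and continuously at home — but it leaves open the
question this package answers: *given a skeleton time series, how large and
how fast was the turn?*

`turnmetry` takes the output of any 3D pose estimator (a `T x 17 x 3` joint
coordinate series in the common 17-keypoint convention) and computes turning
angle, angular speed and maximum angular velocity; quantises angles into the
45° bins clinicians use when rating turns by eye; segments turning episodes
out of continuous recordings; scores predictions against annotation tables
(accuracy, MAE, weighted precision, Cohen's kappa); and runs per-subject
PD-versus-control group comparisons. A synthetic articulated-motion
generator with exact ground truth backs the entire test suite. Pose
estimation itself (video → skeleton) is a deliberate plugin boundary: any
system that writes the documented skeleton CSV plugs in upstream.

## The method

At frame *t* the left-minus-right hip and knee vectors, projected onto the
ground (XY) plane, indicate the facing direction:

    H_t = (x, y)_left_hip  - (x, y)_right_hip
    K_t = (x, y)_left_knee - (x, y)_right_knee

The per-frame turning increment is the angle between consecutive vectors,
and the clip's turning angle sums the hip/knee average:

    theta = 1/2 * sum_{t=0}^{T-2} [ asin(|H_t x H_{t+1}| / (|H_t||H_{t+1}|))
                                  + asin(|K_t x K_{t+1}| / (|K_t||K_{t+1}|)) ]

Angular speed is `omega = theta / d` for clip duration `d`, and the maximum
angular velocity converts the largest single increment to degrees per
second: `w_max = max_t(theta_t) / dt`, with `dt = 1/fps`. The continuous
angle is finally quantised to the nearest 45° bin (e.g. anything in
90° ± 22.5° is labelled 90°). Any subset of the hip, knee and shoulder
joint pairs can be selected (equal-weight average), which supports
joint-set ablations; hip+knee is the default.

## Worked example

```r
library(turnmetry)

# a synthetic 135-degree turn over 2 s at 30 fps, with exact ground truth
sim <- simulate_turn(synthetic_turn_spec(135, duration_s = 2, fps = 30, seed = 9))
est <- cumulative_angle(sim$seq, joint_sets = c("hip", "knee"))
est
#> <turn_estimate> theta = 135.00 deg over 2.00 s (faithful mode, joints: hip+knee)
#>   omega = 67.50 deg/s, w_max = 68.64 deg/s, 60 frames

as.numeric(quantize_to_bin(est$theta_deg))
#> [1] 135
```

The estimator recovers the generated 135° exactly on noise-free input; the
peak velocity (68.6°/s) slightly exceeds the mean speed (67.5°/s) because
the generated yaw profile is sampled on a finite frame grid. Group
comparison from per-subject summary statistics (a bundled 12-vs-12
PD/control free-living cohort):

```r
s <- reference_cohort_summary()
th <- s[s$measure == "theta", ]
compare_groups_summary(th$mean[1], th$sd[1], th$n[1],
                       th$mean[2], th$sd[2], th$n[2], measure = "theta")
#> <group_comparison> theta (pooled t)
#>   A: 92.65 +/- 13.21 (n=12)   B: 103.75 +/- 16.75 (n=12)
#>   mean diff = -11.10 (95% CI -23.87 to 1.67), t = -1.80 (df 22.0), p = 0.0852, d = -0.74
```

PD subjects turn through smaller angles on average (−11.1°, a moderate
effect size of d = −0.74 that does not reach significance at n = 12+12) and
substantially more slowly (mean max angular velocity difference −32.3°/s,
d = −0.97, p < 0.05 — run the same call with `measure = "wmax"`).

A thin command-line wrapper ships in `inst/cli/turnmetry.R` with
`estimate`, `detect`, `summarize`, `evaluate`, `stats` and `simulate`
subcommands over these functions.

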