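---
title: "Flow-defined walkers: stimulus model, designs, and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flow-defined walkers: stimulus model, designs, and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

flowwalker builds random-dot self-motion displays in which a point-light
walker is carried entirely by motion: each frame is a spatially uniform dot
field ("white noise"), and the walker's body exists only as a region whose
optic flow differs from the surrounding self-motion flow. This vignette
documents the underlying model, the tunable parameters and their defaults,
the numerical choices, and the limits of what the synthetic components can
show.

## Scene geometry and background flow

The scene is a ground plane with a dot sky at infinite distance, viewed by
an eye (simulated camera) `eye_height = 1.8` m above the plane. The display
is a flat screen `viewing_distance = 1` m ahead (2.24 m x 1.85 m, 800 x 600
pixels, 60 Hz). Screen coordinates are metres from the screen centre, x
right and y up; pixels are a derived view used only by the rasterizer.
Projection is a standard pinhole: a point \((X, Y, Z)\) in the observer
frame (z forward) maps to \((x, y) = d\,(X, Y)/Z\) with \(d\) the viewing
distance. Gaze is fixed straight ahead for every heading; only the
translation direction varies, so the focus of expansion (FOE) of the flow
field sits at \(x = d \tan\theta\) for heading \(\theta\). Headings of
\(\pm5^\circ\) and \(\pm10^\circ\) are read as angles of the translation
vector; for a fixed camera this coincides with the FOE eccentricity
convention, so the distinction has no observable consequence.

Ground-dot motion is computed as an exact finite step, not an integrated
velocity field: each dot is back-projected onto the plane, the observer is
advanced by `speed * dt` along its heading (1.5 m/s by default), and the
point is re-projected. Over a 102-frame trial this avoids any discretization
drift; the displacement agrees with the analytic image velocity
\(\dot{x} = (x T_z - d\,T_x)/Z\) to first order in `dt` (verified by a
Richardson-extrapolation test). A useful exact property follows: every
background displacement lies on the line through the FOE, because the dot,
its translated copy, and the translation vector are coplanar with the
nodal point. Sky dots are directions without depth and never move.

## The gait cycle

The walker is an 18-marker figure: head, left/right shoulders, elbows,
wrists, hands, hips, knees, ankles and foot tips (17 enumerated parts), plus
a pelvis/body-centre marker as the 18th. Any 18-joint trajectory table can
be loaded from a delimited text file (`load_gait()`, one row per frame, 54
`joint_axis` columns, a `# period_s:` header); absent such a recording the
built-in synthesizer (`synthesize_gait()`) produces a sagittal-plane
sinusoidal gait: legs half a cycle apart, arms in counter-phase with the
ipsilateral leg, a double-frequency vertical trunk bob, and a small foot
lift during swing. Amplitudes and marker heights are `gait_params()`
arguments (metres); the defaults draw a ~1.7-m walker with 0.30-m leg and
0.22-m arm excursions, ordinary values for a 1.2 m/s walk. The synthesizer
is deterministic and drift-free by construction: joint offsets are
body-centred, and all translation comes from the walker path. The cycle
period defaults to exactly 68/60 s, i.e. 1.1333 s or 68 frames at 60 Hz, so
the 1.7-s trial spans exactly 1.5 cycles.

The synthesizer emulates the kinematic structure that the tasks rely on
(counter-phase limbs, cyclic posture change, distinct postures across the
cycle); it does not reproduce the fine dynamics of a motion-capture
recording (asymmetries, jerk, individual style). Results that depend only
on disk geometry and path kinematics are unaffected by this substitution;
anything that depends on naturalistic articulation detail is outside what
the synthetic gait can show.

## Walker paths and the articulation factors

Two paths are used. The *equidistant* walker is specified directly in the
observer frame: depth pinned at 1.5 m (the walker is shifted in depth with
the observer), lateral position running from 1.02 m on one side of the
display centre to 1.02 m on the other at 1.2 m/s, facing \(\pm90^\circ\).
The *approaching* walker starts 5 m ahead on the midline in the world and
walks a 45-degree tilted path toward the observer's track; its observer-
frame position subtracts the observer's own displacement.

Facing, articulation and translation are deliberately decoupled. The
schedule's direction factor is the facing side. Backward articulation plays
the cycle in reverse frame order (a backward pose at phase \(p\) is the
forward pose at \(1-p\)), and implies translation opposite the facing, as
for a real backward walker. The moonwalk flag then reverses translation
once more while leaving articulation and facing untouched. Frame `i` of a
stimulus shows the state after `i` frame intervals, so the final frame
falls at exactly 1.7 s = 1.5 cycles, where the forward and backward poses
coincide — the walker's final posture is identical across all four
articulation/translation cases, removing a potential end-posture cue.

Body membership is evaluated in world units on the walker's fronto-parallel
plane: a screen position is inside the body iff the ray through it meets
that plane within 0.02 m of a joint centre. Because the radius is specified
in metres, the disks shrink correctly with distance for the approaching
walker, and the membership boundary is exact rather than a rasterized
approximation.

## The dot engine

Dots are placed uniformly at 1.4694 dots/deg². The total count is the
density times the angular area of the screen; for a flat 2.24 x 1.85 m
screen at 1 m the angular measure is convention-dependent, so the package
offers the product of the horizontal and vertical angular extents (default,
12,126 dots) or the exact solid angle of the rectangle (10,249 dots). The
stated density and the 0.02-m disk radius imply only a few dots per joint
disk at 1.5 m; the package follows the stated radius and density.

Each frame, every dot is displaced by the background flow or, inside the
silhouette, by the condition rule:

* **congruent-with-walker** — each joint disk carries its own dot
  population, locked to the disk centre in world metres, seeded at the
  background density; background dots covered by the silhouette are hidden,
  not deleted, and resume when uncovered. This keeps the display density
  constant without doubling dots; occlusion semantics are a package choice.
* **incongruent-with-walker** — dots inside the body move with the walker's
  displayed (observer-frame) velocity with the lateral component negated:
  pure leftward motion for a rightward equidistant walker, mirrored lateral
  with the same approach for the approaching walker. Defining the mirror on
  the observer-frame velocity keeps the equidistant inside-flow the exact
  negative of the walker translation for every heading.
* **congruent-with-flow** — each inside dot is treated as a static scene
  point at the walker's current depth and at the dot's height above ground,
  and displaced by one finite step of the observer translation. Its
  direction therefore matches the background flow at that pixel exactly
  (both are epipolar displacements through the same FOE) while its speed
  exceeds the more distant background — including above the horizon, where
  sky dots are otherwise static. For the equidistant walker the assumed
  depth is re-evaluated each frame at the constant 1.5-m distance; a truly
  static object could not stay equidistant, so the rule is applied to the
  momentary depth.

Dots have a limited lifetime: each frame every dot is replaced with
probability 0.15 at a fresh uniform position with fresh attribution (a
replacement landing inside the silhouette immediately follows the inside
rule). Dots leaving the screen respawn uniformly. Dots crossing the
silhouette outline are captured at the next frame boundary — attribution
follows position, so from that frame on their motion matches the intended
flow at their location; 60-Hz frames are the time quantum, and no sub-frame
event timing is attempted. One master seed per stimulus feeds separate
substreams for initialization, lifetime and respawn, making every stage
reproducible and independently testable.

Frames are emitted as data frames of dot positions (with optional
diagnostic labels that are never rendered) and can be rasterized to 800x600
binary PNGs, one nearest pixel per dot.

## Experiment designs

The heading experiment is 280 trials: 4 blocks, each presenting the 7
walker conditions (no-walker plus both paths x three flow conditions) in
random order, with the condition's 10 trials (5 headings x 2 sides)
shuffled inside it. The facing and articulation experiments are 192 trials:
4 blocks x 6 walker conditions x 8 trials (2 articulations x 2 translations
x 2 sides). Successive blocks are constrained not to repeat the previous
block's last condition first, so every maximal run of one walker condition
has exactly the sub-block length (10 or 8). The no-walker side factor is a
formal duplicate; its trials still carry independent stimulus seeds.
Practice trials are excluded from schedules, and counterbalancing of
experiment order across participants is metadata only.

## Response analysis

* The no-walker regression pools all participants' trials (ordinary least
  squares of perceived on simulated heading, normal-theory 95% CIs). Bias
  summaries instead aggregate within participant first, then across
  participants with t-based CIs; both conventions are intentional and
  documented because they answer different questions.
* Mirror collapse signs each walker trial's error by the walker's motion
  direction, so positive bias means "toward walker motion"; it is
  idempotent, and on a left/right-balanced design the collapsed mean equals
  half the difference of the raw side means.
* The one-way repeated-measures ANOVA is computed from the standard sums of
  squares; the Greenhouse-Geisser epsilon comes from the double-centred
  condition covariance and is clamped to \([1/(k-1), 1]\). A literally null
  effect (identical condition columns) yields the 0/0 form and is reported
  as F = 0. The implementation is cross-checked against the multivariate-
  model route in `car` to 1e-8.
* Percent-correct intervals use the normal (Wald) approximation
  \(1.96\sqrt{\hat p(1-\hat p)/n}\) with \(n = 384\) (12 participants x 32
  trials per condition), and percentages are rounded half-up to one
  decimal, matching how such results are reported in text. No correction
  beyond planned comparisons is applied.

## The synthetic pooled-flow observer

The machine responder for the heading task implements the pooled
rigid-scene account: every motion vector contributes to heading estimation,
with no segmentation of independently moving regions (it never reads the
diagnostic labels). Candidate FOEs lie on the horizontal axis, matching the
horizontal adjustment task, on a grid of 0.1° steps over ±12° with
parabolic refinement around the minimum (resolution well below 0.01°). For
a candidate \(f\), the translational component of each displacement is
radial from \(f\) with a free per-dot magnitude (the unknown depth), so
only the tangential component is unexplained; the residual is the magnitude-weighted
squared sine of the angle between displacement and radial direction.

Crucially, the estimator also fits a free yaw-rotation component per
candidate, in closed form (the rotation field enters the tangential
residual linearly, so the optimal rotation is a one-dimensional least-
squares solution). This matters for the science: a purely lateral patch of
motion is tangentially symmetric about any FOE on its line of motion, so a
translation-only fit has no consistent preference and the equidistant bias
direction would be seed noise. With the rotation degree of freedom, uniform
lateral motion inside the walker is partially absorbed as spurious
rotation, and compensating for that rotation shifts the fitted heading
toward the walker's motion — the classic rotation/translation-ambiguity
mechanism for the bias produced by laterally moving objects. With
`rotation = "none"` the estimator reduces to the translation-only residual.

On rigid no-walker stimuli the estimator is consistent (errors well below
0.5°, in practice ~1e-4°, because background displacements are exactly
epipolar). On walker stimuli it reproduces the qualitative signature:
positive bias (toward walker motion) for the equidistant
congruent-with-walker condition, negative of comparable magnitude for
incongruent-with-walker, essentially zero for congruent-with-flow (those
vectors are exactly radial from the true FOE, so they add no tangential
misfit), and positive for the approaching incongruent walker. The
magnitudes are not calibrated to the ~1.3° human biases and are not meant
to be; only the sign pattern is a claim. Dots replaced by the lifetime
process contribute no displacement on their rebirth frame, mirroring how
limited lifetime caps motion correspondences. When more vectors are
available than `n_sample` (default 30,000) a deterministic subsample is
used.

The facing/articulation responders are purely stochastic stand-ins
(programmed per-condition accuracies); they exercise the schedule and
analysis pipelines and make no claim about biological-motion perception.

## Numerical choices and degenerate inputs

Projection round trips are exact to 1e-9 m on the visible ground region.
Points at or behind the camera are non-projectable errors; screen positions
at or above the horizon have no ground intersection and are sky by
attribution. The equidistant depth is pinned to 1e-12 m. Membership ties
between overlapping disks go to the nearest joint (first index on exact
ties). Zero-variance bias sets are flagged as degenerate rather than
silently producing t statistics. Gait files must contain all 18 joints with
finite values; mean forward/lateral drift is removed on load and reported.

The test-suite problem sizes are deliberate: full-density (12,126-dot)
stimuli are used where the claim concerns the engine's statistics (density
stationarity, per-frame uniformity, capture semantics, observer biases,
with 10-20 seeds per property), and sparse fields are used where only
mechanics are at stake. The observer's bias signature is evaluated at 10
seeds per condition; the reported human effect sizes are checked by
round-tripping the printed numbers through the analysis code, since they
depend on human participants and cannot be regenerated by simulation.

## Known limitations

* No eye or head rotation, curvilinear self-motion, or stereo; the camera
  axis is fixed.
* The synthetic gait is a kinematic sketch, not a validated human gait.
* The pooled-flow observer searches heading on the horizontal axis only and
  uses engine correspondences rather than solving optical flow from pixel
  data; its bias magnitudes are mechanism demonstrations, not fits to human
  data.
* Anti-aliased rendering, luminance calibration and real-time playback are
  out of scope; frames are precomputed.
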