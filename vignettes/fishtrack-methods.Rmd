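---
title: "Tracking and closed-loop methods in fishtrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking and closed-loop methods in fishtrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishtrack)
```

# Scope

`fishtrack` implements the computational core of a behavioral rig for larval
zebrafish: extracting tail, eye and whole-body kinematics from grayscale
video, turning those kinematics into online behavior-state estimates, and
closing the loop between behavior and visual stimulation under a timed,
fully logged protocol. Everything that touches hardware — cameras,
projectors, triggers, GUIs — is out of scope; the package operates on frame
sequences and is validated against its own synthetic-fish renderer, for
which the ground truth is exact by construction.

# Conventions

All modules share one coordinate convention: pixel positions are `(x, y)`
with `x` the 0-based column and `y` the 0-based row, origin at the top-left
corner. A direction angle `theta` corresponds to the displacement
`(cos(theta), sin(theta))`; angles are radians. Internal processing assumes
the fish is *bright on dark* after preprocessing — the `invert` flag of
`preproc_spec()` adapts transmitted-light sources where the fish is dark on
bright. Having one convention downstream keeps every tracker free of
per-source branches.

# Preprocessing and background model

`preprocess()` applies, in order: inversion (`range_max - v`), integer
block downsampling, Gaussian blur, and clip-to-zero below a threshold.
Downsampling uses *block averaging* rather than decimation so photometry is
preserved (a thin tail must not vanish at 2x). Whether clipping precedes or
follows the blur is genuinely ambiguous in practice; blur-then-clip is the
default and `clip_before_blur` exposes the alternative.

The background for freely-swimming tracking (`background_model()`) is the
arithmetic mean of the first `n_init_frames`, then an exponential moving
average `mean <- (1 - a) mean + a frame` with `a = dt / time_constant`
computed from frame timestamps and clamped to `[0, 1]`. The time-constant
semantics are the minimal ones consistent with "slowly updated": timestamps
(not frame counts) drive the update so irregular frame intervals behave
sensibly, and the clamp keeps the recursion stable for pathological gaps.
`foreground()` is `max(mean - frame, 0)`: only pixels darker than the
background are active, which is exactly a dark fish on a bright arena.

# Tail skeletonization

Tracing starts from a user-given tail-base point and resting direction and
walks `n_segments` steps of length `tail_length / n_segments`. Two segment
finders are provided:

* **com** — sample a square window (side `window_size`, default one
  segment length) centered one segment-length ahead along the previous
  direction; the next direction points from the previous endpoint to the
  window's intensity-weighted center of mass.
* **arc** — sample intensities along an arc of radius one segment length
  spanning `arc_halfwidth` (default pi/4) around the previous direction and
  take the arg-max.

Numerical choices that matter:

* all intensities are read with *bilinear interpolation*, so angular
  resolution is not limited by pixel quantization;
* the COM window grid is symmetric about its center — an asymmetric grid
  biases the center of mass by a fraction of a pixel, which at short
  segment lengths translates into degrees of heading error;
* the arc grid always contains the zero-deviation angle, and the arg-max is
  refined by a parabolic fit through its two neighbors (skipped on exact
  plateaus, where the tie-break "smallest angular deviation wins" applies);
* the bend between consecutive segments is clamped to `max_bend` (default
  pi/2) so a trace can never fold back onto the body;
* a window or arc that is fully outside the frame, or contains no
  intensity, carries the previous direction forward and flags the trace
  invalid — tracing never raises mid-sequence, because one bad frame must
  not abort an experiment.

On rendered ground truth the COM method is both more accurate and more
robust to resolution loss than the arc method (the acceptance suite checks
the mean absolute segment-angle error of both at full and half resolution),
which is why it is the default.

`resample_segments()` interpolates the absolute angle profile linearly over
normalized arc length, preserving the end angles exactly; consequently
`total_curvature()` — the difference between last and first segment angle,
equal to the telescoping sum of successive differences — is invariant under
resampling to machine precision.

# Eye tracking

Within a user ROI the image is binarized *strictly below* a threshold (eyes
are much darker than the background), 8-connected components are labeled,
and the two largest with at least `min_area` pixels (default 20) are kept.
An ellipse is fitted to each component from second-order central moments —
robust for filled blobs, unlike boundary least-squares — with the 1/12 px^2
variance of a unit pixel added to each coordinate before converting
eigenvalues to semi-axes (`2 sqrt(lambda)`, exact for a filled ellipse).
Orientation is an axial quantity and is folded to `[0, pi)`; consecutive
frames are unwrapped against the previous state so a smooth rotation never
jumps by pi.

Degeneracy is decided on the *raw* moments: a collinear set gets minor axis
0 and the line's angle; a set whose moment anisotropy
`(l1 - l2) / (l1 + l2)` is below 0.02 (a disc) carries no orientation and
the previous frame's angle is held, flagged. Left/right assignment projects
the component centroids on a configurable axis (default the image x-axis,
matching a head-restrained fish pointing up); the ordering rule is a
package choice — nothing in the underlying method defines it.

# Freely-swimming tracking

Per frame: update the background, compute the foreground, threshold it and
keep connected components within `area_range`. Within each candidate blob
the two eyes and the swim bladder are found as the three darkest local
minima of the raw image below `eye_bladder_threshold`, separated by
non-maximum suppression of one eye diameter (`nms_radius`, default 3 px) —
plain thresholding plus labeling is not used because touching eye discs
merge under 8-connectivity. The head center is the mean of the three
centroids. If fewer than three minima exist the blob centroid and principal
axis are used, flagged low-confidence (the principal axis is ambiguous by
pi, so the tail direction below resolves it whenever possible).

The initial tail direction is the arg-max of the foreground on a circle of
half `tail_radius` around the head; the heading is that angle plus pi,
refined as pi plus the angle of the first traced tail segment. Identity
maintenance is greedy minimum-cost matching on
`distance + heading_weight * |heading difference|` with matches beyond
`max_jump` rejected; greedy (not optimal) assignment is adequate for the
at-most-three-fish regime this pipeline targets. Unmatched detections get
fresh ids; unmatched fish are retired with a final `visible = FALSE` row.

Kinematics are smoothed by a causal Kalman filter with a constant-velocity
state `(x, y, heading, vx, vy, heading rate)` — the method names the filter
but not the model, and constant velocity is the weakest model that still
exploits temporal continuity. The process noise is discrete
white-acceleration with intensity `q = 2e4` px^2/s^3 by default, chosen so
that bout-scale accelerations (~10^3 px/s^2 at 300 Hz) are tracked without
lag dominating the error budget while measurement jitter is still strongly
attenuated; `r_pos = 1` px^2 and `r_ang = 0.05` rad^2 match the observed
detection noise on rendered scenes. Heading measurements are unwrapped
against the prediction before the update.

`bout_kinematics()` segments a trajectory where speed crosses a hysteresis
pair (`speed_on`, `speed_off`) — no universal threshold exists, so both are
required configuration — and rigidly re-aligns each bout to origin position
and zero initial heading, making re-alignment of an aligned bout exactly
the identity.

# Estimators and the closed loop

**Vigor** is the trailing-window *population* standard deviation of the
total tail curvature, window 50 ms (15 samples at the 300 Hz acquisition
rate the tracker targets), emitting 0 until the window fills. Population
(not sample) std is fixed so the implementation is bit-comparable with a
brute-force oracle. **Fish forward velocity** is `-vigor_scale * vigor`
when vigor is at or above `swim_threshold`, else 0 — negative meaning
forward, the convention under which "the fish is swimming" reads
`fish_vel < -15` for a 15 mm/s threshold. Both `vigor_scale` and
`swim_threshold` depend on preparation and magnification and therefore have
no silent defaults. The closed-loop grating law is
`v_grating = v_base + gain * v_fish`: since `v_fish <= 0` while swimming,
swimming drives the grating backward relative to its 10 mm/s open-loop
speed; gain 0 is exactly open loop, and the replication protocol uses gains
0.5 / 1.0 / 1.5.

`interbout_intervals()` detects bouts as maximal runs with vigor at or
above threshold, after merging gaps shorter than `min_gap`. Bouts follow a
half-open sample convention — a bout ends one sample period after its last
supra-threshold sample — so gaps between rectangular vigor pulses are
recovered exactly; with real (smeared) vigor traces the trailing window
shifts both edges by about half a window, which cancels in the interval.

**Calibration** maps camera pixels to display coordinates with an affine
transform estimated from exactly three projected points — three
non-collinear pairs determine an affine map uniquely, a projective map
would need four. Points are detected as the three brightest strict local
maxima after a small blur, refined to sub-pixel precision by a local center
of mass, and sorted lexicographically for stable correspondence. Collinear
configurations (triangle area below a tolerance) are rejected.

**Phototaxis geometry**: the light/dark boundary is the line through the
fish position along its heading; a point is on the bright side iff the sign
of the 2-D cross product of heading and offset matches the protocol-chosen
side (positive = left).

# Protocol execution and logging

A protocol is an ordered list of stimuli with durations; stimulus k starts
at the exact cumulative onset of the durations before it, fires `start`
once, and `update` on every tick while active. On a transition tick only
the *incoming* stimulus updates — the outgoing one had its final update a
tick earlier; one of the two had to be chosen and incoming-only keeps
"duration" meaning "number of update ticks" exactly. The simulated clock
counts integer ticks over an exact ticks-per-second rate (`t = k / fps`),
so whole-second transitions are exact in floating point and two runs of the
same protocol are byte-identical. Real-time execution targets the tens-of-
milliseconds granularity of an interpreted runtime; milli- or microsecond
precision is explicitly not promised, and all tests run on the simulated
clock for hardware-independent determinism.

`combine_stimuli()` fans start/update out to all members, logging each
plain member's dynamic state under name-prefixed keys; nested combiners
pass their members' already-prefixed state through, so combination is
associative at the level of logs, and a singleton combine returns the
stimulus itself. `conditional_stimulus()` evaluates a pure predicate on the
latest estimator sample each tick, runs the active branch and logs the
branch taken; it refuses to start without an estimator stream.

Every parameter read during a run goes through an access-recording
parameter tree, and the saved metadata lists both all parameters and the
accessed subset — the audit test asserts the latter is contained in the
former, so nothing that influenced a run can be missing from the record.
Logs are saved as CSV (15 significant digits; round trip within 1e-12) or
HDF5 (lossless); Feather was dropped deliberately — two formats cover the
test value and the third only adds a dependency. Hardware triggering is
reduced to a start-barrier interface with a no-op implementation.

# The synthetic generator: what it emulates, what it does not

`synthfish` renders anti-aliased, sub-pixel-positioned fixtures so that
recovery tolerances measure algorithm error, not raster error:

* tails as bright polylines of given width with per-segment ground-truth
  angles (constrained to the tracker's `max_bend`, since a fixture that the
  contract excludes would test nothing);
* eyes as dark filled ellipses with exact centers, axes and orientations;
* swim scenes as dark fish — head disc, two darker eye discs about a third
  of a head width apart, a darker swim-bladder disc behind, thin tail — on
  a bright arena, with bout-and-glide kinematics: stationary glides,
  raised-cosine speed envelopes, per-bout turn draws spread smoothly over
  the bout. Defaults: 300 Hz sampling, 200 ms bouts, 0.5 s inter-bout
  glides, 120 px/s peak speed, ~0.5 rad turn SD — the regime the trackers
  assume. Tail-beat frequencies are physiologic (<= 50 Hz) and the
  generator enforces the Nyquist guard `fs > 2 f_beat`. For the closed-loop
  overlap property, longer 600 ms swims are generated, matching the
  sustained bouts evoked by moving gratings.

All generators are seed-deterministic and restore the caller's RNG state.
What the renderer does *not* emulate: refraction and illumination
gradients, body deformation during turns (the body template is rigid; only
the rendered tail bends), occlusions between fish (overlap is rendered as
drawn and such frames are excluded from identity tests), and motion blur.
A green test therefore establishes correctness of the algorithms under the
stated image model, not robustness to every optical artifact of a real rig.

# Known limitations

* Crossing or overlapping fish are not disambiguated; identities are only
  guaranteed while fish are separated.
* The vigor-to-velocity map is proportional; if the underlying relation is
  nonlinear the gain interpretation shifts accordingly.
* Frame sources are directories of ASCII PGM (or PNG) frames and in-memory
  sequences; video containers and TIFF stacks require external conversion.
* Real-clock protocol execution inherits interpreter-level jitter.
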