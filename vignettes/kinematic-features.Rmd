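---
title: "Quantifying emotional expressivity in full-body movement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying emotional expressivity in full-body movement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

When a dancer repeats the same short choreography several times, each time
with a different emotional intention — anger, contentment, fear, joy,
neutrality, sadness — the movements themselves are nominally identical, and
whatever distinguishes the takes lives in *how* they are performed: tempo,
expansion, smoothness, posture, use of space. `kinemotion` computes a fixed
inventory of twelve kinematic features, summarised into thirty-two
per-sequence statistics, from three data modalities of such a recording:

* a 23-keypoint motion-capture time series (positions in meters,
  orientations as Euler angles, the body's center of mass, foot contacts;
  world frame x→north, y→west, z→up; nominal 240 Hz),
* camera-relative landmark coordinates (screen ratios `x, y` in `[0, 1]`
  plus metric depth along the optical axis; nominal 60 Hz),
* silhouette videos as Boolean foreground masks (nominal 1080×1920,
  25 fps).

Because the hardware that produces such recordings is proprietary and its
pilot datasets are large, the package also contains a deterministic
synthetic generator of emotion-modulated choreography, which is the
substrate for all of its tests.

## Features and statistics

For a sequence of `T` frames every feature is a nonnegative scalar per
frame (a norm, distance, angle, ratio, area or volume). Three aggregations
summarise a feature over time: the **average**, the **median absolute
deviation** (MAD, `median(|median(K) − K(t)|)`, with *no* 1.4826
consistency constant — the definition is the literal median of absolute
deviations), and the **maximum**. They differ in their sensitivity to
outliers (max most, MAD least), which matters when expressivity is carried
by short bursts.

| feature | source | per-frame definition | statistics |
|---|---|---|---|
| speed | mocap | ‖dp/dt‖₂ | avg, MAD, max |
| acceleration | mocap | ‖d²p/dt²‖₂ | avg, MAD, max |
| angular speed | mocap | ‖dω/dt‖₂ (Euler, unwrapped) | avg, MAD, max |
| angular acceleration | mocap | ‖d²ω/dt²‖₂ | avg, MAD, max |
| limb contraction | mocap | mean head↔extremity distance | avg, MAD |
| CoM distance | mocap | ‖p_j − μ‖₂ | avg, MAD |
| quantity of motion | silhouette | vacated / active pixels | avg, MAD, integral |
| dimensionless jerk | mocap | (T⁵/Δp²)∫‖d³p/dt³‖² dt | single value |
| head angle wrt back | mocap | angle(T8→neck, neck→head) | avg, MAD |
| head angle wrt vertical | mocap | angle(ẑ, neck→head) | avg, MAD |
| convex hull 3D | mocap | hull volume of 23 keypoints | avg, MAD, global, union |
| convex hull 2D | campos | hull area of screen landmarks | avg, MAD, global, union |

That inventory is 12 + 8 + 3 + 1 + 8 = 32 `(feature, statistic)` kinds;
`extract_features()` emits exactly these (per-joint kinds additionally
carry one row per keypoint plus an `ALL` row holding the cross-keypoint
mean — the inventory counts kinds, not rows).

## Numerical choices

**Derivatives.** Source files may carry vendor-estimated velocity /
acceleration channels; when present they are used (switchable with
`prefer_file_channels = FALSE`), otherwise derivatives come from finite
differences: central stencils in the interior, one-sided stencils at the
boundary (second-order one-sided for the third derivative — repeated
application of the first-difference operator was rejected because its
boundary error for the third derivative grows like `1/h` and visibly
inflates the squared-jerk integral). The first/last `order` frames are
boundary-estimated; aggregations include them.

**Euler unwrapping.** Orientation channels are unwrapped per axis (jumps
larger than π folded) before differentiation and before resampling;
otherwise a continuous rotation crossing the ±π seam produces a spurious
spike and the one-revolution-per-second example (angular speed 2π rad/s)
fails at the wrap frame.

**Dimensionless jerk.** `λ = (T⁵/Δp²) ∫‖jerk‖² dt` with `T` the duration
*in seconds* (the formula is only dimensionless with physical time) and
`Δp` the movement extent, defined here as the Euclidean diameter of the
trajectory point set — computed exactly up to 10⁴ frames, by
bounding-box diagonal beyond. The trajectory defaults to the center of
mass (the feature is full-body; the only canonical full-body trajectory),
with any keypoint selectable. The integral uses the trapezoidal rule on
the frame grid. λ is scale-invariant by construction and stable under
resampling of smooth trajectories (both tested, at 1e-9 and 1 %).

**Convex hulls.** No computational-geometry package is assumed: 3D hull
facets are found by brute-force supporting-plane enumeration with
coplanar-face merging (exact for the ≤ 23-point frames it serves, and for
merged vertex sets after an interior-point prefilter), 2D hulls use the
standard Andrew/Graham construction with shoelace areas. The **global**
aggregation is the hull of all keypoints over all frames; the **union**
aggregation is the measure of the union of per-frame hulls, a subset of
the global hull. The 2D union is computed exactly by a vertical slab
decomposition with breakpoints at every vertex and pairwise edge
crossing. The 3D union is voxelized (default 1 cm); both the union and
the global hull are counted on the same grid and the union volume is
reported as `global_volume · union_count / global_count`, which (a)
guarantees union ≤ global, (b) makes a static pose give union = global
exactly, and (c) cancels most voxelization bias (resolution-stability is
tested at < 2 % between 4 cm and 2 cm grids).

**Quantity of motion.** `q(t) = |Q_δ(t)| / |f(t)|` where the motion mask
`Q_δ(t)` collects pixels active in some of the previous δ frames but not
the current one. δ is not fixed by the definition; the package default is
δ = 5 (0.2 s at 25 fps) and every output records the δ used. Warm-up
frames use the available history; frames with an empty silhouette are
undefined (`NA`), excluded from aggregation, and warned about.

**Chance tests.** The forced-choice chance level is 1/6 ≈ 16.67 %.
"Chi-square" recognition-vs-chance testing is implemented as the two-cell
(correct vs incorrect) goodness-of-fit statistic with df = 1; the test is
invariant to swapping the correct/incorrect labels with complementary
expected proportions.

## The synthetic generator

`generate_choreography()` builds poses by forward kinematics on a fixed
skeleton with anthropometric-style bone lengths (so bone lengths are
preserved to machine precision; the tests assert ± 1 mm), with arm-dominant
periodic keyframe curves — the recorded pilot choreographies kept
expressivity mostly in the arms, and the generator mirrors that. Emotion
enters through five dials (`emotion_profiles()`):

| emotion | speed | expansion | jitter (m) | head tilt (rad) | pause |
|---|---|---|---|---|---|
| neutrality | 1.00 | 1.00 | 0.0010 | 0.00 | 0.10 |
| joy | 1.50 | 1.20 | 0.0015 | −0.10 | 0.05 |
| contentment | 0.80 | 1.05 | 0.0008 | 0.00 | 0.15 |
| sadness | 0.55 | 0.80 | 0.0010 | 0.40 | 0.30 |
| fear | 0.65 | 0.75 | 0.0030 | 0.10 | 0.35 |
| anger | 1.80 | 1.15 | 0.0040 | 0.00 | 0.10 |

The directions encode what the movement-emotion literature consistently
reports: fast movement for anger and joy, slow for sadness and fear;
expansion for joy, contraction for fear and sadness; a downward head tilt
uniquely for sadness; jitter (inverse smoothness) for anger and fear. The
magnitudes are the package's own stated world, chosen once under two
design constraints rather than fitted to anything: (i) the speed dial must
dominate the extracted-speed ordering — the generator's documented
invariant is that extracted average speed ranks the emotions exactly as
the speed scales do, on every seed — so jitter amplitudes sit an order of
magnitude below the arm-swing scale and the jitter band is fixed at ~4 Hz
in physical time (framerate-independent); and (ii) the pause dial must
not confound that ordering, so pauses are implemented as a monotone time
warp `g` with `g(0)=0, g(T)=T` — holds are compensated by faster movement
elsewhere, leaving the path length and hence the average speed governed
by the speed scale alone. With those constraints, the smoothness dial
still separates dimensionless jerk by over an order of magnitude between
e.g. fear and contentment.

The time warp also makes the speed dial exactly multiplicative: doubling
it doubles mean extracted hand speed (tested at ± 5 %).

A dataset build (`build_dataset()`) reproduces the pilot design: 9
sequences × 6 emotion takes (in the fixed performance order neutrality,
joy, contentment, sadness, fear, anger) + 1 explanation take per sequence
= 54 emotional / 63 total entries, each written as MVNX-style XML, a CSV
file set, camera-relative JSON and silhouette masks (plain-text PBM — the
deliverable is text-only and PBM is the natural Boolean-mask format),
with per-entry seeds recorded in a manifest.

**What a green test does and does not establish.** The generator produces
kinematically plausible, emotion-modulated motion — it is *not* human
motion. Green tests establish that the feature definitions, their
implementations and the I/O contracts are correct and that the advertised
invariants hold on exactly the class of signals the generator emits. They
establish nothing about real dancers, real silhouette segmentation noise,
sensor drift, soft-tissue artifacts, or the perceptual validity of the
emotion dials. Observer-rating results (recognition rates of real human
judgments) are human-participant data and are not computationally
reproducible here; the ratings module is validated against hand-computed
and simulated tables instead.

## Open design points, resolved

* **MVNX dialect.** Only a minimal documented subset is read (segments;
  per-frame position / orientation / centerOfMass / derivative channels /
  footContacts; unknown elements warn and are skipped). Orientations are
  Euler XYZ triplets in radians rather than the vendor's quaternions —
  the feature definitions differentiate Euler vectors.
* **Camera convention.** CamPos `y = 1` is the top of the *rendered*
  frame (not any crop); depth is along the optical axis, matching render
  engine depth passes. Temporal resampling of projections is by nearest
  frame (≤ half a source frame of timing error), preserving exactly
  captured poses.
* **2D hull landmarks.** The hull is taken over all 23 landmarks by
  default; `landmarks =` restricts to a marker subset.
* **Resampling.** Linear interpolation on a uniform grid spanning exactly
  the source time range; when the duration is not a multiple of the target
  period the effective rate is nudged to the nearest value that is, so the
  first and last captured poses are always preserved. Upsampling is
  refused unless forced.
* **Frames and time.** Storage is 1-based, time of stored frame `k` is
  `(k − 1)/framerate` seconds.

## Known limitations

* The brute-force 3D hull is O(n³·n); it is exact and fast for per-frame
  bodies and moderate merged vertex sets, but the global hull of very
  long sequences (many thousands of hull vertices) would be slow —
  long recordings should be subsampled for the hull aggregations.
* The 2D union slab sweep is exact but quadratic in the number of edges;
  at 60 Hz over minutes of footage it becomes the dominant cost.
* The 3D union is an estimate with voxel-resolution granularity (the
  calibrated estimator removes most, not all, discretization error).
* Silhouette rasterization uses per-bone capsules with a mean-depth
  radius; it does not model self-occlusion-dependent thickness, clothing,
  or segmentation noise.
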