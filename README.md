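# kinemotion

Kinematic feature extraction for emotional full-body movement.

`kinemotion` is for researchers in experimental psychology, affective
neuroscience and computer vision who work with *same-sequence* movement
stimuli: the same short choreography performed repeatedly, each repetition
with a different emotional intention (anger, contentment, fear, joy,
neutrality, sadness). Because the movements are nominally identical,
emotional expressivity must live in the kinematics — and the package
measures it.

From three data modalities —

* **motion capture**: 23 body keypoints (Pelvis … Left toe) with positions
  `p_j(t)` in meters, Euler orientations `ω_ξ(t)` in radians, center of
  mass `μ(t)` and foot contacts, in a z-up world frame at a nominal 240 Hz
  (read from an MVNX-style XML dialect, written to per-quantity CSV);
* **camera-relative coordinates** ("CamPos"): per-landmark screen ratios
  `x, y ∈ [0, 1]` plus metric depth, from a pinhole camera model (JSON);
* **silhouette video**: Boolean foreground masks `f(t)` (plain-text PBM)

— it computes 12 kinematic features and 32 summary statistics per
sequence:

| group | features |
|---|---|
| speed / acceleration | `v_j = ‖∇_t p_j‖₂`, `a_j = ‖∇²_t p_j‖₂`, angular speed `‖∇_t ω_ξ‖₂`, angular acceleration `‖∇²_t ω_ξ‖₂` (average, MAD, max each) |
| expansion / contraction | limb contraction `¼ Σ ‖p_head − p_extremity‖₂`; distance to center of mass `‖p_j − μ‖₂` (average, MAD) |
| movement activity | quantity of motion `q(t) = |Q_δ(t)|₁ / |f(t)|₁`, with motion mask `Q_δ(t) = (⋁_{i=1..δ} f(t−i)) ∧ ¬f(t)` (average, MAD, integral) |
| smoothness | dimensionless jerk `λ = (T⁵/Δp²) ∫ ‖∇³_t p‖² dt` |
| body tilt | head angle to the back `arccos(u_ab·u_bc)` and to the vertical `arccos(ẑ·u_bc)` (average, MAD) |
| space | convex hull 3D volume (m³) and 2D screen area (average, MAD, global-hull, union-of-hulls) |

MAD is the plain median absolute deviation `median(|median(K) − K(t)|)`
(no consistency constant). "Global" aggregates the hull over all frames at
once; "union" measures the union of per-frame hulls, always a subset of
the global hull.

A deterministic synthetic generator produces emotion-modulated 23-keypoint
choreography (speed / expansion / smoothness / head-tilt / pause dials per
emotion), renders silhouettes through a virtual camera, and reproduces the
9-sequence × 6-emotion (+ 9 explanation takes, 63 stimuli total) dataset
design — so the entire pipeline is testable without proprietary hardware.
An observer-ratings module computes forced-choice confusion matrices,
recognition summaries, and chi-square tests against the 16.67 % chance
level.

## Worked example

```r
library(kinemotion)

# one synthetic "anger" take of sequence 1 (reduced scale: 1 s at 60 Hz)
s    <- generate_choreography(1, "anger", duration = 1, framerate = 60,
                              seed = 17)
cam  <- camera_model()                         # 4 m in front, 50° FOV
cp   <- project_campos(s, cam, out_hz = 30)    # screen-ratio landmarks
clip <- render_silhouette(s, cam, fps = 12, size = c(108, 192))

tab <- extract_features(s, cp, clip, sequence = "seq1", emotion = "anger",
                        voxel = 0.05)
count_statistic_kinds(tab)
#> [1] 32

subset(tab, keypoint == "ALL" & feature %in%
         c("speed", "limb_contraction", "qom", "convex_hull_3d") &
         statistic %in% c("average", "global", "union"))[, 3:7]
#>           feature statistic keypoint     value units
#>             speed   average      ALL 0.3041    m/s
#>  limb_contraction   average      ALL 1.2150    m
#>    convex_hull_3d   average      ALL 0.1332    m^3
#>    convex_hull_3d    global      ALL 0.3249    m^3
#>    convex_hull_3d     union      ALL 0.2669    m^3
#>               qom   average      ALL 0.4102    dimensionless
```

The numbers behave as the emotion dials say they should: the per-frame
hull averages 0.13 m³ while the global hull over the whole take is
0.32 m³ (the arms sweep through space they never occupy at once), the
union 0.27 m³ sits between them, and 41 % of the silhouette's pixels were
vacated within the δ = 5 frame window on average — a fast, expansive,
active take. The same comparison for a "sadness" take gives a mean hand
speed of 0.45 m/s against 1.83 m/s for anger, and a mean head tilt from
vertical of 0.43 rad against 0.04 rad.

Observer ratings against chance (e.g. 412 correct of 1080 forced-choice
responses, 6 options):

```r
chance_test(412, 1080, categories = 6)
#> $statistic  358.83      $df 1      $p_value 5.07e-80
#> $observed_rate 38.15 %  $chance_rate 16.67 %
```

## Command line

```sh
inst/cli/kinemotion synth    --out ds --seed 7
inst/cli/kinemotion convert  --mvnx ds/seq1_anger/seq1_anger.mvnx --out conv --campos
inst/cli/kinemotion extract  --in conv/csv --campos conv/campos.json --out summary.csv
inst/cli/kinemotion qom      --frames ds/seq1_anger/silhouette --out qom.csv --delta 5
inst/cli/kinemotion validate --out report
```

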