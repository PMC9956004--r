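---
title: "Detecting and counting anguilliform fish in acoustic-camera video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and counting anguilliform fish in acoustic-camera video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eelsonar)
```

## The problem

Downstream-migrating silver eels pass monitoring stations mostly at night
and in turbid water, where optical cameras are blind. High-frequency
imaging sonars ("acoustic cameras") image them regardless, as elongated
bright echoes moving across a speckled background, but whole-season
datasets run to hundreds of hours per camera and manual reading is the
bottleneck. `eelsonar` automates the reading: it detects elongated
undulating targets, follows them across frames, counts each pass once, and
scores the automatic count against an operator's reference count.

The package deliberately begins at standard video. Proprietary sonar
formats differ per vendor and are converted upstream; `read_sequence()`
accepts an uncompressed grayscale AVI or a PNG/TIFF frame directory plus a
YAML/JSON sidecar with the recording parameters that drive every derived
threshold: the pixel size along the range axis `r` (mm), the frame rate
`fps`, the mean intensity of an empty reference image, and the
operator-set minimum eel length `L_min` (cm).

## Stage by stage

### Screening with singular-value ratios

An empty sonar frame is approximately a rank-one matrix (its mean
intensity surface) plus speckle, so its 2nd and 3rd singular values sit at
the speckle noise floor. An elongated body adds low-rank structure and
lifts exactly those singular values, while diffuse intensity changes move
mostly the 1st. The echogram therefore stores, per frame,
`ratio_k = sigma_k(frame) / sigma_k(reference)` for `k = 2, 3`, and frames
with either ratio above its threshold (default 1.2, tunable with
`tune_screening()`) are collected into intervals of interest; unflagged
gaps up to half a second are bridged so a single pass stays one interval.

Numerical choices: both numerator and denominator are clamped below at
`1e-8`, so a blank (rank-deficient) frame against a blank reference gives
ratio 1 rather than 0/0. When no reference frame is supplied, the frame
with the *smallest* 2nd singular value is used — objects only ever raise
it, so the minimizing frame is an empty one even in recordings where
passes are frequent. A pixel-wise median composite would be the obvious
alternative, but averaging suppresses the speckle and inflates every
ratio by the ratio of the two noise floors; an actual frame keeps the
denominator honest. A `ratio_mode = "sigma1"` variant (normalizing by the
frame's own leading singular value) is provided behind a switch.

### Background subtraction and candidates

Within the intervals, each frame is smoothed with an exact box mean filter
whose kernel is 40 mm x 30 mm converted to pixels (rounded half-up, floor
1 px), then segmented by a per-pixel adaptive Gaussian-mixture background
model (3 modes; learning rate `1/history` with `history = 14 x fps`
frames; a pixel is foreground when its value is outside
`variance threshold x mode variance` of every background-designated mode,
with `variance threshold = 1.5 x reference mean intensity`, floored at 1
for a degenerate blank reference). The model is primed on up to `history`
frames preceding each interval, preserving streaming semantics. New modes
start at variance 36 (sd 6 grey levels) with a variance floor of 4:
initialization must be tight enough that a fish-sized intensity step
(tens of grey levels above background) segments immediately rather than
after the variance has decayed from a large initial value.

A 15 x 15 px dilation merges nearby echo fragments into one region of
interest so one fish is analyzed once; components are labeled with
8-connectivity, and each candidate keeps its *undilated* foreground
pixels (the dilation only groups, it must not thicken the shape that the
morphology stage measures). Components whose fitted-ellipse major axis is
below `0.25 x L_min` are discarded as too short to be an eel. Survivors
are cropped into a square thumbnail of side `L_min + 30 cm`,
zero-padded at frame borders.

### Morphology

Shape statistics come from the second-order central moments of the
candidate pixels, with each pixel contributing its own footprint variance
(`scale^2/12` per axis) so a one-pixel line has eccentricity strictly
below 1. Eccentricity uses the focal-distance over major-axis definition
`sqrt(1 - (b/a)^2)`. Orientations are reported in [0°, 180°) and always
compared modulo 180°.

Body length is the geodesic length of the reconstructed skeleton: the mask
is thinned (Zhang-Suen), each fragment is reduced to its longest geodesic
chain through the 8-connected skeleton graph, and fragment chains are
greedily bridged — nearest endpoint pair first — while the gap is below
`0.5 x L_min` and the bridge deviates less than 65° from both fragment end
tangents. The 45° gate one might first reach for is too strict: with the
default undulation geometry the body's local tangent deviates up to
`2*pi*A/lambda ~ 40°` from the travel axis, so legitimate bridges across a
crest exceed 45°, while the pathological case the gate exists for —
merging two parallel animals — needs a near-90° bridge and is still
rejected at 65°. If irreconcilable chains remain, the longest one is the
body and the rest contribute nothing: that is conservative against
merging distinct animals into one long "fish".

The serpentine-shape test divides the body pixels into `k = 3` sections by
k-means (10 restarts under a fixed seed, best within-cluster sum of
squares, so classification is reproducible) and measures each section's
eccentricity, ordered head-to-tail along the skeleton chain. An
anguilliform body is curved as a whole but nearly straight per section; a
compact fish is non-eccentric everywhere.

One convention is worth stating: the moment-ellipse "major axis" of a thin
straight bar is `2/sqrt(3) ~ 1.15x` the bar's true length (the ellipse
with matching variance extends past a uniform segment). The skeleton
length is therefore compared against planted truth and against the chain's
endpoint chord in the tests, not against the moment axis.

### Tracking

Candidates are associated frame to frame when the new centroid lies within
a circle of diameter `1.5 x L_min` around the track's last position —
radius multiplied by the number of elapsed frames, so a fish missed for
`n` frames is searched for proportionally further — and the orientation
difference is below 25°. Admissible pairs are matched one-to-one greedily
by distance (ties: smaller angle difference, then older track). Tracks
unseen for `max_skip_frames` close. The default gap is half a second of
frames: because the radius scales with the gap, a one-second window would
scale the circle to most of the field-of-view width, and a track whose
fish has just exited would capture the next fish entering — merging two
passes into one track that then fails the direction rule, losing both.
Half a second still bridges realistic detection dropouts.

### Classification

Frame rules: body length `>= 0.40 x L_ref` (with `L_ref` the reference
eel length, i.e. `L_min` in mm), a minimum-area rule with coefficient
0.75, and eccentricity `>= 0.90`. Track rules: mean travel distance per
frame `>= L_ref / fps` (one reference length per second), direction always
along the current, and minimum / mean eccentricity at or above the
length-class thresholds (0.85 / 0.90 for the 30-60 cm class, 0.90 / 0.92
for 60-90 cm). A track is anguilliform iff at least five frames pass all
frame rules and every track rule holds.

Two readings were genuinely open and are resolved as follows:

* **Area reference.** Taken literally, "area >= 0.75 x thumbnail area"
  can never hold: a 70 cm x 3 cm body fills ~3% of its
  `(L_min + 30 cm)^2` thumbnail. Comparing against the candidate's own
  bounding box fails differently — an undulating body fills only ~20% of
  its box (height `2 x amplitude + width`) while a compact ellipse fills
  `pi/4 ~ 0.785` of its box, so that rule *inverts* and rejects exactly
  the eels. The default reference is therefore the nominal body area
  `L_ref x 30 mm`, keeping the printed 0.75 coefficient as a minimum-size
  rule that is dimensionally meaningful. Both other modes remain available
  in `decision_rules(area_reference=)` and are exercised in the tests.
* **Track-scale eccentricity.** Computing min/mean eccentricity only over
  the frames that pass the frame rules makes the classifier non-monotone:
  raising the frame eccentricity threshold shrinks the counted set, which
  can *raise* the min/mean and flip a track to positive. Tightening a
  threshold must never create positives, so the track-scale eccentricities
  are taken over all detections of the track.

`frame_rules()` can also be asked to test all three section
eccentricities instead of the overall one (`use_section_ecc = TRUE`).

## Evaluation

`match_predictions()` matches predicted passes to reference passes
greedily in time order within a tolerance (default 5 s; operators match
visually, so the tolerance is a modeling choice, not data). The first
prediction per reference fish is a TP; further predictions of the same
fish are FP of category "tracking" — the counting error that
`identification_precision()` removes again. True negatives do not exist
in this design because operators do not log non-target objects, so the
confusion matrix is TP/FN/FP only and accuracy-style metrics are
unavailable by construction. FP categories other than "tracking"
(arcing artifacts, merged fish, other) are operator judgments supplied via
an annotations table; the package implements the tally and percentage
machinery, not the judgment.

`bootstrap_count_regression()` regresses automatic on reference hourly
counts, then draws 100 subsamples of 70% of the hours (without
replacement; a with-replacement switch exists) and tests the replicate
slopes against 1 with a one-sample t-test. When the replicate slopes are
numerically constant (identity-like inputs) the t-test is degenerate and
the p-value is reported as 1 or 0 by direct comparison of the constant
slope with 1.

## The synthetic scene generator

`make_scene()` renders: a stationary background at the configured
reference mean intensity with additive Gaussian speckle clipped to
[0, 255]; eels as constant-width bands around a sinusoidally undulating
centerline of exactly the specified arc length (amplitude 8% and
wavelength 60% of body length by default, tail-beat 1.5 Hz, cruising speed
1.2 body lengths per second — typical migrating-eel kinematics), advancing
at constant speed along the cross-range axis; compact fish and debris as
filled ellipses (default aspect 0.6, i.e. eccentricity 0.8, matching the
non-eel body shapes the classifier must reject); and arc-shaped
high-intensity streaks emulating the "arcing" artifact of strong
near-camera reflectors. Every event logs per-frame ground-truth masks, a
centerline (the length oracle), and a pass record in the reference-count
schema. Everything is deterministic given the seed.

Echo fragmentation drops random *interior* runs of the body (expected
dropped fraction = the rate), splitting the echo into pieces the skeleton
bridging must re-join. The first and last body blocks are never dropped:
truncation of the extremities is a different error mode — a shorter fish,
which no reconstruction could undo — whereas the fragmentation dial
specifically exercises mid-body dropouts.

What the generator does **not** emulate, and what passing tests therefore
do not show: range-dependent beam spreading and resolution loss,
multipath and reverberation, the BlueView structural-noise quadrants,
schooling behavior, or shape deformation near strong reflectors. Synthetic
recall/precision figures characterize the pipeline's logic under
controlled conditions, not expected field performance.

Default test geometry: frames of 200 x 260-280 px at 10 mm/px and 7 fps
(a 2 m window), scenes of 120-360 frames with up to 10 eels (620-880 mm)
and 10 compact fish in two range lanes. These sizes make a full
screening-to-classification run of a twenty-pass scene a matter of a
minute or two on one core while keeping every body tens of pixels long —
large enough for the morphology to be meaningful.

## Known limitations

* The SV-ratio screening assumes a stationary background; slow
  gain drift is absorbed by the background model downstream but will
  inflate screening ratios until the reference is re-chosen.
* The greedy one-to-one association has no appearance model; two fish
  crossing paths inside one gate radius can swap tracks. A global
  assignment could be put behind the same interface if needed.
* Decision thresholds are those of the rule table plus development-scene
  tuning of the screening thresholds; they are not learned, and transfer
  to a new site or camera should start with `tune_screening()` on a
  locally validated hour of data.
* Body length is measured in the image plane; a fish tilted out of plane
  is foreshortened and its length under-estimated.
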