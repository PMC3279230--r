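---
title: "Fall detection from RGB-D video: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fall detection from RGB-D video: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

fallwatch detects unexpected falls of a single monitored person from a
stationary indoor RGB camera, optionally augmented with an aligned depth
channel. This vignette describes the models each stage implements, the
parameters that matter and their defaults, what the synthetic scene
generator does and does not emulate, and the design decisions taken where
the design was genuinely open.

## Pipeline overview

Each frame passes through four stages:

1. **Moving-region extraction** — a per-pixel Gaussian mixture background
   model combined (by union) with a weighted three-frame difference.
2. **Shadow removal** — every moving-region pixel is classified object or
   cast shadow by a two-stage spectral test.
3. **Tracking** — object blobs are associated across frames with a
   fixed-gain alpha-beta-gamma predictor, accumulating per-object feature
   histories.
4. **Event detection** — a two-stage cascade on the bounding-box aspect
   ratio, the normalized vertical velocity of the silhouette centroid, and
   the variation of its median depth.

## Foreground segmentation

Each pixel carries a mixture of `k = 3` Gaussians over RGB with a shared
per-component variance. Components are ranked by weight/sigma and the
smallest prefix whose cumulative weight exceeds `bg_threshold = 0.7` is
called background; a pixel is foreground when its value lies farther than
`match_threshold = 2.5` standard deviations from every background
component. The learning rate defaults to 0.01 per frame.

Two update policies are available. The classic full update adapts every
pixel, which absorbs a person who stops moving in roughly
`log(0.7/0.95)/log(1 - 0.01) ≈ 30` frames — one second of stillness — after
which the blob fragments and its bounding box becomes meaningless. The
default policy (`update_mode = "background_only"`) therefore freezes the
model at foreground pixels, a standard selective-update variant in the
background-subtraction literature: a lying person remains segmented
indefinitely, while uncovered background re-matches its frozen component
immediately. The cost is that genuine scene changes (moved furniture)
persist as foreground until reset; for a fall monitor this is the right
trade.

Because a mixture model alone responds sluggishly to motion onset, the
moving region is the union of the mixture mask with a weighted difference
of consecutive frames: a pixel is flagged when
`w1*|I_t - I_{t-1}| + w2*|I_{t+1} - I_t|` (per channel, then the channel
maximum) exceeds `diff_threshold = 0.1`, with `w1 = w2 = 0.5`. The union
keeps both non-moving and fast-moving subjects; an intersection mode is
available in the configuration. The combined mask is cleaned by
morphological opening (disc radius 1) and closing (radius 2) and components
below 50 px are dropped.

The three-frame difference necessarily marks a thin band of background at
the leading and trailing edges of a moving silhouette ("ghost" pixels:
background now, object one frame away). These survive into the moving
region by design — the union rule cannot distinguish them — and they are
classified *object* by the shadow test (their appearance matches the
background, so the value-ratio gate rejects them as shadow). Their
practical effect is a modest inflation of the measured bounding box during
fast motion, quantified below under the detector.

## Shadow removal

A cast shadow darkens the background without changing its chromaticity.
The first test operates in HSV: a moving-region pixel is a shadow candidate
iff its value ratio against the reference background lies in
`[alpha, beta] = [0.4, 0.9]`, its saturation difference is at most
`t_s = 0.1`, and its circular hue distance at most `t_h = 0.1` (hue lives
on [0, 1); the distance is `min(|dh|, 1 - |dh|)`, which avoids spurious
rejections at the red seam). Hue is meaningless on achromatic pixels, so
the hue gate passes when both saturations are below 0.05. A pixel whose
background value is exactly zero can not be darkened and is never a shadow
candidate.

The second test uses normalized rg chromaticity, `r = R/(R+G+B)` and
`g = G/(R+G+B)` (with `r = g = 1/3` declared at black pixels so the
difference stays defined): the pixel must be strictly darker than the
background in both R and G, with `|dr| - |dg| <= t_n = 0.05`. That
asymmetric form is implemented as printed in its source; a
`both_bounded` mode (`|dr| <= t_n` and `|dg| <= t_n`) is selectable in the
configuration for users who prefer the symmetric reading. The two tests
run as a cascade — the second is evaluated only where the first fired —
and a pixel is labelled shadow exactly when both agree; every other
moving-region pixel is an object pixel, so object + shadow counts always
equal the region size.

The reference background is re-derived every frame from the mixture
model's dominant-weight means.

All five thresholds are empirical constants. The defaults were chosen so
that an ideally rendered shadow (chroma preserved, value attenuated by
k in [0.4, 0.9]) passes both tests at every pixel while a differently
colored actor fails them; all are exposed in the configuration.

## Tracking

Blobs are 8-connected components of object-labelled pixels with at least
`min_blob_area = 50` px. Each tracked object carries a fixed-gain
alpha-beta-gamma filter per axis (gains 0.5, 0.4, 0.1; `dt = 1/fps`),
which estimates position, velocity and acceleration and has zero
steady-state error on constant-acceleration trajectories — the property
that lets it follow an accelerating body mid-fall. Stability of a gain
triple is asserted at construction by requiring the spectral radius of the
closed-loop error transition matrix `(I - KH)F` to be below 1; at the
default gains the radius is 0.946, so transients decay by about 5% per
frame.

Association is greedy nearest-neighbour between predicted and measured
centroids within a gate of 0.15 x frame height, ties broken toward the
older track. A single-subject home scenario does not warrant global
(Hungarian) assignment. Unmatched tracks coast on their predictor for up
to `max_missed = 10` frames, then close; re-appearing blobs get fresh
identities.

The blob's depth coordinate `Z_c` is the **median** depth over its pixels.
The median rather than the mean is deliberate: ghost pixels carry
background depth, and during a fast fall they can reach ~15% of the blob's
area — enough to mask the toward-camera depth change of a forward fall if
averaged in, while leaving the median untouched.

## Event detection

Per frame and per object the detector computes:

* `ratio` — bounding-box width/height. Width over height makes the ratio
  *rise* as a body goes horizontal: standing ≈ 0.5, lying ≥ 2 for a
  sideways fall.
* `velocity` — `(y_c[t] - y_c[t-5]) / (5 * frame_height) * fps`, in frame
  heights per second, positive downward. Per-second units are the only
  reading under which the conventional ±0.3 threshold is attainable: in
  per-frame units it would demand a drop of 1.5 frame heights within the
  window, which no in-frame subject can produce.
* `delta_z` — `Z_c[t] - Z_c[t-5]`, positive when moving away from the
  camera (backward fall), negative toward it (forward fall).

The cascade first tests `ratio >= th1` (default 1.5, inclusive). Sideways
falls exceed it easily. Backward and forward falls often do not — the
silhouette foreshortens instead of elongating — and escalate to the second
stage, which declares a fall when `th2 <= ratio < th1` (with `th2 = 1.0`),
`|velocity| >= 0.3` and `|delta_z| >= th_depth = 0.1` hold together. A fall
verdict requires the triggering condition to persist for 5 consecutive
frames (~0.17 s at 30 fps), and consecutive fall frames merge into one
event whose stage is the stage that held at the triggering frame. The
absolute depth level after a backward fall (`Z_c` staying high) is visible
in the traces but is deliberately not a trigger: the detector uses the
depth *variation*, which is camera-geometry-independent.

`th1 = 1.5` and `th_velocity = 0.3` follow the conventional operating
points for this feature set; `th2` and `th_depth` have no conventional
values and were fixed at 1.0 and 0.1 so that a genuine backward fall
(depth change ≥ 0.25) clears the depth gate with a 2–3x margin while
level activities (walking, crouching) sit well below both. All six
detector parameters are configuration-exposed.

Raising any threshold can only shrink the per-frame fall condition;
persistence filtering preserves that monotonicity for event counts in all
but pathological run-splitting cases.

## The synthetic scene generator

Real recordings of falls are scarce and privacy-laden, so the package
ships a generator that renders everything the pipeline consumes: an
indoor background (flat color with a chroma-preserving vertical brightness
gradient), an actor as a filled axis-aligned ellipse, a cast shadow as a
displaced ellipse where the background RGB is multiplied by
`shadow_attenuation = 0.6` (chromaticity preserved exactly — the spectral
model the shadow tests assume), a depth plane (constant 0.9 background,
actor pixels at the scripted depth), and i.i.d. Gaussian pixel noise
(sigma = 0.01 by default) added after ground truth is recorded. The first
10 frames are background only, emulating the camera running before the
person enters; the pipeline uses them to seed the background model.

Scripted activities cover the eight canonical classes: walking, standing,
crouching down, standing up, and falls backward / forward / left / right.
The scripts are shaped in the detector's feature space with margins in
both directions: crouching raises the aspect ratio only to ~0.9 (below
`th2`) at a vertical velocity below 0.21 heights/s; sideways falls push
the ratio monotonically past 2.2 within 12 frames; backward and forward
falls peak at a scripted ratio of 1.25 while the centroid drops at ≥ 0.35
heights/s and the depth moves by 0.4 over a 14-frame fall (~0.47 s at
30 fps). Motion-edge ghosts add up to ~0.15 to the *measured* ratio during
the fall itself, which the 1.25 scripted peak absorbs without crossing
`th1`.

Default geometry is 160 x 120 at 30 fps, 60 actor frames per sequence;
the shadow-contract checks run at 320 x 240. These sizes exercise every
code path at realistic aspect ratios while keeping a 40-sequence benchmark
(8 activities x 5 randomized variants: actor height 0.50-0.60 of frame
height, fall onset 15-22, jittered actor color and starting depth)
comfortably reproducible on a single CPU. The suite is deterministic given
its master seed; `generate_benchmark_suite()` returns per-sequence
configurations rather than rendered frames so sequences can be rendered,
processed and discarded one at a time.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: articulated body shape and self-occlusion,
penumbra gradients and soft shadow edges, depth sensor noise and holes,
illumination changes, camera jitter, occluding furniture, and multi-person
interaction. The benchmark demonstrates that the pipeline's logic is
correct under its own spectral assumptions, not field performance.

## Numerical conventions and degenerate inputs

* Channel values live in [0, 1]; 8-bit inputs are divided by 255, 16-bit
  depth by 65535. Pixel coordinates are 0-based `(x, y)`, rectangles
  half-open.
* Achromatic pixels take hue 0 and saturation 0; black pixels take
  `r = g = 1/3`.
* Velocity and depth variation are undefined until the track history
  exceeds the window; the detector treats them as 0, so a newborn track
  cannot fire the second-stage detector on its first frames.
* A sequence without depth degrades the second detector to
  ratio + velocity (`delta_z = 0` throughout).
* Mixture variances are floored at 1e-3 so noise-free initialization
  leaves a finite match gate.
* Ties in component ranking and in association distance are broken by
  index (older component / older track first), making every run
  bit-reproducible.

## Limitations

The detector is per-object and binary (fall / normal); posture recognition,
inactivity zones around beds and chairs, and alarm delivery are out of
scope. Greedy association will swap identities if two people cross within
the gate. The selective background update never re-learns a permanently
changed scene without re-initialization. Thresholds were set for indoor,
stationary-camera geometry; a ceiling-mounted or wide-angle view changes
the meaning of the aspect ratio and requires re-tuning.
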