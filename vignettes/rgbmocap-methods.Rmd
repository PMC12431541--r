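---
title: "Methods: camera model, wand calibration, marker synthesis and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: camera model, wand calibration, marker synthesis and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, algorithms and numerical choices
behind `rgbmocap`, in the order data flows through a capture session:
camera geometry, wand calibration, training-image synthesis for the
marker detector, multi-view reconstruction, and the accuracy and
robustness analyses. It also states exactly what the built-in scene
simulator does and does not emulate, so the reader can judge what a
passing test suite implies about real recordings.

## Camera model and triangulation

A camera is a single real 3x4 projection matrix `P` mapping homogeneous
lab coordinates in millimetres to homogeneous pixel coordinates — the
11-parameter direct linear transformation (DLT) form. We deliberately do
not factor `P` into intrinsics and extrinsics, and we model no lens
distortion: modern machine-vision lenses at 1080p are close enough to
pinhole that the residual is far below the other error sources in this
pipeline, and the wand calibration below estimates the full projective
form anyway. Pixels are 0-based with the origin at the top-left corner,
`u` rightward and `v` downward.

On construction `P` is scaled so the left 3x3 block has positive
determinant and a unit third row; with that convention the homogeneous
scale of a projected point equals its depth in millimetres, and the
behind-camera test is simply `depth <= 0`. Projection is invariant to
this rescaling, so nothing observable changes.

A pixel back-projects to a *camera ray*: the half-line from the camera
centre (the null space of `P`) through all points with positive depth
that project to that pixel. Triangulation from two or more cameras
returns the point minimizing the sum of squared perpendicular
point-to-line distances to the observation rays — the midpoint method, a
closed-form 3x3 linear solve. We triangulate in ray space rather than
reprojection space because the downstream acceptance rule (the 5 mm
gate) and the reported *reconstruction error* (mean point-to-ray
distance over contributing cameras) are both defined in millimetres in
ray space; using the same objective keeps the accepted points and their
quality metric consistent. Degeneracy (all rays near-parallel, or
coincident centres) is detected by the ratio of extreme eigenvalues of
the normal matrix (threshold `1e-9`) and raised as an error rather than
returning an ill-conditioned solve. If a point falls behind a ray's
origin, the distance to the origin is returned and flagged; the metric
itself stays a line distance for gating purposes, since a behind-camera
point will fail every other test anyway.

## Wand calibration

All cameras are estimated from synchronized pixel observations of a
rigid wand carrying two markers a known distance apart (`WandSpec`,
user-supplied in millimetres — the one quantity the method cannot infer).
The pipeline:

1. **Bootstrap pair.** The two cameras sharing the most observations
   (overridable via `wand_config(ref_pair=)`) give a normalized
   eight-point fundamental matrix. Assuming, for this pair only, a
   shared focal length, centred principal point, square pixels and zero
   skew, the essential matrix is decomposed into relative pose with the
   cheirality test.
2. **Focal search.** That shared focal length is unknown; it is found by
   a coarse log-spaced grid plus golden-section refinement (relative
   tolerance `1e-9`) minimizing the coefficient of variation of the
   reconstructed wand lengths. A rigid length standard seen in many
   positions and orientations is exactly the information that fixes
   metric structure; at the true focal the two-view reconstruction makes
   the length constant.
3. **Incremental resection.** Remaining cameras are added in order of
   overlap by weighted DLT resection (Hartley-normalized, at least 6
   non-coplanar points), re-triangulating the structure after each
   addition. Because the camera model is fully projective, resection
   onto a projectively consistent structure is exact for noise-free
   data — no metric upgrade is needed to reach zero reprojection.
4. **Alternation.** Resection and intersection alternate with
   Huber-reweighted residuals (threshold 3 px) until the reprojection
   RMS stops decreasing (tolerance `1e-10` px); the trace of accepted
   iterates is stored and is non-increasing by construction.
5. **Bundle adjustment.** A Levenberg–Marquardt sparse bundle over all
   12 entries of every `P` and all marker positions. Residuals are
   Huber-weighted reprojection errors plus, per frame with both markers,
   a *length-spread* penalty `lambda * (|a - b| - mean length)` with
   `lambda = 2` px/mm. The penalty is essential, not cosmetic:
   reprojection error is exactly invariant under any homography of the
   whole scene (cameras compensated), so with noisy data the data alone
   cannot distinguish a metric reconstruction from a projectively warped
   one — the constant wand length is the only metric anchor. Point
   blocks are the per-frame marker pairs (6 degrees of freedom), which
   keeps the normal equations in standard sparse-bundle form with a
   small Schur complement over the cameras. The bundle is skipped when
   the alternation already converged below `1e-7` px (noise-free data).
6. **Metric upgrade.** The minimizing homography is then removed
   explicitly: a 4x4 scene homography (12 effective parameters; the
   translation column is pure gauge) is fitted by damped Gauss–Newton to
   (i) make plainly re-triangulated wand lengths match the known value
   and (ii) make every warped camera's RQ-decomposed intrinsics satisfy
   zero skew and unit pixel aspect — near-exact properties of real
   sensors, weighted strongly (1000) — with the principal point softly
   tied to the image centre (weight 30, since real principal points are
   only approximately centred). The fit uses *plainly* triangulated
   lengths because the bundle's own penalty shrinks per-frame lengths
   toward their mean and would hide the distortion signal. Applying the
   upgrade changes no reprojection residual; it only selects the correct
   member of the gauge family. The optimization runs on a centred,
   unit-scale copy of the scene so all parameters are O(1).
7. **Gauge and scale.** Finally the similarity gauge is fixed — first
   camera centre at the origin, its orientation canonical — and the
   global scale set so the mean reconstructed wand length equals the
   known distance.

The reported wand marker positions are re-estimated per frame with the
known length as a *soft* measurement (weight 4 relative to a 1 mm ray
residual, Gauss–Newton on the 6-dof pair). The weight is deliberately
moderate: a near-hard constraint would drive the length-error metric to
zero by fiat and destroy its diagnostic value, while ignoring the known
length discards real information; weight 4 treats the machined wand
length as roughly four times more trustworthy than a single ray
residual. Missing observations (a camera missing a marker in a frame)
simply contribute no residual anywhere.

Failure modes raise errors rather than degrade silently: fewer than two
cameras or fewer than 15 usable frames (connectivity), a camera sharing
fewer than 6 points with the calibrated structure (connectivity), and a
near-coplanar wand cloud (degeneracy, detected in the resection
normalization).

## Training-image synthesis

The synthesis module builds the training set for a marker detector by
compositing virtual markers onto crops of marker-free video frames. All
sampling ranges live in `synthesis_config()` and are written alongside
every generated dataset.

* **Virtual spheres.** A disc (rasterized at 48 px and resized later) is
  split into nine regions by two vertical and two horizontal boundary
  lines; the first line of each pair is sampled uniformly in
  [0.25, 0.42] of the diameter and the second in [0.58, 0.75], and the
  regions are resized (nearest-neighbour) so the boundaries land at the
  sampled positions. The line ranges are this package's defaults —
  chosen so no region can vanish and the shapes stay recognizably
  circular; they are configurable. One axis is then scaled by a factor
  in [0.80, 1.00] (chosen side at random). The fill colour is uniform
  HSL with H in [140, 160], S in [240, 255], L in [140, 170], all on
  0-255 scales (hue mapped as 256 steps over the full circle).
* **Virtual tape.** With probability 0.5 a tape patch is drawn: a
  rectangle of length 1.5-3.0 and width 0.8-1.6 sphere diameters
  (package defaults, configurable), compressed vertically by an aspect
  ratio in [0.10, 1.00] (emulating a tape surface seen off-axis),
  rotated in [0, 360) degrees, offset from its image centre by up to
  half a sphere diameter, and filled with HSL H in [0, 30], S in
  [0, 20], L in [200, 255]. The positional offset is baked into the
  tape's own image so that anchoring the image centre keeps the
  randomness.
* **Composition.** The tape-image centre is anchored at
  `v1 = v2 * r_aspect + v3 * (1 - r_aspect)`, where `v2` is the sphere
  centroid, `v3` its bottom-edge point, and `r_aspect` the tape aspect
  ratio: a face-on tape sits behind the sphere's centre, a fully
  foreshortened one at its bottom edge. The tape is drawn underneath
  the sphere. Both layers are resized (nearest-neighbour, matching the
  resize used for their generation) so the sphere's larger bbox
  dimension hits an integer target drawn from [8, 24] px — resizing the
  sphere's own tight canvas guarantees the achieved diameter equals the
  target exactly — and the composite is rotated by a uniform random
  angle (nearest-neighbour, enlarged canvas). We resize the layers
  before compositing rather than after; the two orders differ only in
  sub-pixel rounding, and this one makes the diameter guarantee exact.
* **Insertion.** A random 320x320 crop of the background frame is
  upscaled to 640x640 with Catmull–Rom bicubic interpolation (the
  standard a = -0.5 kernel, half-pixel centre convention, clamped
  edges), and 7-12 composed markers are placed by rejection sampling so
  that their blur-dilated masks never overlap (overlapping markers
  would corrupt each other's annotations; the placement rejects up to
  200 positions before failing loudly). Each marker's boundary is
  smoothed by a separable Gaussian of sigma in [0.5, 3.0] px applied to
  a local patch, after which the background is restored outside the
  marker mask dilated by `3 * sigma` — so the blur feathers the marker
  edge into a narrow band while every pixel outside that band stays
  bit-identical to the upscaled crop. Annotations are the tight
  bounding boxes of the sphere masks, normalized to [0, 1], one
  `class cx cy w h` line per marker.
* **Determinism.** One seeded generator drives each training image, and
  dataset generation derives one sub-seed per image from the master
  seed, so any image can be regenerated in isolation, bit-identically.

A practical note on the bbox-coverage property: with the deformation
ranges above, a few percent of markers (strongly deformed shapes at
8-10 px) have bbox-corner pixels that no disc drawn in the tight box can
cover, so per-marker disc coverage bottoms out around 0.85 even though
the mean is ~0.98. The tests therefore assert exact bbox tightness per
marker, a 0.8 floor per marker, and a 0.95 mean.

## Detection plumbing

The detector itself is a contract: any function taking an image and a
configuration and returning centres, box sizes, confidences and classes
can be plugged in — the fine-tuned network in production, or the
packaged colour-threshold detector (HSL in-range mask, connected
components via `EBImage::bwlabel`, centroid and tight box per component)
in tests. Before detection the image is upscaled by an integer factor
(default 2, bicubic), and detected coordinates are mapped back by pure
division. Division is a convention, not an identity: under the
half-pixel bicubic convention the exact inverse map is
`(x + 0.5)/f - 0.5`, so pure division carries a systematic `+0.25` px
offset at factor 2. We keep the plain-division convention for
simplicity and document that the offset is common to all cameras and
largely cancels in triangulation; the end-to-end test bounds its net
effect. Default thresholds are deliberately permissive (confidence and
IoU both 0.01) — with markers this small, suppression is better done
geometrically downstream. The square-bounding-box filter
(`min(w,h)/max(w,h) >= 1 - tolerance`) discards detections of partially
occluded markers, whose elongated boxes have centres shifted off the
true marker centre.

## Multi-view reconstruction

Correspondence across cameras is unknown, so candidate points are
grown: seed with all detection pairs from the two widest-baseline
cameras (widest first, because baseline length controls triangulation
conditioning), keep seeds whose two rays already agree within the gate,
then for each remaining camera add the detection that keeps every ray
distance below the gate with the lowest mean — re-triangulating after
every addition, so the gate is always tested against the updated point.
Candidates need at least `min_cameras` (default 3) cameras and every
ray within `gate_mm` (default 5 mm). Conflicts are resolved by most
cameras, then lowest mean ray distance; each detection contributes to
at most one point (exclusivity — sharing a detection between two
accepted points would double-count evidence). Seeding then continues
with the next-widest pair over the detections still unclaimed, which
recovers markers that happened to be missing (dropout, occlusion) in
the widest pair. All orderings are deterministic given sorted camera
ids, so reruns are bit-identical. A pre-filter only tries detections
whose rays pass within twice the gate of the current candidate — a
conservative bound, since adding a ray pulls the point toward it.

Labels are propagated frame-to-frame by greedy nearest-neighbour
association with a per-frame jump limit (scaled by the gap length when
a label skipped frames); an association with a second candidate inside
the limit is flagged ambiguous rather than resolved silently, and
unmatched points receive stable anonymous ids.

## Evaluation

*Bland–Altman* agreement runs per coordinate component on
proposed-minus-gold differences: fixed bias is the mean difference
(one-sample t-test), proportional bias the ordinary-least-squares slope
of difference on pairwise mean (t-test on the slope), limits of
agreement mean ± 1.96 SD. Parametric tests are appropriate at the
sample sizes this is designed for (tens of thousands of paired points);
no nonparametric fallback is provided. Zero-variance differences are
flagged degenerate instead of producing meaningless t statistics.
*Resultant error* is the Euclidean norm of the 3D error vector; its
95th and 99th percentiles use linear interpolation between order
statistics (R quantile type 7 — the convention is stated because the
source of comparison numbers rarely states one).

The *robustness Monte Carlo* measures sensitivity of a reconstruction
to digitization error: per iteration, a reconstructed point is drawn
uniformly within its camera-count stratum; for each contributing camera
the stored digitized coordinate is displaced by a uniform draw over the
disk obtained by reprojecting a sphere (default diameter 12 mm, half
the 24 mm marker) centred at the point; the point is re-triangulated
from the noisy coordinates and its displacement recorded. Disk sampling
is uniform over area (`r * sqrt(U)`), and the disk radius is computed
per camera at the point's depth. By default every contributing camera
is perturbed each iteration; `per_camera = "one"` switches to
perturbing a single random camera, since the natural-language
description of such procedures is ambiguous between the two readings.
Means and maxima are aggregated per camera count.

## The scene simulator, and what tests do not show

The simulator produces the fixtures for everything above: a ring of
cameras around a 2 x 4 x 2 m volume (all corners projected inside every
image, with the largest focal length that achieves that at a 7 % margin
— at 1080p this puts a 24 mm marker at roughly 5.5-9 px across the
volume, or 11-18 px after the 2x detection upscale), 25 gait-like
marker trajectories (forward progression plus limb-like sinusoids,
larger amplitudes distally), wand sweeps with exactly constant
separation on a quasi-periodic volume-covering path, exact or noisy
projections with independent dropout, and rendered frames with
coverage-antialiased discs in the marker colour range.

The gait model is plausible multi-target geometry, not biomechanics: no
soft-tissue artifact, no marker occlusion by the body, no motion blur,
no lighting variation, no lens distortion, and rendered markers are
perfect discs. Consequently, passing tests demonstrate the geometry,
calibration, bookkeeping and statistics are correct — they do not
demonstrate detector accuracy on real video, which depends on the
fine-tuned network and the recording conditions.

Default problem sizes in the tests and the acceptance script — 500 wand
frames, 60-500 frames per unit scene, 200-1000 synthesized images,
10^4 Monte Carlo iterations per stratum, 2-3 rendered frames per camera
end to end — are the package's chosen verification scale: large enough
that every statistical check has comfortable power, small enough to run
on a laptop in minutes. All of them scale up by changing one argument.

## Known limitations

* Wand calibration assumes the bootstrap pair shares a focal length and
  centred principal point; rigs mixing very different lenses should
  supply `ref_pair` as two similar cameras. The bundle re-frees all 11
  parameters per camera afterwards.
* The metric upgrade leans on zero-skew/unit-aspect intrinsics; a
  sensor with anamorphic pixels would need those weights relaxed.
* Correspondence search is greedy; with very dense markers (spacing
  approaching the gate) or heavy detection noise it can return
  additional ghost points that satisfy the gate. They are genuine
  solutions of the published acceptance rule, not bookkeeping errors;
  raising `min_cameras` or applying the squareness filter suppresses
  them.
* Trajectory tracking does no gap-filling or smoothing, and gait events
  or joint angles are out of scope.
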