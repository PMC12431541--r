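# rgbmocap

Marker-based motion capture from ordinary RGB cameras, in R.

Infrared optical motion capture automates marker digitization but is
expensive; manual digitization of RGB video is cheap but laborious. A
middle road is to keep the physical spherical markers, record with
synchronized RGB cameras, and let an object-detection network find the
marker centers in every frame. `rgbmocap` implements everything around
that detector:

* **Geometry** — the 11-parameter projective camera (DLT form)
  `x ~ P X`, pixel-to-ray back-projection, and multi-ray triangulation
  by the midpoint method: the reconstructed point minimizes
  `sum_i d(X, r_i)^2`, the sum of squared perpendicular distances to
  the camera rays. The mean of `d(X, r_i)` over contributing cameras is
  the *reconstruction error* reported throughout.
* **Wand calibration** — all cameras are estimated from synchronized
  views of a rigid two-marker wand of known length swept through the
  volume: eight-point bootstrap of a reference pair, a focal search
  that minimizes the spread of reconstructed wand lengths, incremental
  DLT resection, sparse bundle adjustment, and a closed "metric
  upgrade" over the scene-homography gauge that restores a constant
  wand length and physically valid intrinsics.
* **Training-data synthesis** — annotated 640x640 training images for
  fine-tuning a detector: deformed virtual spheres in the marker's HSL
  range (H 140-160, S 240-255, L 140-170 on 0-255 scales), optional
  white-tape patches anchored at
  `v1 = v2 * r_aspect + v3 * (1 - r_aspect)` between the sphere
  centroid `v2` and bottom edge `v3`, random sphere diameters of
  8-24 px, 7-12 markers per image, per-marker Gaussian edge blur
  (sigma 0.5-3.0), automatic normalized bounding-box labels.
* **Reconstruction** — cross-camera correspondence search under the
  acceptance rule *at least 3 cameras, every ray within 5 mm of the
  reconstructed point*, detection exclusivity, and nearest-neighbour
  label tracking with TRC/CSV export.
* **Evaluation** — per-component Bland–Altman agreement (fixed bias by
  one-sample t-test, proportional bias by regressing difference on
  pairwise mean, limits of agreement at mean ± 1.96 SD), resultant
  (3D Euclidean) error statistics, and a robustness Monte Carlo that
  perturbs digitized coordinates inside the reprojection of a 12 mm
  sphere and re-triangulates.
* **Scene simulator** — ground-truth rigs (8 cameras around a
  2 x 4 x 2 m volume), 25 gait-like marker trajectories, wand sweeps,
  exact or noisy projections, and rendered frames, so the whole
  pipeline is testable end to end with a GPU-free colour-threshold
  detector standing in for the network.

## Worked example

Simulate a capture session, calibrate from the wand, reconstruct, and
evaluate:

```r
library(rgbmocap)

scene <- make_scene(duration_s = 0.1, wand_frames = 500, seed = 5)

# wand calibration from pixel observations of the two wand markers
wt <- scene$wand_track
obs <- do.call(rbind, lapply(names(scene$cameras), function(cid) {
  cam <- scene$cameras[[cid]]
  pa <- project_points(cam, wt$a); pb <- project_points(cam, wt$b)
  rbind(data.frame(frame = 1:500, camera = cid, marker = "a", u = pa$u, v = pa$v),
        data.frame(frame = 1:500, camera = cid, marker = "b", u = pb$u, v = pb$v))
}))
cal <- calibrate_from_wand(obs, wand_length_mm = 500)
cal
#> <wand_calibration  8 cameras, 500 frames
#>   wand length error 0.0000 mm (sd 0.0000)
#>   reconstruction error 0.0000 mm, reprojection RMS 0.00000 px>
```

With noise-free observations the rig is recovered to numerical
precision; with 0.3 px Gaussian detection noise the same call reports a
wand length error of ~0.09 mm and a reconstruction error (mean
point-to-ray distance) of ~1.5 mm.

```r
# reconstruct one frame of the 25 gait markers and check the gate
det <- project_scene(scene, frames = 1)
pts <- match_and_triangulate(det, scene$cameras, reconstruction_config())
length(pts)
#> [1] 25
range(sapply(pts, `[[`, "mean_ray_distance"))
#> [1] 0.000000e+00 5.899087e-05

# robustness of an 8-camera reconstruction to 12 mm digitization noise
rb <- robustness_mc(pts, scene$cameras,
                    robustness_config(iterations = 10000, seed = 42))
rb[, c("n_cameras", "mean_mm", "max_mm")]
#>   n_cameras  mean_mm   max_mm
#> 1         8 2.170797 5.793985
```

A command-line front end wrapping these functions is installed at
`inst/cli/rgbmocap.R` (subcommands `simulate`, `calibrate-wand`,
`detect`, `reconstruct`, `evaluate`, `robustness`, `build-dataset`).

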