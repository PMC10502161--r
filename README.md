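# insect3d

3D insect tracking from two orthogonal cameras, in R.

Small plant-dwelling insects (planthoppers, aphids and similar pests) are
hard to monitor automatically: a single camera sees only a 2D projection, so
motion toward or away from the lens is invisible. `insect3d` implements a
dual-camera monitoring pipeline for a potted plant filmed by two cameras
mounted 90° apart: camera 1 observes the world (x, z) plane, camera 2 the
(y, z) plane, and the shared vertical axis z ties the two views together.
From per-frame 2D detections it reconstructs millimetre-scale 3D
trajectories for each insect and summarises their movement.

The pipeline has four stages:

1. **Calibration.** Each camera is calibrated by a measured landmark: a
   known physical length `L` (mm) whose endpoints sit at pixels `p_a`,
   `p_b` gives the scale `RATIO = L / |p_a − p_b|` in mm/pixel. Four
   ratios (horizontal and vertical per camera) and the pixel position of
   the world origin `(X0, Y0)` in each view fully specify the mapping

   ```
   x = (X1 − X01)·XRATIO      z1 = (Y01 − Y1)·ZRATIO1
   y = (X02 − X2)·YRATIO      z2 = (Y02 − Y2)·ZRATIO2
   ```

   with `z` taken from either camera or their mean. The mapping is
   orthographic: constant ratios, no perspective term.

2. **Cross-camera pairing and localization.** Within a frame, detections
   from the two cameras are paired greedily by agreement of their implied
   heights `|z1 − z2|` (the only coordinate both views observe), and each
   pair is triangulated to a 3D world point.

3. **Tracking and re-identification.** Frame-to-frame association is
   nearest-neighbour in 3D with a hard gate (default 2 mm per 1/30 s step)
   plus an appearance gate: each detection's bounding box is resampled to
   40×40 px and summarised by a normalized per-channel colour histogram
   `h_i = n_i / N`; two boxes match when the histogram-intersection
   dissimilarity `1 − Σ min(a_i, b_i)/C` is below a threshold. Detector
   dropouts fragment tracks; fragments are re-merged greedily by appearance,
   under the rule that temporally overlapping fragments are distinct
   insects. Tracks seen in fewer than 15 frames are pruned as noise.

4. **Statistics and export.** Per-insect total travelled distance
   `Σ_f ‖p(f+1) − p(f)‖₂`, windowed speed profiles (mm per minute),
   point-cloud export (CSV / ASCII PLY) and 3D or projected trajectory
   plots.

Because trained detector weights are not part of the package, a seeded
scene simulator stands in for the detector: it generates ground-truth 3D
trajectories in the real rig's geometry (28 mm pot, cameras 200 mm away,
30 fps), projects them into both image planes, and corrupts the detection
streams with pixel noise, missed detections, spurious detections and
occlusion windows. A naive blob detector is included so the full
image-to-track path can also be exercised on rendered frames.

## Worked example

```r
library(insect3d)

# calibration: pot width 28 mm spans pixels 902..458 in camera 1
compute_ratio(28, 902, 458)
#> [1] 0.06306306

# localize one detection pair seen at (730, 1278) and (745, 1283)
cams <- reference_cameras(round_ratios = TRUE)
d1 <- tibble::tibble(frame_index = 0L, x_center = 730, y_center = 1278)
d2 <- tibble::tibble(frame_index = 0L, x_center = 745, y_center = 1283)
pixels_to_world(d1, d2, cams$cam1, cams$cam2)
#> # A tibble: 1 × 6
#>   frame_index      x     y     z z_cam1 z_cam2
#>         <int>  <dbl> <dbl> <dbl>  <dbl>  <dbl>
#> 1           0 -0.441 -1.42  8.24   7.70   8.78
```

The insect sits 0.441 mm left of and 1.42 mm in front of the pot centre,
about 8 mm above the ground; the two cameras' independent height estimates
(7.70 and 8.78 mm) differ by about a millimetre of calibration error, and
`z` is their mean.

```r
# simulate a noisy 20 s scene and track it end to end
cams   <- reference_cameras()
sc     <- scene_config(n_insects = 3, duration = 20, pixel_noise_sd = 1,
                       p_miss = 0.05, rng_seed = 7)
truth  <- simulate_trajectories(sc)
scene  <- project_scene(truth, cams$cam1, cams$cam2, sc)
tracks <- track_video(scene$labels_cam1, scene$labels_cam2,
                      cams$cam1, cams$cam2, n_frames = truth$frame_count)
tracks
#> <track_set> 3 track(s), 1713 observation(s), 600 frame(s)

evaluate_tracking(truth, tracks)
#> # A tibble: 1 × 8
#>   n_truth_tracks n_est_tracks completeness identity_switches  rmse ...
#> 1              3            3        0.952                 0 0.123

dplyr::select(motion_stats(tracks), -profile)
#> # A tibble: 3 × 6
#>   track_id n_obs first_frame last_frame total_distance net_displacement
#> 1        1   564           0        599           88.0             4.02
#> 2        2   569           0        599           92.3             2.62
#> 3        3   580           0        599           92.9             3.18
```

All three insects are recovered as single identities (no switches) with
95% of truth observations found — the 5% shortfall is exactly the injected
miss rate — and 0.12 mm position error. Note how 1 px of detection noise
inflates the summed path length (`total_distance`) far above the net
displacement; see the vignette for why raw path sums on noisy detections
are upper-bound estimates. `autoplot(tracks)` draws the camera-view
projections coloured by identity, `plot_tracks()` writes a 3D scatter, and
`export_point_cloud()` writes CSV/PLY point clouds.

A command-line front end wraps the same functions:

```sh
Rscript inst/scripts/insect3d pipeline \
  --config inst/extdata/reference_config.yaml --out out/ --seed 3
# [track] 3 track(s), 1800 observation(s)
# [stats] total distance per track: 6.31, 6.87, 7.01 mm
```

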