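---
title: "Methods: dual-camera 3D insect tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-camera 3D insect tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insect3d)
```

## The measurement model

Two cameras film a potted plant from directions 90° apart, 200 mm from the
pot centre and 86 mm above the ground. World coordinates are millimetres in
a right-handed frame with origin at the pot centre; camera 1 images the
(x, z) plane, camera 2 the (y, z) plane. Each camera's frames are cropped
to a region of interest around the plant and resized (bilinear) to a fixed
raster, and every pixel coordinate in the package refers to that raster,
with the usual image convention: origin top-left, x rightward, y downward.

Image formation is modelled as *orthographic*: a constant mm-per-pixel
ratio per axis per camera, calibrated from measured landmarks
(`compute_ratio(L, p_a, p_b) = L / |p_a - p_b|`). This is an approximation;
at 200 mm stand-off, a ±15 mm excursion toward a camera changes true image
scale by roughly ±7%, which the model ignores. The approximation is what
makes calibration possible with a ruler and two reference points rather
than a full intrinsic/extrinsic camera model, and it is accurate for
motion roughly in the plant's vertical plane. Lens distortion is likewise
out of scope.

A detection pair maps to world coordinates as

- `x = (X1 − X01)·XRATIO`, `y = (X02 − X2)·YRATIO`,
- `z1 = (Y01 − Y1)·ZRATIO1`, `z2 = (Y02 − Y2)·ZRATIO2`,

where `(X0i, Y0i)` is the pixel position of the world origin in camera
`i`. Both cameras estimate the same physical height, so `z` must be fused
from `z1, z2`. The package defaults to their mean (`z_policy = "mean"`),
which halves pixel-quantization variance; either camera alone is
selectable. On the reference rig the two vertical calibrations disagree
by about 1% of scale, so `z1` and `z2` can differ by ~1 mm at 80 mm
height — a calibration property, not an error of either view. The
cross-camera pairing tolerance (`z_pair_tolerance`, default 2 mm) absorbs
this; when residual disagreement matters, fuse with `"cam1"` or `"cam2"`
and treat the other view as a check.

`reference_cameras()` builds this rig's camera pair; ratios are kept at
full floating precision internally and rounded only for display
(`round_ratios = TRUE` reproduces the 3–4 decimal constants used in
worked examples).

## Tracking

**Cross-camera pairing.** Height is the only coordinate observed by both
views, so detections are paired greedily by ascending `|z1 − z2|`, each
detection used at most once, rejecting pairs that disagree by more than
`z_pair_tolerance` (2 mm). Detections seen in one camera only produce no
3D point: for the target insects (≈1 mm body length moving a few mm/s)
a one-camera sighting carries no depth information worth a motion model,
and the miss is recovered later by re-identification.

**Frame-to-frame association.** Candidates at frame t+1 are matched to
tracks last seen at frame t by nearest 3D distance, gated at
`threshold_distance` (2 mm): at 30 fps an insect crawling even 10 mm/s
moves 0.33 mm per frame, so 2 mm is a generous physical bound, while two
insects closer than 2 mm are genuinely ambiguous. When appearance is
available the match must also pass the histogram gate below. A per-track
nearest-neighbour rule can hand one candidate to two tracks, so conflicts
are resolved greedily by ascending distance with each candidate consumed
once; exact ties break by track order then candidate index, making the
tracker deterministic by construction (it uses no random numbers).

**Appearance.** Every bounding box is clipped to the frame (partial
occlusion at the edge is expected), resampled to `hist_w × hist_h`
(40×40) pixels, and reduced to per-channel intensity histograms
normalized by the patch pixel count. The dissimilarity between two boxes
is one minus the mean per-channel histogram intersection, in [0, 1], zero
for identical histograms. Defaults: RGB, 16 bins per channel,
concatenated. The bin count trades invariance against discrimination: 16
bins tolerate the blur of a 12×17 px insect crop while still separating
differently coloured individuals; both are configurable
(`feature_config()`). When the tracker is given frames it computes
histograms itself; simulator label streams carry equivalent per-detection
histograms so the appearance pathway runs without storing frames.

**Re-identification.** A missed detection ends a fragment; the insect's
reappearance starts a new one. Fragments are merged using appearance
only: the dissimilarity between the earlier fragment's last-appearance
histogram and the later fragment's first-appearance histogram must be
below `threshold_his` (default 0.3, chosen so same-insect crops under
mild noise pass and distinct-colour insects fail), the gap must be within
`max_gap` (default unlimited), and the two fragments must not overlap in
time — coexistence in any frame proves two distinct insects. Bridged gap
frames stay empty; no interpolation is invented.

Merge order was the one genuinely open design choice. Considering merges
globally in order of ascending dissimilarity sounds natural, but when one
insect leaves many fragments of near-identical appearance the pairwise
dissimilarities are statistical near-ties, and the global order then
stitches two or more interleaved chains through one insect's fragments,
splitting its identity. The package therefore defaults to an online
sweep (`reid_order = "chronological"`): fragments are visited in start
order and each is attached to the best-matching eligible lost chain. This
keeps one chain per insect whenever appearance separates insects at all,
and reduces to the same result as the global order when fragments are
few. The global ordering remains available as
`reid_order = "appearance"` for study.

**Pruning.** Background clutter can produce consistent detections for a
few frames. Tracks with fewer than `min_track_frames` observations
(default 15, i.e. 0.5 s at 30 fps — counted after re-identification, with
an inclusive boundary) are discarded. Pruning is idempotent.

## Movement statistics

Total travelled distance is the sum of Euclidean step lengths between
consecutive observations. For merged tracks the straight line across an
occlusion gap is counted once, making the total a lower bound on the true
path. The windowed speed profile partitions frames into consecutive
windows of `window × fps` frames from frame 0, assigns each step to the
window containing its starting frame, and therefore sums exactly to the
total; a trailing partial window is flagged. With `window = 60` the
profile reads as mm per minute.

A caution that applies to any path-integral statistic: independent
per-frame position noise *adds* length. At 1 px detection noise
(≈0.12 mm RMS in world coordinates) a stationary insect accrues roughly
0.15 mm of spurious path per frame — several times a slow insect's true
movement. Net displacement and windowed profiles on smoothed or noiseless
detections are unaffected; kinematic smoothing itself is deliberately out
of scope.

## The scene simulator

The simulator generates what the detector would have produced, under the
reference rig's fixed conditions: a 28 mm pot, cameras 200 mm away at
86 mm height, 30 fps, insect bounding boxes of mean 12×17 px with ±20%
uniform size jitter. Insects move by a waypoint walk — piecewise-linear
paths toward uniformly drawn waypoints at a bounded per-frame step
(default `step_scale` 0.01 mm/frame ≈ 0.3 mm/s, the pace of a slowly
crawling hopper) — confined to ±28 mm around the plant axis and 0–150 mm
height. Each insect keeps to its own height band (an equal split of the
plant height with a 15% margin), as settled insects on distinct leaves
do; with up to a handful of insects this also guarantees the >10 mm
separation under which tracking is unambiguous. Corruption follows the
detector's observed failure modes: Gaussian pixel noise on projected
centres (then rounding to whole pixels, as in integer label files),
whole-observation misses with probability `p_miss`, Poisson-rate spurious
boxes uniform over each raster, and per-track occlusion windows. A miss
drops the observation in *both* cameras: the dominant causes (pose, blur,
occlusion by the plant near the insect) affect both views of a 1 mm
target together, and the alternative — independent per-camera drops —
would make every analysis of miss handling conflate two failure rates.
All randomness derives from `rng_seed` through one substream per concern
(motion, box jitter, pixel noise, misses, spurious detections), so
enabling one noise source never shifts another; output is bit-stable for
a fixed seed.

What the simulator does *not* emulate: perspective scale change (the
geometry model is orthographic, so simulator and tracker share the
projection by construction — projection-model error is not measurable
here), plant growth or leaf occlusion geometry, appearance change with
pose or lighting, correlated (burst) detector failures, and detector
localization bias. Passing tests on simulated scenes therefore validate
the geometry, association, re-identification and statistics machinery —
not the detector itself, which is pluggable (any producer of the label
format, including the included naive blob detector, can stand in).

Rendered frames (light background, optional stem stripe, insects as
filled ellipses in per-insect colours) exist so the histogram and
blob-detection paths can be exercised on images; the blob detector
thresholds luminance and keeps connected components within an area band.

## Numerical and interface choices

- **Bilinear resampling** uses pixel-centre alignment
  (`src = (dst − 0.5)·scale + 0.5`, clamped), implemented in-package so
  ROI handling, box resampling and the simulator agree exactly on the
  convention; it is verified against an independently coded per-pixel
  oracle.
- **Label dialects.** Both pixel-unit and normalized YOLO-style label
  files are supported behind an explicit `coords` flag, never guessed:
  misreading one dialect as the other corrupts geometry by orders of
  magnitude. Files are written at 6 decimals, making round trips
  loss-free at that precision. One file per camera per frame,
  `frame_{index:06d}.txt`.
- **Histogram degenerate cases.** A box fully outside the frame is an
  error; a partially visible box is clipped. Bins are equal-width on
  [0, 1] with the top edge closed.
- **Greedy ties.** All greedy assignments (pairing, association,
  evaluation matching) order by cost with deterministic index tie-breaks,
  so results are invariant to detection file ordering except under exact
  cost ties.
- **Evaluation.** `evaluate_tracking()` matches truth to estimate per
  frame (greedy, gated at `match_radius`) and reports completeness
  (fraction of all truth observations recovered), identity switches (a
  truth track changing its matched estimated track), RMSE over matched
  pairs, and never-matched spurious tracks. Completeness is charged for
  undetectable observations too: with 5% missed detections even perfect
  tracking tops out at 95%.
- **Problem sizes.** The shipped tests run scenes of 1–3 insects at 30 fps
  for 2–60 s (up to 5,400 truth observations per scene, five replicates
  for the noise study), which keeps the full suite under a few minutes on
  one core while leaving every code path, including rendering and the
  CLI, exercised end to end.

## Known limitations

- Orthographic calibration biases x/y for insects far off the plant
  plane; the bias is proportional to depth excursion and unmodelled.
- Appearance is colour-histogram only: two same-coloured insects that
  pass within the association gate of each other, or that alternate
  during an occlusion, can swap identities. Texture or learned embeddings
  are out of scope.
- Path-length statistics inflate under detection noise (above); no
  smoothing is applied.
- Re-identification trusts the no-temporal-overlap rule; a spurious track
  overlapping a real gap can block a correct merge.
- The monitoring volume is a single plant; the simulator's height-band
  motion model is not a behavioural model of any species.
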