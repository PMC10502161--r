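# Reference bench configuration: two orthogonal cameras around a 28 mm
# planting pot, calibrated from measured landmarks. All physical constants
# live here, never in code.
calibration:
  cam1:
    origin: [737, 1350]
    roi:
      crop_top_left: [757, 0]
      crop_bottom_right: [1457, 850]
      resize_to: [1400, 1700]
    horizontal:            # pot width across the camera-1 view
      length_mm: 28
      pixel_a: 902
      pixel_b: 458
    vertical:              # ground to first leaf
      length_mm: 63.15
      pixel_a: 1345
      pixel_b: 756
  cam2:
    origin: [722, 1364]
    roi:
      crop_top_left: [1095, 0]
      crop_bottom_right: [2495, 1700]
      resize_to: [1400, 1700]
    horizontal:            # pot width across the camera-2 view
      length_mm: 28
      pixel_a: 973
      pixel_b: 519
    vertical:              # distance between the two horizontal pot lines
      length_mm: 18
      pixel_a: 1644
      pixel_b: 1478
tracker:
  threshold_distance: 2    # mm between consecutive frames
  threshold_his: 0.3       # histogram dissimilarity gate
  min_track_frames: 15     # 0.5 s at 30 fps
  z_pair_tolerance: 2      # mm of cross-camera height disagreement
  fps: 30
features:
  hist_w: 40
  hist_h: 40
  bins_per_channel: 16
  channels: 3
scene:                     # used by the simulate stage
  n_insects: 3
  duration: 20
  pixel_noise_sd: 0       # noise adds jitter that inflates summed path
                          # length; keep the demo scene clean
  p_miss: 0               # label-file pipelines carry no appearance, so
                          # miss-induced gaps would stay unmerged; use the
                          # frames path (detect + track --frames) to study
                          # missed detections with re-identification
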