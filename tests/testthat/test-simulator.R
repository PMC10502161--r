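test_that("trajectory simulation is deterministic and bounded", {
  sc <- scene_config(n_insects = 3, duration = 5, rng_seed = 9)
  t1 <- simulate_trajectories(sc)
  t2 <- simulate_trajectories(sc)
  expect_equal(tidy(t1), tidy(t2))
  obs <- tidy(t1)
  expect_equal(nrow(obs), 3 * 150)
  # confinement box
  expect_true(all(abs(obs$x) <= sc$pot_width))
  expect_true(all(abs(obs$y) <= sc$pot_width))
  expect_true(all(obs$z >= 0 & obs$z <= 150))
  # stationary model never moves
  st <- simulate_trajectories(scene_config(n_insects = 2, duration = 2,
                                           motion = "stationary",
                                           rng_seed = 9))
  expect_equal(sum(motion_stats(st)$total_distance), 0)
})

test_that("per-frame steps never exceed the configured step scale", {
  sc <- scene_config(n_insects = 2, duration = 170, step_scale = 0.05,
                     rng_seed = 23)
  obs <- tidy(simulate_trajectories(sc)) # > 10^4 frames audited
  steps <- obs |>
    dplyr::group_by(track_id) |>
    dplyr::reframe(step = sqrt(diff(x)^2 + diff(y)^2 + diff(z)^2))
  expect_gt(nrow(steps), 10000)
  expect_lte(max(steps$step), 0.05 + 1e-12)
})

test_that("noiseless projection round-trips through the geometry", {
  cams <- ref_cams
  sc <- scene_config(n_insects = 3, duration = 2, rng_seed = 29)
  truth <- simulate_trajectories(sc)
  scene <- project_scene(truth, cams$cam1, cams$cam2, sc, appearance = "none")
  # align label rows with truth observations by (insect, frame)
  l1 <- dplyr::arrange(scene$labels_cam1, truth_id, frame_index)
  l2 <- dplyr::arrange(scene$labels_cam2, truth_id, frame_index)
  tr <- dplyr::arrange(tidy(truth), track_id, frame_index)
  expect_equal(nrow(l1), nrow(tr))
  w <- pixels_to_world(l1, l2, cams$cam1, cams$cam2)
  max_ratio <- max(cams$cam1$horizontal_ratio, cams$cam1$vertical_ratio,
                   cams$cam2$horizontal_ratio, cams$cam2$vertical_ratio)
  expect_lt(max(abs(w$x - tr$x)), 0.5 * max_ratio)
  expect_lt(max(abs(w$y - tr$y)), 0.5 * max_ratio)
  expect_lt(max(abs(w$z - tr$z)), 0.5 * max_ratio)
})

test_that("projection is bit-stable for a fixed seed and misses drop both views", {
  cams <- ref_cams
  sc <- scene_config(n_insects = 2, duration = 2, pixel_noise_sd = 1,
                     p_miss = 0.2, fp_rate = 0.5, rng_seed = 31)
  truth <- simulate_trajectories(sc)
  s1 <- project_scene(truth, cams$cam1, cams$cam2, sc, appearance = "none")
  s2 <- project_scene(truth, cams$cam1, cams$cam2, sc, appearance = "none")
  expect_equal(s1$labels_cam1, s2$labels_cam1)
  expect_equal(s1$labels_cam2, s2$labels_cam2)
  # a missed truth observation is absent from both cameras
  k1 <- paste(s1$labels_cam1$frame_index, s1$labels_cam1$truth_id)
  k2 <- paste(s1$labels_cam2$frame_index, s1$labels_cam2$truth_id)
  expect_setequal(k1[!is.na(s1$labels_cam1$truth_id)],
                  k2[!is.na(s1$labels_cam2$truth_id)])
  # p_miss = 1 empties the true-detection stream
  s3 <- project_scene(truth, cams$cam1, cams$cam2,
                      scene_config(n_insects = 2, duration = 2, p_miss = 1,
                                   rng_seed = 31), appearance = "none")
  expect_equal(nrow(s3$labels_cam1), 0L)
})

test_that("spurious detection counts follow the Poisson expectation", {
  cams <- ref_cams
  sc <- scene_config(n_insects = 0, duration = 1000 / 30, fp_rate = 2,
                     rng_seed = 37)
  truth <- simulate_trajectories(sc)
  scene <- project_scene(truth, cams$cam1, cams$cam2, sc, appearance = "none")
  n_fp <- nrow(scene$labels_cam1)
  expect_lt(abs(n_fp - 2000), 3 * sqrt(2000))
})

test_that("rendered colours separate insects more than frames separate one insect", {
  cams <- toy_cameras()
  sc <- scene_config(n_insects = 2, duration = 2, rng_seed = 43,
                     step_scale = 0.2)
  truth <- simulate_trajectories(sc)
  scene <- project_scene(truth, cams$cam1, cams$cam2, sc, appearance = "none")
  frames <- render_frames(scene, camera = 1, frames_to_render = 0:1,
                          stem_width = 0)
  lab <- scene$labels_cam1
  cfg <- feature_config()
  h <- function(f, id) {
    d <- lab[lab$frame_index == f & lab$truth_id == id, ]
    box_histogram(frames[[f + 1]], d, cfg)
  }
  same <- hist_difference(h(0, 1), h(1, 1))
  cross <- hist_difference(h(0, 1), h(0, 2))
  expect_lt(same, cross)
  expect_lt(same, 0.3)
  expect_gt(cross, 0.3)
  # painted ellipse count equals detection count
  img <- frames[[1]]
  found <- detect_blobs(img, threshold = 0.8, min_area = 5)
  expect_equal(nrow(found), sum(lab$frame_index == 0))
  # empty scene renders the plain background
  empty_truth <- simulate_trajectories(scene_config(n_insects = 0,
                                                    duration = 1 / 30))
  es <- project_scene(empty_truth, cams$cam1, cams$cam2,
                      scene_config(n_insects = 0, duration = 1 / 30),
                      appearance = "none")
  bg <- render_frames(es, camera = 1, stem_width = 0)[[1]]
  expect_true(all(bg == 0.85))
})

test_that("tracking metrics agree with a hand-coded matcher on a small scene", {
  truth <- make_tracks(
    list(frames = 0:9, x = rep(0, 10), y = rep(0, 10), z = rep(10, 10)),
    list(frames = 0:9, x = rep(5, 10), y = rep(5, 10), z = rep(60, 10)))
  # estimate: track 1 exact; track 2 offset by 0.2 mm and split in two
  est <- track_set(dplyr::bind_rows(
    tibble::tibble(track_id = 1L, frame_index = 0:9, x = 0, y = 0, z = 10),
    tibble::tibble(track_id = 2L, frame_index = 0:4, x = 5.2, y = 5, z = 60),
    tibble::tibble(track_id = 3L, frame_index = 5:9, x = 5.2, y = 5, z = 60)))
  ev <- evaluate_tracking(truth, est, match_radius = 1)
  expect_equal(ev$completeness, 1)
  expect_equal(ev$identity_switches, 1L) # one split = one switch
  expect_equal(ev$spurious_tracks, 0L)
  # hand-computed RMSE: half the matches at 0, half at 0.2
  expect_equal(ev$rmse, sqrt(mean(c(rep(0, 10), rep(0.2^2, 10)))))
  # self-comparison is perfect
  self <- evaluate_tracking(truth, truth)
  expect_equal(self$completeness, 1)
  expect_equal(self$identity_switches, 0L)
  expect_equal(self$rmse, 0)
  # an estimate far from every truth point is spurious
  bogus <- track_set(tibble::tibble(track_id = 9L, frame_index = 0:9,
                                    x = 20, y = 20, z = 140))
  ev2 <- evaluate_tracking(truth, bogus)
  expect_equal(ev2$completeness, 0)
  expect_equal(ev2$spurious_tracks, 1L)
})

test_that("pipeline position error grows with pixel noise", {
  cams <- ref_cams
  rmse_at <- function(sd) {
    sc <- scene_config(n_insects = 3, duration = 5, pixel_noise_sd = sd,
                       rng_seed = 53)
    truth <- simulate_trajectories(sc)
    scene <- project_scene(truth, cams$cam1, cams$cam2, sc,
                           appearance = "none")
    ts <- track_video(scene$labels_cam1, scene$labels_cam2,
                      cams$cam1, cams$cam2, n_frames = truth$frame_count)
    evaluate_tracking(truth, ts)$rmse
  }
  r <- vapply(c(0, 0.5, 1, 2), rmse_at, 0)
  expect_true(all(diff(r) > 0))
})
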