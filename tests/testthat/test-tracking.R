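cfg_default <- tracker_config()

test_that("cross-camera pairing matches exhaustive minimum-cost assignment", {
  cams <- ref_cams
  set.seed(55)
  for (rep in 1:10) {
    # three insects at distinct, well-separated heights
    z <- sort(runif(3, 5, 140)); z <- z + c(0, 8, 16)
    pts <- tibble::tibble(x = runif(3, -10, 10), y = runif(3, -10, 10), z = z)
    px <- world_to_pixels(pts, cams$cam1, cams$cam2)
    perm <- sample(3)
    d1 <- tibble::tibble(x_center = px$x1, y_center = px$y1)
    d2 <- tibble::tibble(x_center = px$x2[perm], y_center = px$y2[perm])
    got <- match_cameras(d1, d2, cams$cam1, cams$cam2, cfg_default)
    z1 <- (cams$cam1$origin[2] - d1$y_center) * cams$cam1$vertical_ratio
    z2 <- (cams$cam2$origin[2] - d2$y_center) * cams$cam2$vertical_ratio
    cost <- abs(outer(z1, z2, "-"))
    oracle <- brute_force_assignment(cost, gate = cfg_default$z_pair_tolerance)
    expect_equal(as.matrix(got$pairs[order(got$pairs$i1), c("i1", "i2")]),
                 oracle, ignore_attr = TRUE)
    # the recovered pairing undoes the permutation
    expect_equal(got$pairs$i2[order(got$pairs$i1)], order(perm))
  }
})

test_that("detections seen by only one camera stay unpaired", {
  cams <- ref_cams
  d1 <- tibble::tibble(x_center = c(700, 800), y_center = c(1200, 400))
  d2 <- tibble::tibble(x_center = 710, y_center = 1210)
  got <- match_cameras(d1, d2, cams$cam1, cams$cam2, cfg_default)
  expect_equal(nrow(got$pairs), 1L)
  expect_equal(got$unmatched1, 2L)
  expect_length(got$unmatched2, 0L)
  # heights disagreeing beyond tolerance are never paired
  far <- match_cameras(tibble::tibble(x_center = 700, y_center = 1200),
                       tibble::tibble(x_center = 700, y_center = 600),
                       cams$cam1, cams$cam2, cfg_default)
  expect_equal(nrow(far$pairs), 0L)
})

test_that("frame association gates by distance and histogram", {
  act <- tibble::tibble(track_id = 1L, x = 0, y = 0, z = 10)
  # candidate within gate -> matched
  near <- tibble::tibble(x = 0.3, y = 0.4, z = 10)
  r <- associate_frame(act, near, cfg_default)
  expect_equal(r$matches$track_id, 1L)
  expect_equal(r$matches$distance, 0.5)
  # candidate 2.5 mm away with a 2 mm gate -> new track opens
  far <- tibble::tibble(x = 2.5, y = 0, z = 10)
  r2 <- associate_frame(act, far, cfg_default)
  expect_equal(nrow(r2$matches), 0L)
  expect_equal(r2$new_candidates, 1L)
  expect_equal(r2$lost_tracks, 1L)
  # appearance veto: near in space, different colour
  red <- solid_hist(c(1, 0, 0)); blue <- solid_hist(c(0, 0, 1))
  act_h <- dplyr::mutate(act, hist = list(red))
  cand_h <- dplyr::mutate(near, hist = list(blue))
  r3 <- associate_frame(act_h, cand_h, cfg_default)
  expect_equal(nrow(r3$matches), 0L)
  # same colour passes
  cand_h2 <- dplyr::mutate(near, hist = list(red))
  expect_equal(nrow(associate_frame(act_h, cand_h2, cfg_default)$matches), 1L)
})

test_that("greedy association equals exhaustive matching on separated cases", {
  set.seed(77)
  for (rep in 1:10) {
    act <- tibble::tibble(track_id = 1:3,
                          x = runif(3, -10, 10), y = runif(3, -10, 10),
                          z = c(10, 60, 110))
    # candidates near their own tracks, in shuffled order
    perm <- sample(3)
    cand <- tibble::tibble(x = act$x[perm] + runif(3, -0.3, 0.3),
                           y = act$y[perm] + runif(3, -0.3, 0.3),
                           z = act$z[perm] + runif(3, -0.3, 0.3))
    r <- associate_frame(act, cand, cfg_default)
    cost <- sqrt(outer(act$x, cand$x, "-")^2 + outer(act$y, cand$y, "-")^2 +
                 outer(act$z, cand$z, "-")^2)
    oracle <- brute_force_assignment(cost, gate = cfg_default$threshold_distance)
    got <- cbind(match(r$matches$track_id, act$track_id), r$matches$candidate)
    expect_equal(got[order(got[, 1]), , drop = FALSE], oracle,
                 ignore_attr = TRUE)
  }
})

test_that("association is invariant to detection order within a frame", {
  cams <- ref_cams
  set.seed(88)
  pts <- tibble::tibble(x = c(-5, 0, 5), y = c(0, 5, -5), z = c(20, 70, 120))
  px <- world_to_pixels(pts, cams$cam1, cams$cam2)
  lab <- function(ord1, ord2) {
    l1 <- tibble::tibble(frame_index = rep(0:1, each = 3),
                         x_center = rep(round(px$x1[ord1]), 2),
                         y_center = rep(round(px$y1[ord1]), 2),
                         width = 12, height = 17)
    l2 <- tibble::tibble(frame_index = rep(0:1, each = 3),
                         x_center = rep(round(px$x2[ord2]), 2),
                         y_center = rep(round(px$y2[ord2]), 2),
                         width = 12, height = 17)
    track_video(l1, l2, cams$cam1, cams$cam2,
                tracker_config(min_track_frames = 1), n_frames = 2L)
  }
  base <- tidy(lab(1:3, 1:3))
  for (i in 1:3) {
    o1 <- sample(3); o2 <- sample(3)
    other <- tidy(lab(o1, o2))
    # same set of 3D positions per frame regardless of file ordering
    key <- function(d) dplyr::arrange(d[c("frame_index", "x", "y", "z")],
                                      frame_index, x, y, z)
    expect_equal(key(other), key(base))
  }
})

test_that("temporally overlapping fragments are never merged", {
  red <- solid_hist(c(0.8, 0.1, 0.1))
  obs <- dplyr::bind_rows(
    tibble::tibble(track_id = 1L, frame_index = 0:29, x = 0, y = 0, z = 10),
    tibble::tibble(track_id = 2L, frame_index = 20:49, x = 5, y = 5, z = 60))
  ts <- track_set(obs, appearance = list(
    `1` = list(first = red, last = red),
    `2` = list(first = red, last = red)))
  for (ord in c("chronological", "appearance")) {
    merged <- reidentify_tracks(ts, tracker_config(reid_order = ord))
    expect_equal(sort(unique(merged$observations$track_id)), c(1L, 2L))
  }
  # single fragment is returned unchanged
  single <- track_set(obs[obs$track_id == 1L, ],
                      appearance = list(`1` = list(first = red, last = red)))
  expect_equal(tidy(reidentify_tracks(single, cfg_default)), tidy(single))
})

test_that("the smallest-dissimilarity gap pair merges first (greedy order)", {
  # three fragments; the (1 -> 3) gap pair has strictly the smallest
  # dissimilarity, and fragment 2 overlaps fragment 1 so the only valid
  # merges are 1->3 and 2->3
  h_a <- solid_hist(c(0.9, 0.2, 0.2))
  h_b <- solid_hist(c(0.2, 0.2, 0.9))
  h_c <- solid_hist(c(0.85, 0.25, 0.2)) # close to a, far from b
  obs <- dplyr::bind_rows(
    tibble::tibble(track_id = 1L, frame_index = 0:9, x = 0, y = 0, z = 10),
    tibble::tibble(track_id = 2L, frame_index = 5:14, x = 5, y = 5, z = 60),
    tibble::tibble(track_id = 3L, frame_index = 20:29, x = 0, y = 0, z = 10))
  app <- list(`1` = list(first = h_a, last = h_a),
              `2` = list(first = h_b, last = h_b),
              `3` = list(first = h_c, last = h_c))
  d13 <- hist_difference(h_a, h_c)
  d23 <- hist_difference(h_b, h_c)
  expect_lt(d13, d23) # construction: 1->3 strictly smallest
  # exhaustive oracle over all valid merge sequences: the reachable final
  # states are {1+3, 2}, {1, 2+3} or no merge; minimal total dissimilarity
  # is achieved by merging 1->3
  for (ord in c("chronological", "appearance")) {
    merged <- reidentify_tracks(track_set(obs, appearance = app),
                                tracker_config(reid_order = ord,
                                               threshold_his = 0.9))
    got <- sort(unique(merged$observations$track_id))
    expect_equal(got, c(1L, 2L))
    expect_equal(sort(merged$observations$frame_index[
      merged$observations$track_id == 1L]), c(0:9, 20:29))
  }
})

test_that("pruning removes short tracks inclusively and idempotently", {
  obs <- dplyr::bind_rows(
    tibble::tibble(track_id = 1L, frame_index = 0:0, x = 0, y = 0, z = 0),
    tibble::tibble(track_id = 2L, frame_index = 0:13, x = 1, y = 0, z = 0),
    tibble::tibble(track_id = 3L, frame_index = 0:14, x = 2, y = 0, z = 0))
  ts <- track_set(obs)
  pruned <- prune_false_tracks(ts, cfg_default)
  expect_equal(unique(pruned$observations$track_id), 3L) # 15 obs kept
  again <- prune_false_tracks(pruned, cfg_default)
  expect_equal(tidy(again), tidy(pruned))
})

test_that("noiseless multi-insect scenes are recovered exactly", {
  cams <- ref_cams
  sc <- scene_config(n_insects = 3, duration = 5, rng_seed = 13)
  truth <- simulate_trajectories(sc)
  scene <- project_scene(truth, cams$cam1, cams$cam2, sc)
  ts <- track_video(scene$labels_cam1, scene$labels_cam2,
                    cams$cam1, cams$cam2, n_frames = truth$frame_count)
  ev <- evaluate_tracking(truth, ts)
  expect_equal(ev$n_est_tracks, 3L)
  expect_equal(ev$identity_switches, 0L)
  expect_equal(ev$completeness, 1)
  max_ratio <- max(cams$cam1$horizontal_ratio, cams$cam1$vertical_ratio,
                   cams$cam2$horizontal_ratio, cams$cam2$vertical_ratio)
  expect_lte(ev$rmse, 0.5 * max_ratio)
  # association never links observations farther than the gate in one step
  steps <- tidy(ts) |>
    dplyr::group_by(track_id) |>
    dplyr::reframe(gap = diff(frame_index),
                   step = sqrt(diff(x)^2 + diff(y)^2 + diff(z)^2))
  expect_true(all(steps$step[steps$gap == 1] < 2))
})

test_that("an occluded insect is re-identified into a single merged track", {
  cams <- ref_cams
  sc <- scene_config(n_insects = 2, duration = 8, rng_seed = 17,
                     occlusions = tibble::tibble(track_id = 1L,
                                                 start = 90L, end = 149L))
  truth <- simulate_trajectories(sc)
  scene <- project_scene(truth, cams$cam1, cams$cam2, sc)
  ts <- track_video(scene$labels_cam1, scene$labels_cam2,
                    cams$cam1, cams$cam2, n_frames = truth$frame_count)
  obs <- tidy(ts)
  expect_equal(length(unique(obs$track_id)), 2L)
  ev <- evaluate_tracking(truth, ts)
  expect_equal(ev$identity_switches, 0L)
  # exactly one track carries the gap, left empty rather than interpolated
  has_gap <- tapply(obs$frame_index, obs$track_id,
                    function(f) !any(f %in% 90:149) && min(f) < 90 &&
                                max(f) > 149)
  expect_equal(sum(has_gap), 1L)
})

test_that("empty streams give an empty track set", {
  cams <- ref_cams
  empty <- tibble::tibble(frame_index = integer(), x_center = double(),
                          y_center = double(), width = double(),
                          height = double())
  ts <- track_video(empty, empty, cams$cam1, cams$cam2, n_frames = 10L)
  expect_s3_class(ts, "track_set")
  expect_equal(nrow(ts$observations), 0L)
  expect_error(track_video(empty, empty, cams$cam1, cams$cam2,
                           frames1 = list(matrix(1, 2, 2)), frames2 = list()),
               "Synchronization")
})
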