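#' Tracker configuration
#'
#' @param threshold_distance Association gate in mm: the maximum 3D
#'   displacement allowed between consecutive-frame observations of one
#'   insect (2 mm at 30 fps — insects cannot move far in 1/30 s).
#' @param threshold_his Maximum histogram-intersection dissimilarity for two
#'   observations to count as the same insect.
#' @param min_track_frames Tracks observed in fewer frames are discarded as
#'   background noise (false-track pruning); 15 frames is 0.5 s at 30 fps.
#' @param z_pair_tolerance Cross-camera pairing gate in mm: both cameras
#'   observe the shared vertical coordinate, so a true detection pair must
#'   agree on z to within this tolerance.
#' @param fps Video frame rate in frames per second.
#' @param z_policy How the two per-camera z estimates are fused; see
#'   [pixels_to_world()].
#' @param max_gap Maximum frame gap bridged by re-identification
#'   (default unlimited: a lost insect stays eligible for the whole video).
#' @param reid_order Order in which fragment merges are considered during
#'   re-identification; see [reidentify_tracks()].
#' @return An object of class `tracker_config`.
#' @export
tracker_config <- function(threshold_distance = 2, threshold_his = 0.3,
                           min_track_frames = 15, z_pair_tolerance = 2,
                           fps = 30, z_policy = "mean", max_gap = Inf,
                           reid_order = c("chronological", "appearance")) {
  stopifnot(threshold_distance > 0, threshold_his > 0, min_track_frames > 0,
            z_pair_tolerance > 0, fps > 0, max_gap > 0)
  z_policy <- match.arg(z_policy, z_policies)
  reid_order <- match.arg(reid_order)
  structure(list(threshold_distance = threshold_distance,
                 threshold_his = threshold_his,
                 min_track_frames = as.integer(min_track_frames),
                 z_pair_tolerance = z_pair_tolerance,
                 fps = fps, z_policy = z_policy, max_gap = max_gap,
                 reid_order = reid_order),
            class = "tracker_config")
}

# Greedy one-to-one assignment on a cost matrix: repeatedly take the
# cheapest unused (row, col) with cost <= gate; exact ties break by lower
# row, then column. Returns a 2-column index matrix.
greedy_assign <- function(cost, gate) {
  n1 <- nrow(cost); n2 <- ncol(cost)
  out <- matrix(0L, min(n1, n2), 2)
  taken <- 0L
  ord <- order(cost, row(cost), col(cost))
  used1 <- logical(n1); used2 <- logical(n2)
  ri <- (ord - 1L) %% n1 + 1L
  ci <- (ord - 1L) %/% n1 + 1L
  for (k in seq_along(ord)) {
    if (cost[ord[k]] > gate) break
    i <- ri[k]; j <- ci[k]
    if (used1[i] || used2[j]) next
    used1[i] <- TRUE; used2[j] <- TRUE
    taken <- taken + 1L
    out[taken, ] <- c(i, j)
  }
  out[seq_len(taken), , drop = FALSE]
}

#' Pair detections across the two cameras by vertical agreement
#'
#' The vertical world coordinate z is the only coordinate observed by both
#' cameras, so `|z1 - z2|` is the natural pairing cost. Pairs are formed
#' greedily by ascending cost; a pair whose cost exceeds `z_pair_tolerance`
#' is rejected, and each detection is used at most once. Detections visible
#' in only one camera remain unpaired and yield no 3D point.
#'
#' @param dets1,dets2 Detection tibbles for one frame, cameras 1 and 2.
#' @param cam1,cam2 [camera_config()] objects.
#' @param cfg A [tracker_config()].
#' @return A list with `pairs` (tibble of row indices `i1`, `i2` into
#'   `dets1`/`dets2` plus the z disagreement `dz`), and integer vectors
#'   `unmatched1`, `unmatched2`.
#' @export
match_cameras <- function(dets1, dets2, cam1, cam2, cfg = tracker_config()) {
  n1 <- nrow(dets1); n2 <- nrow(dets2)
  if (n1 == 0 || n2 == 0) {
    return(list(pairs = tibble::tibble(i1 = integer(), i2 = integer(),
                                       dz = double()),
                unmatched1 = seq_len(n1), unmatched2 = seq_len(n2)))
  }
  z1 <- (cam1$origin[2] - dets1$y_center) * cam1$vertical_ratio
  z2 <- (cam2$origin[2] - dets2$y_center) * cam2$vertical_ratio
  cost <- abs(outer(z1, z2, "-"))
  m <- greedy_assign(cost, cfg$z_pair_tolerance)
  list(pairs = tibble::tibble(i1 = m[, 1], i2 = m[, 2], dz = cost[m]),
       unmatched1 = setdiff(seq_len(n1), m[, 1]),
       unmatched2 = setdiff(seq_len(n2), m[, 2]))
}

# Core of associate_frame on plain vectors; hists may be NULL or lists.
associate_core <- function(ax, ay, az, ahist, cx, cy, cz, chist, cfg) {
  nt <- length(ax); nc <- length(cx)
  if (nt == 0 || nc == 0) {
    return(list(pairs = matrix(0L, 0, 2), dist = double()))
  }
  dist <- sqrt(outer(ax, cx, "-")^2 + outer(ay, cy, "-")^2 +
               outer(az, cz, "-")^2)
  if (!is.null(ahist) && !is.null(chist)) {
    # appearance gate: treat an incompatible pair as unassignable
    for (i in seq_len(nt)) {
      hi <- ahist[[i]]
      if (is.null(hi)) next
      for (j in seq_len(nc)) {
        hj <- chist[[j]]
        if (is.null(hj)) next
        if (dist[i, j] < cfg$threshold_distance &&
            hist_difference(hi, hj) >= cfg$threshold_his) {
          dist[i, j] <- Inf
        }
      }
    }
  }
  m <- greedy_assign(dist, gate = cfg$threshold_distance * (1 - 1e-12))
  list(pairs = m, dist = dist[m])
}

#' Associate active tracks with next-frame candidates
#'
#' For each active track the nearest candidate by 3D Euclidean distance is
#' sought; a match is accepted only if the distance is below
#' `threshold_distance` and (when appearance is available) the histogram
#' dissimilarity is below `threshold_his`. A per-track nearest-neighbour rule
#' can assign one candidate to two tracks, so conflicts are resolved greedily
#' by ascending distance with each candidate consumable once; exact ties
#' break deterministically by track order, then candidate index. Unmatched
#' candidates open new tracks; unmatched tracks become lost.
#'
#' @param active Tibble of track states with columns `track_id`, `x`, `y`,
#'   `z` (last observed position) and optionally a `hist` list-column.
#' @param candidates Tibble with `x`, `y`, `z` and optionally `hist`.
#' @param cfg A [tracker_config()].
#' @return A list with `matches` (tibble `track_id`, `candidate`, `distance`),
#'   `new_candidates` (indices of unmatched candidates) and `lost_tracks`
#'   (ids of unmatched tracks).
#' @export
associate_frame <- function(active, candidates, cfg = tracker_config()) {
  res <- associate_core(active$x, active$y, active$z,
                        if ("hist" %in% names(active)) active$hist else NULL,
                        candidates$x, candidates$y, candidates$z,
                        if ("hist" %in% names(candidates)) candidates$hist
                        else NULL,
                        cfg)
  m <- res$pairs
  list(matches = tibble::tibble(track_id = active$track_id[m[, 1]],
                                candidate = m[, 2], distance = res$dist),
       new_candidates = setdiff(seq_len(nrow(candidates)), m[, 2]),
       lost_tracks = active$track_id[setdiff(seq_len(nrow(active)), m[, 1])])
}

new_track_set <- function(observations, frame_count, appearance = list()) {
  structure(list(observations = observations,
                 frame_count = as.integer(frame_count),
                 appearance = appearance),
            class = "track_set")
}

#' Construct a track set from an observation table
#'
#' @param observations Tibble with columns `track_id`, `frame_index`, `x`,
#'   `y`, `z` (mm); frame indices must be unique within a track.
#' @param frame_count Total number of frames in the video (`numF`); defaults
#'   to `max(frame_index) + 1`.
#' @param appearance Optional named list (by track id) of
#'   `list(first =, last =)` appearance histograms used by
#'   [reidentify_tracks()].
#' @return An object of class `track_set`.
#' @export
track_set <- function(observations, frame_count = NULL, appearance = list()) {
  observations <- tibble::as_tibble(observations)
  stopifnot(all(c("track_id", "frame_index", "x", "y", "z") %in%
                names(observations)))
  split_f <- split(observations$frame_index, observations$track_id)
  if (any(vapply(split_f, anyDuplicated, 0L) > 0)) {
    stop("A track has two observations in the same frame.", call. = FALSE)
  }
  observations <- dplyr::arrange(observations, .data$track_id, .data$frame_index)
  if (is.null(frame_count)) {
    frame_count <- if (nrow(observations)) max(observations$frame_index) + 1L else 0L
  }
  new_track_set(observations, frame_count, appearance)
}

#' @export
print.track_set <- function(x, ...) {
  n <- length(unique(x$observations$track_id))
  cat(sprintf("<track_set> %d track(s), %d observation(s), %d frame(s)\n",
              n, nrow(x$observations), x$frame_count))
  invisible(x)
}

track_spans <- function(ts) {
  ts$observations |>
    dplyr::group_by(.data$track_id) |>
    dplyr::summarise(start = min(.data$frame_index),
                     end = max(.data$frame_index),
                     n_obs = dplyr::n(), .groups = "drop")
}

#' Merge track fragments by appearance (greedy re-identification)
#'
#' Detector failures (occlusion, blur) fragment one insect into several
#' track fragments separated by gaps. A merge joins a lost fragment with a
#' later-starting fragment whose first-appearance histogram best matches the
#' lost fragment's last-appearance histogram, subject to three rules: the
#' dissimilarity must be below `threshold_his`; the gap must be within
#' `max_gap` frames; and the fragments must not overlap in time — two
#' fragments that coexist in any frame are by construction two distinct
#' insects. Frames inside the bridged gap are left empty (the greedy skip).
#' Fragments without appearance histograms are never merged.
#'
#' Two merge orders are available. `"chronological"` (the default) sweeps
#' fragments in order of their starting frame and attaches each to the
#' eligible lost fragment with the smallest dissimilarity — the online
#' best-match rule, which keeps one chain per insect when several fragments
#' of the same insect have near-identical appearance. `"appearance"`
#' repeatedly merges the globally smallest-dissimilarity eligible pair; it
#' favours appearance evidence over temporal adjacency, but under
#' appearance noise near-ties can interleave two chains through one
#' insect's fragments.
#'
#' @param ts A [track_set()] whose `appearance` entries hold first/last
#'   histograms per fragment.
#' @param cfg A [tracker_config()].
#' @return A [track_set()] with merged fragments concatenated under the
#'   earlier fragment's `track_id`.
#' @export
reidentify_tracks <- function(ts, cfg = tracker_config()) {
  stopifnot(inherits(ts, "track_set"))
  frag <- track_spans(ts)
  n <- nrow(frag)
  if (n < 2 || length(ts$appearance) == 0) return(ts)
  app <- ts$appearance
  obs <- ts$observations
  ids <- frag$track_id
  has_hist <- vapply(as.character(ids), function(i) {
    !is.null(app[[i]]) && !is.null(app[[i]]$first) && !is.null(app[[i]]$last)
  }, TRUE)
  # D[a, b]: dissimilarity of a's last appearance vs b's first appearance
  D <- matrix(Inf, n, n)
  for (a in which(has_hist)) for (b in which(has_hist)) {
    if (a != b) D[a, b] <- hist_difference(app[[as.character(ids[a])]]$last,
                                           app[[as.character(ids[b])]]$first)
  }
  start <- frag$start; end <- frag$end
  alive <- rep(TRUE, n)

  do_merge <- function(a, b) {
    keep <- ids[a]; absorb <- ids[b]
    obs$track_id[obs$track_id == absorb] <<- keep
    app[[as.character(keep)]]$last <<- app[[as.character(absorb)]]$last
    app[[as.character(absorb)]] <<- NULL
    end[a] <<- end[b]
    D[a, ] <<- D[b, ]  # merged chain's outgoing appearance is absorb's
    alive[b] <<- FALSE
    D[b, ] <<- Inf; D[, b] <<- Inf
  }

  if (cfg$reid_order == "chronological") {
    for (b in order(start, ids)) {
      elig <- which(alive & end < start[b] & start[b] - end <= cfg$max_gap)
      elig <- elig[elig != b & D[elig, b] < cfg$threshold_his]
      if (!alive[b] || length(elig) == 0) next
      a <- elig[which.min(D[elig, b])]
      # b's observations join a's chain; the chain keeps slot a
      do_merge(a, b)
    }
  } else {
    repeat {
      valid <- outer(end, start, function(e, s) s > e & s - e <= cfg$max_gap) &
        outer(alive, alive, "&")
      cand <- D < cfg$threshold_his & valid
      if (!any(cand)) break
      k <- which(cand)[which.min(D[cand])]
      a <- (k - 1) %% n + 1; b <- (k - 1) %/% n + 1
      do_merge(a, b)
    }
  }
  obs <- dplyr::arrange(obs, .data$track_id, .data$frame_index)
  new_track_set(obs, ts$frame_count, app)
}

#' Remove short-lived tracks as detection noise
#'
#' Background clutter occasionally produces consistent detections for a few
#' frames; a real insect is visible much longer. Tracks with fewer than
#' `min_track_frames` observations (counted after re-identification) are
#' removed; the boundary is inclusive — a track with exactly
#' `min_track_frames` observations is kept. Idempotent.
#'
#' @param ts A [track_set()].
#' @param cfg A [tracker_config()].
#' @return The pruned [track_set()].
#' @export
prune_false_tracks <- function(ts, cfg = tracker_config()) {
  stopifnot(inherits(ts, "track_set"))
  counts <- table(ts$observations$track_id)
  keep <- as.integer(names(counts)[counts >= cfg$min_track_frames])
  obs <- dplyr::filter(ts$observations, .data$track_id %in% keep)
  app <- ts$appearance[as.character(keep)]
  app <- app[!vapply(app, is.null, TRUE)]
  new_track_set(obs, ts$frame_count, app)
}

#' Track insects in 3D through a dual-camera video
#'
#' The full pipeline, frame by frame: pair detections across cameras by
#' vertical agreement ([match_cameras()]), triangulate each pair to a 3D
#' world point (the [pixels_to_world()] mapping), and associate points with
#' active tracks by nearest-neighbour gating ([associate_frame()]). After
#' the last frame, fragments are merged by appearance
#' ([reidentify_tracks()]) and short noise tracks are dropped
#' ([prune_false_tracks()]). Deterministic given inputs and configuration;
#' no randomness anywhere.
#'
#' Appearance histograms are taken from rendered/real frames when `frames1`
#' and `frames2` are supplied, or from a precomputed `hist` list-column in
#' the label tables (as attached by the simulator); with neither,
#' association is by distance only and no re-identification merging occurs.
#'
#' @param labels_cam1,labels_cam2 Detection tibbles over all frames (columns
#'   `frame_index`, `x_center`, `y_center`, `width`, `height`, optional
#'   `hist` list-column).
#' @param cam1,cam2 [camera_config()] objects.
#' @param cfg A [tracker_config()].
#' @param frames1,frames2 Optional lists of frame rasters (index `f + 1`
#'   holds frame `f`) from which box histograms are computed.
#' @param feature_cfg A [feature_config()] for frame-derived histograms.
#' @param n_frames Total frame count; defaults to one past the largest frame
#'   index seen in either label stream.
#' @return A [track_set()].
#' @export
track_video <- function(labels_cam1, labels_cam2, cam1, cam2,
                        cfg = tracker_config(),
                        frames1 = NULL, frames2 = NULL,
                        feature_cfg = feature_config(), n_frames = NULL) {
  if (xor(is.null(frames1), is.null(frames2))) {
    stop("Synchronization error: frames must be supplied for both cameras or neither.",
         call. = FALSE)
  }
  if (!is.null(frames1) && length(frames1) != length(frames2)) {
    stop("Synchronization error: camera frame streams have different lengths.",
         call. = FALSE)
  }
  if (is.null(n_frames)) {
    n_frames <- max(c(labels_cam1$frame_index, labels_cam2$frame_index, -1L)) + 1L
  }
  use_frames <- !is.null(frames1)
  use_label_hist <- !use_frames && "hist" %in% names(labels_cam1) &&
    "hist" %in% names(labels_cam2)

  # flatten label streams to plain vectors once; tibbles are too slow to
  # slice 30 times a second
  flat <- function(lab) {
    list(f = as.integer(lab$frame_index), xc = lab$x_center,
         yc = lab$y_center, w = lab$width, h = lab$height,
         hist = if ("hist" %in% names(lab)) lab$hist else NULL,
         by_frame = split(seq_len(nrow(lab)), lab$frame_index))
  }
  L1 <- flat(labels_cam1); L2 <- flat(labels_cam2)
  z1_all <- (cam1$origin[2] - L1$yc) * cam1$vertical_ratio
  z2_all <- (cam2$origin[2] - L2$yc) * cam2$vertical_ratio
  x_all <- (L1$xc - cam1$origin[1]) * cam1$horizontal_ratio
  y_all <- (cam2$origin[1] - L2$xc) * cam2$horizontal_ratio

  trk_frames <- list(); trk_x <- list(); trk_y <- list(); trk_z <- list()
  trk_first_hist <- list(); trk_last_hist <- list()
  last_x <- double(); last_y <- double(); last_z <- double()
  active_ids <- integer()
  next_id <- 1L

  for (f in seq_len(n_frames) - 1L) {
    key <- as.character(f)
    i1 <- L1$by_frame[[key]] %||% integer()
    i2 <- L2$by_frame[[key]] %||% integer()
    # cross-camera pairing on the shared z coordinate
    if (length(i1) && length(i2)) {
      cost <- abs(outer(z1_all[i1], z2_all[i2], "-"))
      mp <- greedy_assign(cost, cfg$z_pair_tolerance)
    } else {
      mp <- matrix(0L, 0, 2)
    }
    np <- nrow(mp)
    if (np) {
      p1 <- i1[mp[, 1]]; p2 <- i2[mp[, 2]]
      cx <- x_all[p1]; cy <- y_all[p2]
      cz <- switch(cfg$z_policy,
                   mean = (z1_all[p1] + z2_all[p2]) / 2,
                   cam1 = z1_all[p1], cam2 = z2_all[p2])
      chist <- if (use_frames) {
        img1 <- frames1[[f + 1L]]; img2 <- frames2[[f + 1L]]
        lapply(seq_len(np), function(i) {
          combine_hists(
            box_histogram(img1, list(x_center = L1$xc[p1[i]],
                                     y_center = L1$yc[p1[i]],
                                     width = L1$w[p1[i]],
                                     height = L1$h[p1[i]]), feature_cfg),
            box_histogram(img2, list(x_center = L2$xc[p2[i]],
                                     y_center = L2$yc[p2[i]],
                                     width = L2$w[p2[i]],
                                     height = L2$h[p2[i]]), feature_cfg))
        })
      } else if (use_label_hist) {
        lapply(seq_len(np), function(i) {
          combine_hists(L1$hist[[p1[i]]], L2$hist[[p2[i]]])
        })
      } else {
        NULL
      }
    } else {
      cx <- cy <- cz <- double(); chist <- NULL
    }

    if (length(active_ids) && np) {
      ahist <- if (!is.null(chist)) trk_last_hist[active_ids] else NULL
      res <- associate_core(last_x[active_ids], last_y[active_ids],
                            last_z[active_ids], ahist, cx, cy, cz, chist, cfg)
      m <- res$pairs
    } else {
      m <- matrix(0L, 0, 2)
    }
    matched_c <- m[, 2]
    for (r in seq_len(nrow(m))) {
      id <- active_ids[m[r, 1]]; ci <- m[r, 2]
      trk_frames[[id]] <- c(trk_frames[[id]], f)
      trk_x[[id]] <- c(trk_x[[id]], cx[ci])
      trk_y[[id]] <- c(trk_y[[id]], cy[ci])
      trk_z[[id]] <- c(trk_z[[id]], cz[ci])
      last_x[id] <- cx[ci]; last_y[id] <- cy[ci]; last_z[id] <- cz[ci]
      if (!is.null(chist) && !is.null(chist[[ci]])) {
        trk_last_hist[[id]] <- chist[[ci]]
      }
    }
    new_c <- setdiff(seq_len(np), matched_c)
    for (ci in new_c) {
      id <- next_id
      trk_frames[[id]] <- f
      trk_x[[id]] <- cx[ci]; trk_y[[id]] <- cy[ci]; trk_z[[id]] <- cz[ci]
      last_x[id] <- cx[ci]; last_y[id] <- cy[ci]; last_z[id] <- cz[ci]
      h <- if (!is.null(chist)) chist[[ci]] else NULL
      trk_first_hist[id] <- list(h)
      trk_last_hist[id] <- list(h)
      next_id <- next_id + 1L
    }
    active_ids <- c(active_ids[m[, 1]],
                    seq.int(next_id - length(new_c), length.out = length(new_c)))
  }

  n_tracks <- next_id - 1L
  if (n_tracks == 0L) {
    return(new_track_set(tibble::tibble(track_id = integer(),
                                        frame_index = integer(),
                                        x = double(), y = double(), z = double()),
                         n_frames))
  }
  obs <- tibble::tibble(
    track_id = rep(seq_len(n_tracks),
                   vapply(trk_frames[seq_len(n_tracks)], length, 0L)),
    frame_index = as.integer(unlist(trk_frames)),
    x = unlist(trk_x), y = unlist(trk_y), z = unlist(trk_z))
  app <- stats::setNames(
    lapply(seq_len(n_tracks), function(id) {
      list(first = if (id <= length(trk_first_hist)) trk_first_hist[[id]]
                   else NULL,
           last = if (id <= length(trk_last_hist)) trk_last_hist[[id]]
                  else NULL)
    }),
    as.character(seq_len(n_tracks)))
  app <- app[!vapply(app, function(a) is.null(a$first), TRUE)]
  ts <- new_track_set(dplyr::arrange(obs, .data$track_id, .data$frame_index),
                      n_frames, app)
  ts <- reidentify_tracks(ts, cfg)
  prune_false_tracks(ts, cfg)
}

#' Concatenate the two per-camera histograms of one detection pair
#'
#' The combined vector treats each camera's channels as extra channels, so
#' [hist_difference()] averages the intersection over both views.
#'
#' @param h1,h2 Histograms from [box_histogram()].
#' @return A combined histogram vector.
#' @export
combine_hists <- function(h1, h2) {
  if (is.null(h1) || is.null(h2)) return(NULL)
  structure(c(as.numeric(h1), as.numeric(h2)),
            channels = (attr(h1, "channels") %||% 1) +
                       (attr(h2, "channels") %||% 1),
            bins_per_channel = attr(h1, "bins_per_channel"))
}
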