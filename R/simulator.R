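#' Scene configuration for the synthetic dual-camera rig
#'
#' Emulates the physical bench: a vertical plant in a 28 mm pot, two
#' orthogonal cameras 200 mm from the pot centre at 86 mm height, filming at
#' 30 fps. Insects move by a waypoint walk (piecewise-linear paths with
#' bounded per-frame step) confined to a box of `±pot_width` mm around the
#' plant axis and heights 0-150 mm; each insect keeps to its own height band
#' on the plant, as insects settled on distinct leaves do. Projection is
#' orthographic by construction — the ratio calibration model has no
#' perspective term.
#'
#' @param n_insects Number of insects (0-10).
#' @param duration Scene length in seconds.
#' @param fps Frame rate (frames/s).
#' @param pot_width Planting-pot width in mm.
#' @param camera_distance,camera_height Camera placement in mm (recorded for
#'   provenance; orthographic projection does not use them).
#' @param motion `"waypoint_walk"` or `"stationary"`.
#' @param step_scale Maximum per-frame displacement in mm (default 0.01
#'   mm/frame = 0.3 mm/s at 30 fps, the pace of a slowly crawling hopper).
#' @param pixel_noise_sd Gaussian noise added to each projected pixel
#'   coordinate, in pixels.
#' @param p_miss Probability that a truth observation is missed by the
#'   detector (dropped from both cameras: misses stem from the insect's
#'   pose/blur, a cause shared by the views).
#' @param fp_rate Expected spurious detections per frame per camera
#'   (Poisson).
#' @param occlusions Optional tibble `track_id`, `start`, `end` (frame
#'   indices, inclusive): the track's detections are dropped in both cameras
#'   inside each window.
#' @param box_size Mean projected bounding-box size `(w, h)` in pixels.
#' @param box_jitter Relative box-size jitter (uniform, +/- this fraction).
#' @param rng_seed Integer seed; every random draw in the simulator derives
#'   from it through per-concern substreams, so toggling one noise source
#'   does not shift the others.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(n_insects = 3, duration = 60, fps = 30,
                         pot_width = 28, camera_distance = 200,
                         camera_height = 86,
                         motion = c("waypoint_walk", "stationary"),
                         step_scale = 0.01, pixel_noise_sd = 0,
                         p_miss = 0, fp_rate = 0, occlusions = NULL,
                         box_size = c(12, 17), box_jitter = 0.2,
                         rng_seed = 1L) {
  motion <- match.arg(motion)
  stopifnot(n_insects >= 0, duration > 0, fps > 0,
            p_miss >= 0, p_miss <= 1, fp_rate >= 0, pixel_noise_sd >= 0)
  structure(list(n_insects = as.integer(n_insects), duration = duration,
                 fps = fps, pot_width = pot_width,
                 camera_distance = camera_distance,
                 camera_height = camera_height, motion = motion,
                 step_scale = step_scale, pixel_noise_sd = pixel_noise_sd,
                 p_miss = p_miss, fp_rate = fp_rate, occlusions = occlusions,
                 box_size = box_size, box_jitter = box_jitter,
                 z_range = c(0, 150),
                 rng_seed = as.integer(rng_seed)),
            class = "scene_config")
}

with_stream <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate ground-truth 3D insect trajectories
#'
#' Deterministic given `cfg$rng_seed`. Each insect is assigned a private
#' height band (equal split of the 0-150 mm plant height, 15% edge margin,
#' so insects in different bands never come closer vertically than 30% of
#' the band height) and walks between uniformly drawn waypoints inside its
#' band at a per-frame step never exceeding `step_scale`. The stationary
#' model holds every insect at its starting position.
#'
#' @param cfg A [scene_config()].
#' @return A [track_set()] of ground-truth observations.
#' @export
simulate_trajectories <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  n_frames <- as.integer(round(cfg$duration * cfg$fps))
  n <- cfg$n_insects
  if (n == 0) {
    return(track_set(tibble::tibble(track_id = integer(), frame_index = integer(),
                                    x = double(), y = double(), z = double()),
                     frame_count = n_frames))
  }
  zr <- cfg$z_range
  band_h <- (zr[2] - zr[1]) / n
  margin <- 0.15 * band_h
  half <- cfg$pot_width
  obs <- with_stream(cfg$rng_seed + 1L, {
    out <- vector("list", n)
    for (k in seq_len(n)) {
      zlo <- zr[1] + (k - 1) * band_h + margin
      zhi <- zr[1] + k * band_h - margin
      draw_wp <- function() c(stats::runif(1, -half, half),
                              stats::runif(1, -half, half),
                              stats::runif(1, zlo, zhi))
      pos <- draw_wp()
      pts <- matrix(0, n_frames, 3)
      pts[1, ] <- pos
      if (cfg$motion == "stationary") {
        for (f in 2:max(2, n_frames)) if (f <= n_frames) pts[f, ] <- pos
      } else {
        wp <- draw_wp()
        speed <- stats::runif(1, 0.3, 1) * cfg$step_scale
        for (f in seq_len(n_frames - 1)) {
          d <- wp - pos
          len <- sqrt(sum(d^2))
          if (len < speed) {
            pos <- wp
            wp <- draw_wp()
            speed <- stats::runif(1, 0.3, 1) * cfg$step_scale
          } else {
            pos <- pos + d / len * speed
          }
          pts[f + 1, ] <- pos
        }
      }
      out[[k]] <- tibble::tibble(track_id = k,
                                 frame_index = seq_len(n_frames) - 1L,
                                 x = pts[, 1], y = pts[, 2], z = pts[, 3])
    }
    dplyr::bind_rows(out)
  })
  track_set(obs, frame_count = n_frames)
}

insect_palette <- function(n) {
  cols <- grDevices::hcl.colors(max(3L, n), "Dark 3")[seq_len(n)]
  lapply(cols, function(cc) as.numeric(grDevices::col2rgb(cc)) / 255)
}

render_patch <- function(w, h, color, background = 0.85) {
  w <- max(2L, as.integer(round(w))); h <- max(2L, as.integer(round(h)))
  img <- array(background, c(h, w, 3))
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  xs <- matrix(seq_len(w), h, w, byrow = TRUE)
  ys <- matrix(seq_len(h), h, w)
  mask <- ((xs - cx) / (w / 2))^2 + ((ys - cy) / (h / 2))^2 <= 1
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- color[ch]
    img[, , ch] <- plane
  }
  img
}

#' Project a ground-truth scene into noisy dual-camera detection streams
#'
#' Each truth point is projected orthographically into both cameras with
#' [world_to_pixels()]; independent Gaussian pixel noise is added, centres
#' are rounded to whole pixels (as in integer label files), bounding boxes
#' take the observed mean size with uniform jitter, whole truth observations
#' are missed with probability `p_miss`, occlusion windows drop the listed
#' track in both cameras, and Poisson-distributed spurious boxes appear
#' uniformly in each frame. Every surviving detection carries an appearance
#' histogram computed with [box_histogram()] from a rendered patch of the
#' insect's base colour, so appearance-based association and
#' re-identification run exactly as they would on real frames.
#' Deterministic given `cfg$rng_seed`, with one RNG substream per concern.
#'
#' @param truth A [track_set()] from [simulate_trajectories()].
#' @param cam1,cam2 [camera_config()] objects.
#' @param cfg A [scene_config()].
#' @param appearance `"histogram"` (default) attaches per-detection
#'   appearance histograms; `"none"` omits them.
#' @param feature_cfg [feature_config()] used for appearance histograms.
#' @return An object of class `sim_scene`: list with `truth`,
#'   `labels_cam1`, `labels_cam2` (detection tibbles with a `hist`
#'   list-column and a `truth_id` provenance column ignored by the tracker),
#'   `colors` (per-insect base RGB), `cams`, and `config`.
#' @export
project_scene <- function(truth, cam1, cam2, cfg,
                          appearance = c("histogram", "none"),
                          feature_cfg = feature_config()) {
  appearance <- match.arg(appearance)
  stopifnot(inherits(truth, "track_set"), inherits(cfg, "scene_config"))
  obs <- truth$observations
  n_frames <- truth$frame_count
  px <- world_to_pixels(obs, cam1, cam2)
  m <- nrow(obs)
  colors <- insect_palette(max(c(obs$track_id, 1L)))

  # substreams: +2 boxes, +3 pixel noise, +4 misses, +5 false positives
  jit <- with_stream(cfg$rng_seed + 2L,
                     matrix(stats::runif(4 * m, 1 - cfg$box_jitter,
                                         1 + cfg$box_jitter), m, 4))
  noise <- with_stream(cfg$rng_seed + 3L,
                       matrix(stats::rnorm(4 * m, 0, cfg$pixel_noise_sd), m, 4))
  missed <- with_stream(cfg$rng_seed + 4L, stats::runif(m) < cfg$p_miss)

  occluded <- rep(FALSE, m)
  if (!is.null(cfg$occlusions) && nrow(cfg$occlusions)) {
    for (r in seq_len(nrow(cfg$occlusions))) {
      o <- cfg$occlusions[r, ]
      occluded <- occluded | (obs$track_id == o$track_id &
                              obs$frame_index >= o$start &
                              obs$frame_index <= o$end)
    }
  }
  keep <- !missed & !occluded

  # box sizes are whole pixels and colours per-insect, so histograms repeat;
  # cache by (w, h, colour)
  hist_cache <- new.env(parent = emptyenv())
  base_hist <- function(w, h, color) {
    key <- paste(w, h, paste(round(color, 4), collapse = ","), sep = "|")
    got <- hist_cache[[key]]
    if (!is.null(got)) return(got)
    patch <- render_patch(w, h, color)
    out <- box_histogram(patch, list(x_center = (w + 1) / 2,
                                     y_center = (h + 1) / 2,
                                     width = w, height = h), feature_cfg)
    hist_cache[[key]] <- out
    out
  }

  make_labels <- function(cam_id, xc, yc, wj, hj) {
    w <- pmax(2, round(cfg$box_size[1] * wj))
    h <- pmax(2, round(cfg$box_size[2] * hj))
    nx <- noise[, if (cam_id == 1L) 1 else 3]
    ny <- noise[, if (cam_id == 1L) 2 else 4]
    lab <- tibble::tibble(
      camera_id = cam_id, frame_index = obs$frame_index[keep],
      class_label = 0L,
      x_center = round(xc + nx)[keep],
      y_center = round(yc + ny)[keep],
      width = w[keep], height = h[keep], confidence = 1,
      truth_id = obs$track_id[keep])
    if (appearance == "histogram") {
      lab$hist <- lapply(seq_len(nrow(lab)), function(i) {
        base_hist(lab$width[i], lab$height[i], colors[[lab$truth_id[i]]])
      })
    }
    lab
  }
  lab1 <- make_labels(1L, px$x1, px$y1, jit[, 1], jit[, 2])
  lab2 <- make_labels(2L, px$x2, px$y2, jit[, 3], jit[, 4])

  # spurious detections, uniform over each camera's raster
  fp <- with_stream(cfg$rng_seed + 5L, {
    lapply(list(cam1, cam2), function(cam) {
      size <- if (!is.null(cam$roi)) cam$roi$resize_to else c(1400, 1700)
      counts <- stats::rpois(n_frames, cfg$fp_rate)
      tot <- sum(counts)
      if (tot == 0) return(NULL)
      fpt <- tibble::tibble(
        camera_id = cam$camera_id,
        frame_index = rep(seq_len(n_frames) - 1L, counts),
        class_label = 0L,
        x_center = round(stats::runif(tot, 1, size[1])),
        y_center = round(stats::runif(tot, 1, size[2])),
        width = pmax(2, round(cfg$box_size[1] *
                                stats::runif(tot, 1 - cfg$box_jitter,
                                             1 + cfg$box_jitter))),
        height = pmax(2, round(cfg$box_size[2] *
                                 stats::runif(tot, 1 - cfg$box_jitter,
                                              1 + cfg$box_jitter))),
        confidence = 1, truth_id = NA_integer_)
      if (appearance == "histogram") {
        grays <- stats::runif(tot, 0.2, 0.7)
        fpt$hist <- lapply(seq_len(tot), function(i) {
          base_hist(fpt$width[i], fpt$height[i], rep(grays[i], 3))
        })
      }
      fpt
    })
  })
  if (!is.null(fp[[1]])) lab1 <- dplyr::bind_rows(lab1, fp[[1]])
  if (!is.null(fp[[2]])) lab2 <- dplyr::bind_rows(lab2, fp[[2]])
  lab1 <- dplyr::arrange(lab1, .data$frame_index)
  lab2 <- dplyr::arrange(lab2, .data$frame_index)

  structure(list(truth = truth, labels_cam1 = lab1, labels_cam2 = lab2,
                 colors = colors[seq_len(max(c(obs$track_id, 0L)))],
                 cams = list(cam1 = cam1, cam2 = cam2), config = cfg),
            class = "sim_scene")
}

#' @export
print.sim_scene <- function(x, ...) {
  cat(sprintf(
    "<sim_scene> %d insect(s), %d frame(s), %d + %d detections (cam1 + cam2)\n",
    x$config$n_insects, x$truth$frame_count,
    nrow(x$labels_cam1), nrow(x$labels_cam2)))
  invisible(x)
}

#' Render simulated camera frames
#'
#' Paints each true detection of one camera as a filled ellipse in its
#' insect's base colour on a light background with a darker vertical stem
#' stripe through the camera origin. Intended for exercising the histogram
#' and blob-detection paths; keep the ROI raster small when rendering long
#' scenes.
#'
#' @param scene A `sim_scene` from [project_scene()].
#' @param camera 1 or 2.
#' @param frames_to_render Integer frame indices (default: all).
#' @param background Background intensity.
#' @param stem_width Width of the stem stripe in pixels (0 disables).
#' @return A named list of `height x width x 3` arrays, element `f + 1`
#'   holding frame `f` (unrendered frames are `NULL`).
#' @export
render_frames <- function(scene, camera = 1,
                          frames_to_render = NULL, background = 0.85,
                          stem_width = 4) {
  stopifnot(inherits(scene, "sim_scene"))
  cam <- if (camera == 1) scene$cams$cam1 else scene$cams$cam2
  labels <- if (camera == 1) scene$labels_cam1 else scene$labels_cam2
  size <- if (!is.null(cam$roi)) cam$roi$resize_to else c(1400, 1700)
  w <- size[1]; h <- size[2]
  n_frames <- scene$truth$frame_count
  if (is.null(frames_to_render)) frames_to_render <- seq_len(n_frames) - 1L
  base <- array(background, c(h, w, 3))
  if (stem_width > 0) {
    cols <- pmax(1, pmin(w, round(cam$origin[1] + seq(-stem_width / 2,
                                                      stem_width / 2))))
    base[, unique(cols), ] <- 0.55
  }
  out <- vector("list", n_frames)
  by_f <- split(seq_len(nrow(labels)), labels$frame_index)
  for (f in frames_to_render) {
    img <- base
    for (i in by_f[[as.character(f)]] %||% integer()) {
      d <- labels[i, ]
      col <- if (!is.na(d$truth_id)) scene$colors[[d$truth_id]] else rep(0.4, 3)
      x0 <- max(1, round(d$x_center - d$width / 2))
      x1 <- min(w, round(d$x_center + d$width / 2))
      y0 <- max(1, round(d$y_center - d$height / 2))
      y1 <- min(h, round(d$y_center + d$height / 2))
      if (x0 > x1 || y0 > y1) next
      xs <- matrix(x0:x1, y1 - y0 + 1, x1 - x0 + 1, byrow = TRUE)
      ys <- matrix(y0:y1, y1 - y0 + 1, x1 - x0 + 1)
      mask <- ((xs - d$x_center) / (d$width / 2))^2 +
              ((ys - d$y_center) / (d$height / 2))^2 <= 1
      for (ch in 1:3) {
        plane <- img[y0:y1, x0:x1, ch]
        plane[mask] <- col[ch]
        img[y0:y1, x0:x1, ch] <- plane
      }
    }
    out[[f + 1L]] <- img
  }
  out
}
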