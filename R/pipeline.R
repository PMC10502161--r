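#' Read a pipeline configuration file
#'
#' YAML with per-stage sections. All physical constants (camera origins,
#' landmark measurements, thresholds) live in the config, never in code.
#' A camera block gives `origin`, optional `roi`
#' (`crop_top_left`, `crop_bottom_right`, `resize_to`) and either explicit
#' `horizontal_ratio`/`vertical_ratio` (mm/px) or `horizontal`/`vertical`
#' landmark blocks (`length_mm`, `pixel_a`, `pixel_b`) from which ratios are
#' computed with [compute_ratio()]. Optional `tracker`, `features`, `scene`
#' and `detect` sections map onto [tracker_config()], [feature_config()],
#' [scene_config()] and [detect_blobs()] arguments.
#'
#' @param path YAML configuration file.
#' @return A list with `cam1`, `cam2`, `tracker`, `features`, `scene_args`,
#'   `detect_args` and the raw parsed YAML in `raw`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("Config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  known <- c("calibration", "tracker", "features", "scene", "detect")
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("Invalid config key(s): ", paste(bad, collapse = ", "),
         " (known sections: ", paste(known, collapse = ", "), ").",
         call. = FALSE)
  }
  build_cam <- function(id, cc) {
    if (is.null(cc)) stop("Config is missing calibration for camera ", id,
                          call. = FALSE)
    roi <- if (!is.null(cc$roi)) {
      roi_spec(unlist(cc$roi$crop_top_left), unlist(cc$roi$crop_bottom_right),
               unlist(cc$roi$resize_to))
    } else NULL
    ratio_from <- function(block, explicit) {
      if (!is.null(explicit)) return(explicit)
      if (is.null(block)) stop("Camera ", id, " config needs a ratio or a ",
                               "landmark block.", call. = FALSE)
      compute_ratio(block$length_mm, block$pixel_a, block$pixel_b)
    }
    camera_config(id, unlist(cc$origin),
                  horizontal_ratio = ratio_from(cc$horizontal,
                                                cc$horizontal_ratio),
                  vertical_ratio = ratio_from(cc$vertical, cc$vertical_ratio),
                  roi = roi)
  }
  tracker <- do.call(tracker_config, raw$tracker %||% list())
  features <- do.call(feature_config, raw$features %||% list())
  list(cam1 = build_cam(1L, raw$calibration$cam1),
       cam2 = build_cam(2L, raw$calibration$cam2),
       tracker = tracker, features = features,
       scene_args = raw$scene %||% list(),
       detect_args = raw$detect %||% list(),
       raw = raw)
}

write_manifest <- function(out_dir, config_path, seed, stages, inputs) {
  digest_of <- function(p) unname(tools::md5sum(p))
  manifest <- list(
    tool = "insect3d",
    version = as.character(utils::packageVersion("insect3d")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    rng_seed = seed,
    stages = stages,
    config = list(path = normalizePath(config_path),
                  md5 = digest_of(config_path),
                  snapshot = yaml::read_yaml(config_path)),
    inputs = lapply(inputs, function(p) {
      if (file.exists(p) && !dir.exists(p)) list(path = p, md5 = digest_of(p))
      else list(path = p)
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the monitoring pipeline end to end
#'
#' Executes the requested stages in dependency order —
#' `calibrate`, `simulate` or `detect`, `track`, `stats`, `viz` — against a
#' single YAML configuration, writing all artifacts plus a reproducibility
#' manifest (`run_manifest.json`: config snapshot and digest, package
#' version, seed, timestamps) under `out_dir`. Deterministic for a fixed
#' config and seed.
#'
#' Stage artifacts: `calibration.json` (the four mm/px ratios);
#' `labels_cam1/`, `labels_cam2/`, `truth.csv` (simulate);
#' `labels_cam1/`, `labels_cam2/` from frame images (detect);
#' `tracks.csv`, `tracks.ply` (track); `motion_stats.csv`,
#' `speed_profile.csv` (stats); `tracks.png` (viz).
#'
#' @param config_path YAML configuration file (see [read_config()]).
#' @param stages Character vector of stages to run.
#' @param out_dir Output directory, created if missing.
#' @param seed Integer seed controlling all simulator randomness.
#' @param frames_dir1,frames_dir2 Directories of PNG frames (detect stage).
#' @param verbose Emit per-stage progress messages.
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config_path,
                         stages = c("simulate", "track", "stats", "viz"),
                         out_dir = "insect3d_out", seed = 1L,
                         frames_dir1 = NULL, frames_dir2 = NULL,
                         verbose = TRUE) {
  order_all <- c("calibrate", "simulate", "detect", "track", "stats", "viz")
  bad <- setdiff(stages, order_all)
  if (length(bad)) stop("Unknown stage(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  stages <- order_all[order_all %in% stages]
  cfg <- read_config(config_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))
  artifacts <- list()
  image_size <- if (!is.null(cfg$cam1$roi)) cfg$cam1$roi$resize_to
                else c(1400, 1700)

  for (stage in stages) {
    say("[%s] starting", stage)
    if (stage == "calibrate") {
      ratios <- list(xratio = cfg$cam1$horizontal_ratio,
                     zratio1 = cfg$cam1$vertical_ratio,
                     yratio = cfg$cam2$horizontal_ratio,
                     zratio2 = cfg$cam2$vertical_ratio)
      f <- file.path(out_dir, "calibration.json")
      jsonlite::write_json(ratios, f, auto_unbox = TRUE, digits = NA)
      say("  XRATIO=%.3f ZRATIO1=%.3f YRATIO=%.4f ZRATIO2=%.4f",
          ratios$xratio, ratios$zratio1, ratios$yratio, ratios$zratio2)
      artifacts$calibration <- f
    } else if (stage == "simulate") {
      sc <- do.call(scene_config, c(cfg$scene_args, list(rng_seed = seed)))
      truth <- simulate_trajectories(sc)
      scene <- project_scene(truth, cfg$cam1, cfg$cam2, sc,
                             appearance = "none")
      d1 <- file.path(out_dir, "labels_cam1")
      d2 <- file.path(out_dir, "labels_cam2")
      fr <- seq_len(truth$frame_count) - 1L
      write_label_dir(scene$labels_cam1, d1, image_size, frame_range = fr)
      write_label_dir(scene$labels_cam2, d2, image_size, frame_range = fr)
      ft <- file.path(out_dir, "truth.csv")
      export_point_cloud(truth, ft, "xyz_csv")
      say("  %d insects over %d frames; %d + %d detections",
          sc$n_insects, truth$frame_count,
          nrow(scene$labels_cam1), nrow(scene$labels_cam2))
      artifacts$labels1 <- d1; artifacts$labels2 <- d2; artifacts$truth <- ft
    } else if (stage == "detect") {
      if (is.null(frames_dir1) || is.null(frames_dir2)) {
        stop("Stage 'detect' needs frames_dir1 and frames_dir2.", call. = FALSE)
      }
      for (cam_i in 1:2) {
        fdir <- if (cam_i == 1) frames_dir1 else frames_dir2
        if (!dir.exists(fdir)) stop("Missing input: ", fdir, call. = FALSE)
        files <- sort(list.files(fdir, pattern = "\\.png$", full.names = TRUE))
        ddir <- file.path(out_dir, sprintf("labels_cam%d", cam_i))
        dir.create(ddir, recursive = TRUE, showWarnings = FALSE)
        for (k in seq_along(files)) {
          img <- png::readPNG(files[k])
          dets <- do.call(detect_blobs,
                          c(list(image = img, frame_index = k - 1L,
                                 camera_id = cam_i), cfg$detect_args))
          write_label_file(dets, file.path(ddir,
                                           sprintf("frame_%06d.txt", k - 1L)),
                           image_size)
        }
        say("  camera %d: %d frames processed", cam_i, length(files))
        artifacts[[sprintf("labels%d", cam_i)]] <- ddir
      }
    } else if (stage == "track") {
      d1 <- artifacts$labels1 %||% file.path(out_dir, "labels_cam1")
      d2 <- artifacts$labels2 %||% file.path(out_dir, "labels_cam2")
      if (!dir.exists(d1) || !dir.exists(d2)) {
        stop("Stage 'track' needs label directories; missing ",
             if (!dir.exists(d1)) d1 else d2,
             " (run 'simulate' or 'detect' first).", call. = FALSE)
      }
      l1 <- read_label_dir(d1, image_size, camera_id = 1L)
      l2 <- read_label_dir(d2, image_size, camera_id = 2L)
      load_frames <- function(fdir) {
        if (is.null(fdir)) return(NULL)
        files <- sort(list.files(fdir, pattern = "\\.png$", full.names = TRUE))
        lapply(files, png::readPNG)
      }
      fr1 <- load_frames(frames_dir1); fr2 <- load_frames(frames_dir2)
      ts <- track_video(l1, l2, cfg$cam1, cfg$cam2, cfg$tracker,
                        frames1 = fr1, frames2 = fr2,
                        feature_cfg = cfg$features)
      fcsv <- file.path(out_dir, "tracks.csv")
      fply <- file.path(out_dir, "tracks.ply")
      export_point_cloud(ts, fcsv, "xyz_csv")
      export_point_cloud(ts, fply, "ply_ascii")
      say("  %d track(s), %d observation(s)",
          length(unique(ts$observations$track_id)), nrow(ts$observations))
      artifacts$tracks <- fcsv; artifacts$tracks_ply <- fply
    } else if (stage == "stats") {
      fcsv <- artifacts$tracks %||% file.path(out_dir, "tracks.csv")
      if (!file.exists(fcsv)) {
        stop("Stage 'stats' needs ", fcsv, " (run 'track' first).",
             call. = FALSE)
      }
      ts <- read_point_cloud_csv(fcsv)
      window <- cfg$raw$tracker$window %||% 60
      st <- motion_stats(ts, window = window, fps = cfg$tracker$fps)
      prof <- tidyr::unnest(dplyr::select(st, "track_id", "profile"),
                            "profile")
      fstat <- file.path(out_dir, "motion_stats.csv")
      fprof <- file.path(out_dir, "speed_profile.csv")
      utils::write.csv(dplyr::select(st, -"profile"), fstat, row.names = FALSE)
      utils::write.csv(prof, fprof, row.names = FALSE)
      say("  total distance per track: %s mm",
          paste(sprintf("%.2f", st$total_distance), collapse = ", "))
      artifacts$stats <- fstat; artifacts$profile <- fprof
    } else if (stage == "viz") {
      fcsv <- artifacts$tracks %||% file.path(out_dir, "tracks.csv")
      if (!file.exists(fcsv)) {
        stop("Stage 'viz' needs ", fcsv, " (run 'track' first).",
             call. = FALSE)
      }
      ts <- read_point_cloud_csv(fcsv)
      fpng <- file.path(out_dir, "tracks.png")
      plot_tracks(ts, fpng, mode = "per_identity")
      artifacts$figure <- fpng
    }
    say("[%s] done", stage)
  }
  write_manifest(out_dir, config_path, seed, stages,
                 inputs = unlist(artifacts, use.names = FALSE))
  invisible(artifacts)
}
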