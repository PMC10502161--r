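#' Total distance travelled by one track
#'
#' Sum over consecutive observation pairs of the 3D Euclidean norm of the
#' position difference. For merged tracks with occlusion gaps the straight
#' line across the gap is counted once, a lower bound on the true path.
#'
#' @param track Tibble of one track's observations with columns
#'   `frame_index`, `x`, `y`, `z`, ordered by frame.
#' @return Total travelled distance in mm.
#' @export
total_distance <- function(track) {
  if (nrow(track) == 0) stop("Empty track has no travelled distance.",
                             call. = FALSE)
  track <- dplyr::arrange(track, .data$frame_index)
  if (nrow(track) == 1) return(0)
  sum(sqrt(diff(track$x)^2 + diff(track$y)^2 + diff(track$z)^2))
}

#' Windowed speed profile of one track
#'
#' Partitions the video into consecutive fixed-length windows
#' (`window * fps` frames, counted from frame 0) and reports the distance
#' travelled inside each window. A movement segment between frames `f` and
#' `f'` is assigned to the window containing `f`, so the window distances
#' sum exactly to [total_distance()]. The last window may be partial and is
#' flagged.
#'
#' @param track Tibble of one track's observations (`frame_index`, `x`, `y`,
#'   `z`).
#' @param window Window length in seconds (60 s gives mm-per-minute
#'   profiles).
#' @param fps Frame rate in frames per second.
#' @return A tibble with `window_start` (s), `distance` (mm) and `partial`
#'   (flag on a window not fully covered by the video span of the track).
#' @export
speed_profile <- function(track, window = 60, fps = 30) {
  stopifnot(window > 0, fps > 0)
  track <- dplyr::arrange(track, .data$frame_index)
  wf <- window * fps
  if (nrow(track) == 0) {
    return(tibble::tibble(window_start = double(), distance = double(),
                          partial = logical()))
  }
  last_frame <- max(track$frame_index)
  n_windows <- max(1L, as.integer(floor(last_frame / wf)) + 1L)
  dist <- rep(0, n_windows)
  if (nrow(track) > 1) {
    seg <- sqrt(diff(track$x)^2 + diff(track$y)^2 + diff(track$z)^2)
    win <- floor(track$frame_index[-nrow(track)] / wf) + 1
    for (i in seq_along(seg)) dist[win[i]] <- dist[win[i]] + seg[i]
  }
  tibble::tibble(
    window_start = (seq_len(n_windows) - 1) * window,
    distance = dist,
    partial = (seq_len(n_windows) * wf - 1) > last_frame)
}

#' Movement statistics for every track in a set
#'
#' @param ts A [track_set()] (or its observation tibble).
#' @param window Window length in seconds for the speed profile.
#' @param fps Frame rate in frames per second.
#' @return A tibble with one row per track: `track_id`, `n_obs`,
#'   `first_frame`, `last_frame`, `total_distance` (mm), `net_displacement`
#'   (mm, straight line first to last observation) and a nested `profile`
#'   list-column of [speed_profile()] tibbles.
#' @export
motion_stats <- function(ts, window = 60, fps = 30) {
  obs <- if (inherits(ts, "track_set")) ts$observations else tibble::as_tibble(ts)
  obs <- dplyr::arrange(obs, .data$track_id, .data$frame_index)
  purrr::map_dfr(split(obs, obs$track_id), function(d) {
    n <- nrow(d)
    tibble::tibble(
      track_id = d$track_id[1],
      n_obs = n,
      first_frame = min(d$frame_index),
      last_frame = max(d$frame_index),
      total_distance = total_distance(d),
      net_displacement = sqrt((d$x[n] - d$x[1])^2 + (d$y[n] - d$y[1])^2 +
                              (d$z[n] - d$z[1])^2),
      profile = list(speed_profile(d, window = window, fps = fps)))
  })
}

#' Export a track set as a point cloud
#'
#' One point per observation. ASCII PLY carries a per-track colour
#' (distinct hues per identity); CSV carries `track_id` and `frame_index`
#' columns. Coordinates are written at 6 decimals, so CSV export and
#' re-import are loss-free at that precision.
#'
#' @param ts A [track_set()].
#' @param path Output file.
#' @param format `"xyz_csv"` or `"ply_ascii"`.
#' @return `path`, invisibly.
#' @export
export_point_cloud <- function(ts, path, format = c("xyz_csv", "ply_ascii")) {
  format <- match.arg(format)
  stopifnot(inherits(ts, "track_set"))
  obs <- ts$observations
  ok <- tryCatch({
    if (format == "xyz_csv") {
      out <- data.frame(track_id = obs$track_id, frame_index = obs$frame_index,
                        x_mm = round(obs$x, 6), y_mm = round(obs$y, 6),
                        z_mm = round(obs$z, 6))
      utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    } else {
      ids <- sort(unique(obs$track_id))
      cols <- if (length(ids)) t(grDevices::col2rgb(
        grDevices::hcl.colors(max(3L, length(ids)), "Dark 3")[seq_along(ids)]))
        else matrix(integer(), 0, 3)
      ci <- match(obs$track_id, ids)
      header <- c("ply", "format ascii 1.0",
                  sprintf("element vertex %d", nrow(obs)),
                  "property float x", "property float y", "property float z",
                  "property uchar red", "property uchar green",
                  "property uchar blue", "end_header")
      body <- if (nrow(obs)) sprintf("%.6f %.6f %.6f %d %d %d",
                                     obs$x, obs$y, obs$z,
                                     cols[ci, 1], cols[ci, 2], cols[ci, 3])
              else character()
      writeLines(c(header, body), path)
    }
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("Cannot write point cloud to ", path, call. = FALSE)
  invisible(path)
}

#' Read back a CSV point cloud as a track set
#'
#' @param path A file written by [export_point_cloud()] in `xyz_csv` format.
#' @param frame_count Optional total frame count.
#' @return A [track_set()].
#' @export
read_point_cloud_csv <- function(path, frame_count = NULL) {
  d <- utils::read.csv(path)
  track_set(tibble::tibble(track_id = as.integer(d$track_id),
                           frame_index = as.integer(d$frame_index),
                           x = d$x_mm, y = d$y_mm, z = d$z_mm),
            frame_count = frame_count)
}

#' Write a 3D trajectory figure
#'
#' A 3D scatter/line view of all observations in world coordinates (mm).
#' `per_identity` colours points by track id (the re-identified view);
#' `all_points` draws every observation in a single colour (the raw view).
#'
#' @param ts A [track_set()].
#' @param path Output PNG path.
#' @param mode `"per_identity"` or `"all_points"`.
#' @param width,height Figure size in pixels.
#' @return `path`, invisibly.
#' @export
plot_tracks <- function(ts, path, mode = c("per_identity", "all_points"),
                        width = 800, height = 700) {
  mode <- match.arg(mode)
  stopifnot(inherits(ts, "track_set"))
  obs <- ts$observations
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  if (nrow(obs) == 0) {
    p <- lattice::cloud(z ~ x * y, data = data.frame(x = 0, y = 0, z = 0),
                        col = "transparent", xlab = "x (mm)",
                        ylab = "y (mm)", zlab = "z (mm)")
  } else if (mode == "per_identity") {
    obs$identity <- factor(obs$track_id)
    p <- lattice::cloud(z ~ x * y, data = obs, groups = obs$identity,
                        pch = 16, cex = 0.4,
                        xlab = "x (mm)", ylab = "y (mm)", zlab = "z (mm)",
                        auto.key = list(title = "track", space = "right"))
  } else {
    p <- lattice::cloud(z ~ x * y, data = obs, pch = 16, cex = 0.4,
                        col = "grey25",
                        xlab = "x (mm)", ylab = "y (mm)", zlab = "z (mm)")
  }
  print(p)
  invisible(path)
}
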