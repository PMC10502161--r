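#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a track set into its observation table
#'
#' @param x A [track_set()].
#' @param ... Unused.
#' @return A tibble with one row per observation: `track_id`, `frame_index`,
#'   `x`, `y`, `z` (mm).
#' @method tidy track_set
#' @export
tidy.track_set <- function(x, ...) {
  tibble::as_tibble(x$observations)
}

#' One-row summary of a track set
#'
#' @param x A [track_set()].
#' @param ... Unused.
#' @return A tibble with `n_tracks`, `n_obs`, `frame_count`,
#'   `total_distance` (mm, summed over tracks) and `mean_track_length`
#'   (observations per track).
#' @method glance track_set
#' @export
glance.track_set <- function(x, ...) {
  obs <- x$observations
  n_tracks <- length(unique(obs$track_id))
  td <- if (nrow(obs)) sum(motion_stats(x)$total_distance) else 0
  tibble::tibble(
    n_tracks = n_tracks,
    n_obs = nrow(obs),
    frame_count = x$frame_count,
    total_distance = td,
    mean_track_length = if (n_tracks) nrow(obs) / n_tracks else NA_real_)
}

#' Trajectory projections of a track set
#'
#' Side and front views of the 3D trajectories: the (x, z) plane seen by
#' camera 1 and the (y, z) plane seen by camera 2, coloured by identity.
#' For a genuinely 3D rendering written to file, see [plot_tracks()].
#'
#' @param object A [track_set()].
#' @param mode `"per_identity"` (colour by track) or `"all_points"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot track_set
#' @export
autoplot.track_set <- function(object, mode = c("per_identity", "all_points"),
                               ...) {
  mode <- match.arg(mode)
  obs <- object$observations
  long <- dplyr::bind_rows(
    tibble::tibble(view = "camera 1 view (x-z)", h = obs$x, v = obs$z,
                   track_id = obs$track_id, frame_index = obs$frame_index),
    tibble::tibble(view = "camera 2 view (y-z)", h = obs$y, v = obs$z,
                   track_id = obs$track_id, frame_index = obs$frame_index))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$h, y = .data$v))
  p <- if (mode == "per_identity") {
    p + ggplot2::geom_path(ggplot2::aes(colour = factor(.data$track_id),
                                        group = .data$track_id),
                           linewidth = 0.3) +
      ggplot2::geom_point(ggplot2::aes(colour = factor(.data$track_id)),
                          size = 0.5) +
      ggplot2::labs(colour = "track")
  } else {
    p + ggplot2::geom_point(size = 0.5, colour = "grey25")
  }
  p + ggplot2::facet_wrap(~view, scales = "free_x") +
    ggplot2::labs(x = "horizontal position (mm)", y = "height z (mm)") +
    ggplot2::theme_minimal()
}

#' Speed-over-time plot for all tracks
#'
#' Bar-style profile of distance moved per time window (mm per window),
#' one facet per insect — the windowed view of the total-distance sum.
#'
#' @param ts A [track_set()] or the output of [motion_stats()].
#' @param window Window length in seconds.
#' @param fps Frames per second.
#' @return A ggplot object.
#' @export
plot_speed_profile <- function(ts, window = 60, fps = 30) {
  stats <- if (inherits(ts, "track_set")) motion_stats(ts, window, fps) else ts
  prof <- tidyr::unnest(
    dplyr::select(stats, "track_id", "profile"), "profile")
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$window_start + window / 2,
                                     y = .data$distance)) +
    ggplot2::geom_col(width = window * 0.9, fill = "steelblue") +
    ggplot2::facet_wrap(~track_id, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (s)", y = sprintf("distance per %g s window (mm)",
                                              window)) +
    ggplot2::theme_minimal()
}
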