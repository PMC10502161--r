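#' Compare estimated tracks against ground truth
#'
#' Per frame, truth and estimated observations are matched greedily by
#' ascending 3D distance within `match_radius`. From the matched pairs the
#' usual multi-object-tracking summaries are derived:
#' \describe{
#'   \item{completeness}{fraction of all truth observations recovered by
#'     some estimated observation within `match_radius`;}
#'   \item{identity_switches}{number of times a truth track changes which
#'     estimated track it is matched to (a truth track split across two
#'     estimated tracks counts one switch);}
#'   \item{rmse}{root-mean-square 3D position error in mm over matched
#'     pairs;}
#'   \item{spurious_tracks}{estimated tracks that never match any truth
#'     observation.}
#' }
#'
#' @param truth,estimated [track_set()] objects covering the same frames.
#' @param match_radius Maximum 3D distance (mm) for a truth-estimate match.
#' @return A one-row tibble with `n_truth_tracks`, `n_est_tracks`,
#'   `completeness`, `identity_switches`, `rmse`, `spurious_tracks`,
#'   `n_truth_obs`, `n_matched`.
#' @export
evaluate_tracking <- function(truth, estimated, match_radius = 1) {
  stopifnot(inherits(truth, "track_set"), inherits(estimated, "track_set"))
  tr <- truth$observations
  es <- estimated$observations
  by_t <- split(seq_len(nrow(tr)), tr$frame_index)
  by_e <- split(seq_len(nrow(es)), es$frame_index)
  matched <- list()
  for (f in names(by_t)) {
    ti <- by_t[[f]]; ei <- by_e[[f]]
    if (is.null(ei)) next
    dx <- outer(tr$x[ti], es$x[ei], "-")
    dy <- outer(tr$y[ti], es$y[ei], "-")
    dz <- outer(tr$z[ti], es$z[ei], "-")
    dist <- sqrt(dx^2 + dy^2 + dz^2)
    ord <- order(dist, row(dist), col(dist))
    used_t <- logical(length(ti)); used_e <- logical(length(ei))
    rows <- list()
    for (k in ord) {
      if (dist[k] > match_radius) break
      a <- row(dist)[k]; b <- col(dist)[k]
      if (used_t[a] || used_e[b]) next
      used_t[a] <- TRUE; used_e[b] <- TRUE
      rows[[length(rows) + 1]] <- c(ti[a], ei[b], dist[k])
    }
    if (length(rows)) matched[[f]] <- do.call(rbind, rows)
  }
  mm <- if (length(matched)) do.call(rbind, matched) else matrix(0, 0, 3)
  n_truth_obs <- nrow(tr)
  completeness <- if (n_truth_obs) nrow(mm) / n_truth_obs else 1
  rmse <- if (nrow(mm)) sqrt(mean(mm[, 3]^2)) else 0
  switches <- 0L
  if (nrow(mm)) {
    pairs <- tibble::tibble(frame_index = tr$frame_index[mm[, 1]],
                            truth_id = tr$track_id[mm[, 1]],
                            est_id = es$track_id[mm[, 2]])
    pairs <- dplyr::arrange(pairs, .data$truth_id, .data$frame_index)
    switches <- pairs |>
      dplyr::group_by(.data$truth_id) |>
      dplyr::summarise(s = sum(diff(.data$est_id) != 0), .groups = "drop") |>
      dplyr::pull("s") |> sum() |> as.integer()
  }
  est_ids <- unique(es$track_id)
  matched_est <- if (nrow(mm)) unique(es$track_id[mm[, 2]]) else integer()
  tibble::tibble(
    n_truth_tracks = length(unique(tr$track_id)),
    n_est_tracks = length(est_ids),
    completeness = completeness,
    identity_switches = switches,
    rmse = rmse,
    spurious_tracks = length(setdiff(est_ids, matched_est)),
    n_truth_obs = n_truth_obs,
    n_matched = nrow(mm))
}
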