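# Shared fixtures: cameras, tiny rasters, oracles.

# The bench-calibrated rig (full-size 1400 x 1700 ROI rasters).
ref_cams <- reference_cameras()

# Rounded ratios as used in worked examples.
ref_cams_rounded <- reference_cameras(round_ratios = TRUE)

# A miniature rig with small ROI rasters so frames stay cheap to render.
toy_cameras <- function() {
  roi <- roi_spec(c(0, 0), c(140, 170), c(140, 170))
  list(
    cam1 = camera_config(1, c(70, 160), horizontal_ratio = 0.63,
                         vertical_ratio = 1.0, roi = roi),
    cam2 = camera_config(2, c(72, 158), horizontal_ratio = 0.617,
                         vertical_ratio = 1.05, roi = roi)
  )
}

# One-row detection tibble in pixel units.
det_row <- function(x, y, w = 12, h = 17, frame = 0L) {
  tibble::tibble(camera_id = NA_integer_, frame_index = as.integer(frame),
                 class_label = 0L, x_center = x, y_center = y,
                 width = w, height = h, confidence = 1)
}

# Independent bilinear oracle: per-output-pixel loop with the same
# pixel-centre mapping, no vectorization shared with the implementation.
bilinear_oracle <- function(m, width, height) {
  src_h <- nrow(m); src_w <- ncol(m)
  out <- matrix(0, height, width)
  for (i in seq_len(height)) {
    for (j in seq_len(width)) {
      sy <- min(max((i - 0.5) * src_h / height + 0.5, 1), src_h)
      sx <- min(max((j - 0.5) * src_w / width + 0.5, 1), src_w)
      y0 <- min(floor(sy), src_h - 1); y1 <- y0 + 1
      x0 <- min(floor(sx), src_w - 1); x1 <- x0 + 1
      if (src_h == 1) { y0 <- y1 <- 1; fy <- 0 } else fy <- sy - y0
      if (src_w == 1) { x0 <- x1 <- 1; fx <- 0 } else fx <- sx - x0
      out[i, j] <- m[y0, x0] * (1 - fy) * (1 - fx) +
                   m[y0, x1] * (1 - fy) * fx +
                   m[y1, x0] * fy * (1 - fx) +
                   m[y1, x1] * fy * fx
    }
  }
  out
}

# Exhaustive minimum-total-cost one-to-one assignment for small matrices.
brute_force_assignment <- function(cost, gate = Inf) {
  n1 <- nrow(cost); n2 <- ncol(cost)
  stopifnot(n1 <= 6, n2 <= 6)
  # pad to square with gate-exceeding costs to allow unassigned rows
  best <- NULL; best_cost <- Inf
  cols <- seq_len(n2)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  for (p in perms(cols)) {
    k <- min(n1, n2)
    pairs <- cbind(seq_len(k), p[seq_len(k)])
    ok <- cost[pairs] <= gate
    total <- sum(cost[pairs][ok])
    n_assigned <- sum(ok)
    # maximize assignments first, then minimize total cost
    score <- -n_assigned * 1e9 + total
    if (score < best_cost) {
      best_cost <- score
      best <- pairs[ok, , drop = FALSE]
    }
  }
  best[order(best[, 1]), , drop = FALSE]
}

# Build a track_set directly from per-track coordinate matrices.
make_tracks <- function(...) {
  args <- list(...)
  obs <- dplyr::bind_rows(lapply(seq_along(args), function(i) {
    m <- args[[i]]
    tibble::tibble(track_id = i, frame_index = m$frames,
                   x = m$x, y = m$y, z = m$z)
  }))
  track_set(obs)
}

# Solid-colour histogram fixtures for re-identification tests.
solid_hist <- function(color, cfg = feature_config()) {
  patch <- array(rep(color, each = 20 * 20), c(20, 20, 3))
  box_histogram(patch, list(x_center = 10, y_center = 10,
                            width = 18, height = 18), cfg)
}
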