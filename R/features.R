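#' Appearance-feature configuration
#'
#' Every detected bounding box is resampled to a fixed raster
#' (`hist_w` x `hist_h`, default 40 x 40) before its colour histogram is
#' computed, so histograms of differently sized boxes are comparable.
#' Histograms are per-channel with `bins_per_channel` equal-width intensity
#' bins on `[0, 1]`, concatenated across channels; 16 bins per channel is
#' coarse enough to be robust to motion blur while still separating
#' differently coloured insects.
#'
#' @param hist_w,hist_h Resampled box size in pixels.
#' @param bins_per_channel Number of intensity bins per channel.
#' @param channels 1 (grayscale) or 3 (RGB).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(hist_w = 40, hist_h = 40, bins_per_channel = 16,
                           channels = 3) {
  stopifnot(hist_w >= 1, hist_h >= 1, bins_per_channel >= 1,
            channels %in% c(1, 3))
  structure(list(hist_w = as.integer(hist_w), hist_h = as.integer(hist_h),
                 bins_per_channel = as.integer(bins_per_channel),
                 channels = as.integer(channels)),
            class = "feature_config")
}

#' Normalized colour histogram of a detected bounding box
#'
#' The box is clipped to the image (partial occlusion at the frame edge is
#' expected, so out-of-frame parts are dropped rather than rejected),
#' bilinearly resampled to `cfg$hist_w` x `cfg$hist_h`, and per-channel pixel
#' counts over equal-width intensity bins are normalized by the total pixel
#' count `N = hist_w * hist_h`, so each channel's bins sum to 1.
#'
#' @param image Numeric matrix or height x width x channels array in `[0, 1]`.
#' @param detection One-row detection tibble (or list) with `x_center`,
#'   `y_center`, `width`, `height` in pixel units.
#' @param cfg A [feature_config()].
#' @return A numeric vector of length `channels * bins_per_channel` with
#'   attributes `channels` and `bins_per_channel`.
#' @export
box_histogram <- function(image, detection, cfg = feature_config()) {
  d <- dim(image)
  h <- d[1]; w <- d[2]
  nch <- if (length(d) == 3) d[3] else 1L
  xc <- detection$x_center; yc <- detection$y_center
  bw <- detection$width; bh <- detection$height
  c0 <- max(1, round(xc - bw / 2)); c1 <- min(w, round(xc + bw / 2))
  r0 <- max(1, round(yc - bh / 2)); r1 <- min(h, round(yc + bh / 2))
  if (c0 > c1 || r0 > r1) {
    stop("Bounding box lies fully outside the image: empty crop.", call. = FALSE)
  }
  crop <- if (length(d) == 2) image[r0:r1, c0:c1, drop = FALSE]
          else image[r0:r1, c0:c1, , drop = FALSE]
  patch <- resize_bilinear(crop, width = cfg$hist_w, height = cfg$hist_h)
  patch <- if (length(dim(patch)) == 2) array(patch, c(dim(patch), 1L)) else patch
  use_ch <- min(nch, cfg$channels)
  n_bins <- cfg$bins_per_channel
  N <- cfg$hist_w * cfg$hist_h
  hist_one <- function(vals) {
    idx <- pmin(pmax(floor(vals * n_bins) + 1, 1), n_bins)
    tabulate(idx, nbins = n_bins) / N
  }
  bins <- if (cfg$channels == 1L) {
    lum <- if (nch == 1L) patch[, , 1] else apply(patch[, , seq_len(nch)], c(1, 2), mean)
    hist_one(as.vector(lum))
  } else {
    unlist(lapply(seq_len(cfg$channels), function(ch) {
      hist_one(as.vector(patch[, , min(ch, use_ch)]))
    }))
  }
  structure(bins, channels = cfg$channels, bins_per_channel = n_bins)
}

#' Histogram-intersection dissimilarity between two colour histograms
#'
#' The intersection of two normalized histograms is the sum of per-bin
#' minima — the overlapping area under the two curves. The dissimilarity is
#' 1 minus the mean per-channel intersection, so identical histograms give 0,
#' disjoint histograms give 1, and "difference below threshold" means
#' "similar appearance".
#'
#' @param a,b Histograms from [box_histogram()] (or plain numeric vectors of
#'   equal length whose per-channel blocks each sum to 1).
#' @return A dissimilarity in `[0, 1]`; symmetric in its arguments.
#' @export
hist_difference <- function(a, b) {
  if (length(a) != length(b)) {
    stop("Incompatible features: histograms have different lengths.",
         call. = FALSE)
  }
  n_ch <- attr(a, "channels") %||% attr(b, "channels") %||% 1
  1 - sum(pmin(as.numeric(a), as.numeric(b))) / n_ch
}

`%||%` <- function(x, y) if (is.null(x)) y else x
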