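#' Millimetre-per-pixel calibration ratio from a measured landmark
#'
#' The camera rig is calibrated by measuring a known physical length on the
#' plant or pot (in mm) and locating its two endpoints in the cropped camera
#' image (in pixels). The ratio converts pixel offsets from the camera origin
#' into millimetres in world coordinates.
#'
#' @param world_length Measured physical length in millimetres. Must be > 0.
#' @param pixel_a,pixel_b Pixel coordinates of the two landmark endpoints
#'   along the relevant image axis. Must differ.
#' @return The calibration ratio in mm/pixel: `world_length / |pixel_a - pixel_b|`.
#' @examples
#' compute_ratio(28, 902, 458)     # horizontal ratio of camera 1
#' compute_ratio(63.15, 1345, 756) # vertical ratio of camera 1
#' @export
compute_ratio <- function(world_length, pixel_a, pixel_b) {
  stopifnot(is.numeric(world_length), is.numeric(pixel_a), is.numeric(pixel_b))
  if (any(world_length <= 0)) {
    stop("`world_length` must be positive (degenerate calibration measurement).",
         call. = FALSE)
  }
  span <- abs(pixel_a - pixel_b)
  if (any(span == 0)) {
    stop("Landmark pixels coincide: zero pixel span gives a degenerate calibration.",
         call. = FALSE)
  }
  world_length / span
}

#' Region-of-interest specification
#'
#' Each raw camera frame is cropped to a box around the plant and resized
#' (bilinear) to a fixed raster; all pixel coordinates elsewhere in the
#' package refer to this cropped-and-resized ROI raster.
#'
#' @param crop_top_left,crop_bottom_right Pixel `(x, y)` corners of the crop
#'   box in the raw frame (top-left image origin, x rightward, y downward).
#' @param resize_to Target `(width, height)` of the ROI raster in pixels.
#' @return An object of class `roi_spec`.
#' @examples
#' roi_spec(c(757, 0), c(1457, 850), c(1400, 1700)) # camera-1 ROI
#' @export
roi_spec <- function(crop_top_left, crop_bottom_right, resize_to) {
  stopifnot(length(crop_top_left) == 2, length(crop_bottom_right) == 2,
            length(resize_to) == 2)
  if (any(crop_bottom_right <= crop_top_left)) {
    stop("Crop box is empty: bottom-right corner must exceed top-left corner.",
         call. = FALSE)
  }
  if (any(resize_to <= 0)) stop("`resize_to` must be positive.", call. = FALSE)
  structure(
    list(crop_top_left = as.numeric(crop_top_left),
         crop_bottom_right = as.numeric(crop_bottom_right),
         resize_to = as.numeric(resize_to),
         interpolation = "bilinear"),
    class = "roi_spec"
  )
}

#' Camera configuration: the bridge between image and world coordinates
#'
#' World coordinates are a right-handed millimetre frame with origin at the
#' centre of the planting pot. Camera 1 observes the (x, z) plane and camera 2
#' the (y, z) plane; both share the vertical z axis. Each camera carries the
#' pixel position of the world origin in its ROI raster, one horizontal and
#' one vertical mm/pixel ratio, and the sign of its horizontal axis: camera 1
#' maps `x = (X1 - X01) * horizontal_ratio`, camera 2 maps
#' `y = (X02 - X2) * horizontal_ratio` (sign -1 on the pixel offset).
#'
#' @param camera_id 1 or 2.
#' @param origin Pixel `(X0, Y0)` of the world origin in the ROI raster.
#' @param horizontal_ratio mm/pixel along the image x axis (world x for
#'   camera 1, world y for camera 2).
#' @param vertical_ratio mm/pixel along the image y axis (world z).
#' @param roi Optional [roi_spec()] describing how the ROI raster was derived.
#' @return An object of class `camera_config`.
#' @examples
#' camera_config(1, origin = c(737, 1350),
#'               horizontal_ratio = compute_ratio(28, 902, 458),
#'               vertical_ratio = compute_ratio(63.15, 1345, 756))
#' @export
camera_config <- function(camera_id, origin, horizontal_ratio, vertical_ratio,
                          roi = NULL) {
  stopifnot(camera_id %in% c(1L, 2L), length(origin) == 2)
  if (horizontal_ratio <= 0 || vertical_ratio <= 0) {
    stop("Calibration ratios must be positive.", call. = FALSE)
  }
  if (!is.null(roi)) {
    stopifnot(inherits(roi, "roi_spec"))
    if (origin[1] < 0 || origin[1] > roi$resize_to[1] ||
        origin[2] < 0 || origin[2] > roi$resize_to[2]) {
      stop("Camera origin lies outside the ROI raster.", call. = FALSE)
    }
  }
  structure(
    list(camera_id = as.integer(camera_id),
         origin = as.numeric(origin),
         horizontal_ratio = as.numeric(horizontal_ratio),
         vertical_ratio = as.numeric(vertical_ratio),
         horizontal_sign = if (camera_id == 1L) 1 else -1,
         roi = roi),
    class = "camera_config"
  )
}

#' @export
print.camera_config <- function(x, ...) {
  cat(sprintf(
    "<camera_config %d> origin (%g, %g) px, %s %.4g mm/px, vertical %.4g mm/px\n",
    x$camera_id, x$origin[1], x$origin[2],
    if (x$camera_id == 1L) "horizontal (world x)" else "horizontal (world y)",
    x$horizontal_ratio, x$vertical_ratio))
  invisible(x)
}

#' Camera pair calibrated from the reference rig measurements
#'
#' Builds both camera configurations from the reference bench: cameras 200 mm
#' from the pot centre at 86 mm height, origins (737, 1350) and (722, 1364)
#' in the two ROI rasters, and ratios derived from the measured landmarks
#' (28 mm pot width, 63.15 mm ground-to-first-leaf, 18 mm between the two
#' horizontal pot lines).
#'
#' @param round_ratios If `TRUE`, ratios are rounded to the precision used in
#'   worked examples (3-4 decimals); by default full floating precision is kept
#'   and rounding happens only at report time.
#' @return A list with elements `cam1` and `cam2`, each a [camera_config()].
#' @export
reference_cameras <- function(round_ratios = FALSE) {
  xr <- compute_ratio(28, 902, 458)     # pot width seen by camera 1
  zr1 <- compute_ratio(63.15, 1345, 756) # ground to first leaf, camera 1
  yr <- compute_ratio(28, 973, 519)     # pot width seen by camera 2
  zr2 <- compute_ratio(18, 1644, 1478)  # two horizontal pot lines, camera 2
  if (round_ratios) {
    xr <- round(xr, 3); zr1 <- round(zr1, 3)
    yr <- round(yr, 4); zr2 <- round(zr2, 4)
  }
  roi1 <- roi_spec(c(757, 0), c(1457, 850), c(1400, 1700))
  roi2 <- roi_spec(c(1095, 0), c(2495, 1700), c(1400, 1700))
  list(
    cam1 = camera_config(1, c(737, 1350), xr, zr1, roi = roi1),
    cam2 = camera_config(2, c(722, 1364), yr, zr2, roi = roi2)
  )
}

#' Bilinear crop-and-resize of a frame to its ROI raster
#'
#' Crops `image` to the ROI crop box and resizes the crop to the target
#' raster with bilinear interpolation (pixel-centre alignment).
#'
#' @param image A numeric matrix (grayscale) or `height x width x channels`
#'   array with values in `[0, 1]`.
#' @param roi An [roi_spec()]. The crop box must lie inside the image.
#' @return An array of the ROI target size (height, width\[, channels\]).
#' @export
crop_and_resize <- function(image, roi) {
  stopifnot(inherits(roi, "roi_spec"))
  d <- dim(image)
  h <- d[1]; w <- d[2]
  x0 <- roi$crop_top_left[1]; y0 <- roi$crop_top_left[2]
  x1 <- roi$crop_bottom_right[1]; y1 <- roi$crop_bottom_right[2]
  if (x0 < 0 || y0 < 0 || x1 > w || y1 > h) {
    stop(sprintf("Crop box (%g,%g)-(%g,%g) exceeds image bounds %d x %d.",
                 x0, y0, x1, y1, w, h), call. = FALSE)
  }
  # crop is [y0+1, y1] rows and [x0+1, x1] cols under 0-based corner coords
  rows <- (floor(y0) + 1):ceiling(y1)
  cols <- (floor(x0) + 1):ceiling(x1)
  cropped <- if (length(d) == 2) image[rows, cols, drop = FALSE]
             else image[rows, cols, , drop = FALSE]
  resize_bilinear(cropped, width = roi$resize_to[1], height = roi$resize_to[2])
}

#' Bilinear resampling of a raster to a target size
#'
#' Pixel-centre aligned: output pixel centre `i` maps to source coordinate
#' `(i - 0.5) * src/dst + 0.5`, clamped to the source extent. This is the
#' same mapping used when bounding boxes are resampled for histograms.
#'
#' @param image Numeric matrix or height x width x channels array.
#' @param width,height Target raster size in pixels.
#' @return Resampled array of size `height x width [x channels]`.
#' @export
resize_bilinear <- function(image, width, height) {
  d <- dim(image)
  src_h <- d[1]; src_w <- d[2]
  nch <- if (length(d) == 3) d[3] else 1L
  # source coordinates of the target pixel centres
  sx <- pmin(pmax((seq_len(width) - 0.5) * src_w / width + 0.5, 1), src_w)
  sy <- pmin(pmax((seq_len(height) - 0.5) * src_h / height + 0.5, 1), src_h)
  if (src_w == 1) { x0 <- rep(1, width); fx <- rep(0, width) } else {
    x0 <- pmin(floor(sx), src_w - 1); fx <- sx - x0
  }
  if (src_h == 1) { y0 <- rep(1, height); fy <- rep(0, height) } else {
    y0 <- pmin(floor(sy), src_h - 1); fy <- sy - y0
  }
  x1 <- pmin(x0 + 1L, src_w)
  y1 <- pmin(y0 + 1L, src_h)
  out <- array(0, c(height, width, nch))
  img <- if (nch == 1L) array(image, c(src_h, src_w, 1L)) else image
  wy0 <- 1 - fy; wx0 <- 1 - fx
  for (ch in seq_len(nch)) {
    m <- img[, , ch]
    top <- m[y0, x0, drop = FALSE] * outer(wy0, wx0) +
           m[y0, x1, drop = FALSE] * outer(wy0, fx)
    bot <- m[y1, x0, drop = FALSE] * outer(fy, wx0) +
           m[y1, x1, drop = FALSE] * outer(fy, fx)
    out[, , ch] <- top + bot
  }
  if (length(d) == 2) out[, , 1] else out
}

z_policies <- c("mean", "cam1", "cam2")

#' Convert paired 2D detections to 3D world coordinates
#'
#' Camera 1 observes world (x, z), camera 2 observes world (y, z):
#' `x = (X1 - X01) * XRATIO`, `y = (X02 - X2) * YRATIO`,
#' `z1 = (Y01 - Y1) * ZRATIO1`, `z2 = (Y02 - Y2) * ZRATIO2`.
#' Both cameras observe the shared vertical coordinate, so `z` can be taken
#' from either or averaged; averaging is the default because it halves
#' pixel-quantization variance.
#'
#' @param det1,det2 Data frames of detections from camera 1 and camera 2,
#'   matched row by row (same frame), with columns `x_center`, `y_center`
#'   and (optionally) `frame_index`.
#' @param cam1,cam2 [camera_config()] objects for cameras 1 and 2.
#' @param z_policy One of `"mean"` (default), `"cam1"`, `"cam2"`.
#' @return A tibble with columns `frame_index` (if supplied), `x`, `y`, `z`,
#'   `z_cam1`, `z_cam2`, one row per detection pair, all in millimetres.
#' @examples
#' cams <- reference_cameras(round_ratios = TRUE)
#' det1 <- tibble::tibble(frame_index = 0L, x_center = 730, y_center = 1278)
#' det2 <- tibble::tibble(frame_index = 0L, x_center = 745, y_center = 1283)
#' pixels_to_world(det1, det2, cams$cam1, cams$cam2)
#' @export
pixels_to_world <- function(det1, det2, cam1, cam2, z_policy = "mean") {
  stopifnot(inherits(cam1, "camera_config"), inherits(cam2, "camera_config"),
            cam1$camera_id == 1L, cam2$camera_id == 2L,
            nrow(det1) == nrow(det2))
  z_policy <- match.arg(z_policy, z_policies)
  has_f1 <- "frame_index" %in% names(det1)
  has_f2 <- "frame_index" %in% names(det2)
  if (has_f1 && has_f2 &&
      !identical(as.integer(det1$frame_index), as.integer(det2$frame_index))) {
    stop("Synchronization error: paired detections have mismatched frame indices.",
         call. = FALSE)
  }
  x <- (det1$x_center - cam1$origin[1]) * cam1$horizontal_ratio
  y <- (cam2$origin[1] - det2$x_center) * cam2$horizontal_ratio
  z1 <- (cam1$origin[2] - det1$y_center) * cam1$vertical_ratio
  z2 <- (cam2$origin[2] - det2$y_center) * cam2$vertical_ratio
  z <- switch(z_policy, mean = (z1 + z2) / 2, cam1 = z1, cam2 = z2)
  out <- tibble::tibble(x = x, y = y, z = z, z_cam1 = z1, z_cam2 = z2)
  if (has_f1) {
    out <- tibble::add_column(out,
                              frame_index = as.integer(det1$frame_index),
                              .before = 1)
  }
  out
}

#' Project 3D world points into both camera image planes
#'
#' Exact algebraic inverse of [pixels_to_world()], componentwise:
#' `X1 = X01 + x/XRATIO`, `X2 = X02 - y/YRATIO`,
#' `Y1 = Y01 - z/ZRATIO1`, `Y2 = Y02 - z/ZRATIO2`.
#' Image formation is orthographic by construction: the ratio model carries
#' no perspective term.
#'
#' @param points Data frame with world coordinates `x`, `y`, `z` in mm
#'   (and optionally `frame_index`).
#' @param cam1,cam2 [camera_config()] objects.
#' @return A tibble with pixel centres `x1`, `y1` (camera 1) and `x2`, `y2`
#'   (camera 2), plus `frame_index` if supplied.
#' @export
world_to_pixels <- function(points, cam1, cam2) {
  stopifnot(inherits(cam1, "camera_config"), inherits(cam2, "camera_config"))
  out <- tibble::tibble(
    x1 = cam1$origin[1] + points$x / cam1$horizontal_ratio,
    y1 = cam1$origin[2] - points$z / cam1$vertical_ratio,
    x2 = cam2$origin[1] - points$y / cam2$horizontal_ratio,
    y2 = cam2$origin[2] - points$z / cam2$vertical_ratio
  )
  if ("frame_index" %in% names(points)) {
    out <- tibble::add_column(out,
                              frame_index = as.integer(points$frame_index),
                              .before = 1)
  }
  out
}
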