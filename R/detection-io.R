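#' Read a per-frame detection label file
#'
#' One text file per camera per frame, one detection per line in the YOLO
#' style: `class x_center y_center width height [confidence]`. Coordinates
#' are either normalized to `[0, 1]` (YOLO convention) or raw ROI pixels;
#' the dialect is never guessed — silently misreading normalized values as
#' pixels (or vice versa) corrupts downstream geometry by orders of
#' magnitude, so `coords` must be stated explicitly.
#'
#' @param path Path to the label file. An empty or missing-detections file
#'   yields zero rows.
#' @param image_size `(width, height)` of the ROI raster in pixels; used to
#'   scale normalized coordinates.
#' @param coords `"pixel"` or `"normalized"`.
#' @param frame_index,camera_id Optional metadata attached to every row.
#' @return A tibble with columns `camera_id`, `frame_index`, `class_label`,
#'   `x_center`, `y_center`, `width`, `height`, `confidence` (NA when the
#'   file has five fields), always in pixel units.
#' @export
read_label_file <- function(path, image_size, coords = c("pixel", "normalized"),
                            frame_index = NA_integer_, camera_id = NA_integer_) {
  coords <- match.arg(coords)
  stopifnot(length(image_size) == 2)
  if (!file.exists(path)) stop("Label file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  empty <- tibble::tibble(
    camera_id = integer(), frame_index = integer(), class_label = integer(),
    x_center = double(), y_center = double(),
    width = double(), height = double(), confidence = double())
  if (length(lines) == 0) return(empty)
  parsed <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (!length(fields) %in% c(5L, 6L)) {
      stop(sprintf("Malformed label line %d in %s: expected 5 or 6 fields, got %d.",
                   i, path, length(fields)), call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(fields))
    if (anyNA(vals)) {
      stop(sprintf("Malformed label line %d in %s: non-numeric field.", i, path),
           call. = FALSE)
    }
    vals
  })
  m <- do.call(rbind, lapply(parsed, function(v) c(v, NA_real_)[1:6]))
  if (coords == "normalized") {
    if (any(m[, 2:5] < 0 | m[, 2:5] > 1)) {
      stop("Coordinate outside [0, 1] under normalized mode; ",
           "the file is probably in pixel units (use coords = \"pixel\").",
           call. = FALSE)
    }
    m[, c(2, 4)] <- m[, c(2, 4)] * image_size[1]
    m[, c(3, 5)] <- m[, c(3, 5)] * image_size[2]
  }
  tibble::tibble(
    camera_id = as.integer(camera_id), frame_index = as.integer(frame_index),
    class_label = as.integer(m[, 1]),
    x_center = m[, 2], y_center = m[, 3],
    width = m[, 4], height = m[, 5], confidence = m[, 6])
}

#' Write a per-frame detection label file
#'
#' Inverse of [read_label_file()]; detections are written at 6 decimals so
#' read-write round trips are loss-free at that precision. A confidence
#' column, when present and non-NA, becomes the optional sixth field.
#'
#' @param detections Tibble with `class_label`, `x_center`, `y_center`,
#'   `width`, `height` (pixel units) and optional `confidence`.
#' @param path Output file path.
#' @param image_size `(width, height)` in pixels; divisor in normalized mode.
#' @param coords `"pixel"` or `"normalized"`.
#' @return `path`, invisibly.
#' @export
write_label_file <- function(detections, path, image_size,
                             coords = c("pixel", "normalized")) {
  coords <- match.arg(coords)
  stopifnot(length(image_size) == 2)
  if (nrow(detections) == 0) {
    ok <- tryCatch({ writeLines(character(), path); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stop("Cannot write label file: ", path, call. = FALSE)
    return(invisible(path))
  }
  xc <- detections$x_center; yc <- detections$y_center
  w <- detections$width; h <- detections$height
  if (coords == "normalized") {
    xc <- xc / image_size[1]; w <- w / image_size[1]
    yc <- yc / image_size[2]; h <- h / image_size[2]
  }
  conf <- if (is.null(detections$confidence)) rep(NA_real_, nrow(detections))
          else detections$confidence
  num <- function(v) formatC(v, format = "f", digits = 6, drop0trailing = TRUE)
  lines <- vapply(seq_len(nrow(detections)), function(i) {
    base <- paste(detections$class_label[i], num(xc[i]), num(yc[i]),
                  num(w[i]), num(h[i]))
    if (is.na(conf[i])) base else paste(base, num(conf[i]))
  }, character(1))
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("Cannot write label file: ", path, call. = FALSE)
  invisible(path)
}

#' Read a directory tree of label files as per-frame detection streams
#'
#' Expects the layout written by [write_label_dir()]:
#' `dir/frame_000000.txt`, one file per frame, consecutively numbered.
#'
#' @param dir Directory of label files for one camera.
#' @inheritParams read_label_file
#' @return A tibble of detections over all frames (pixel units).
#' @export
read_label_dir <- function(dir, image_size, coords = c("pixel", "normalized"),
                           camera_id = NA_integer_) {
  coords <- match.arg(coords)
  files <- sort(list.files(dir, pattern = "^frame_\\d+\\.txt$", full.names = TRUE))
  if (length(files) == 0) stop("No label files under ", dir, call. = FALSE)
  idx <- as.integer(sub("^frame_(\\d+)\\.txt$", "\\1", basename(files)))
  dplyr::bind_rows(purrr::map2(files, idx, function(f, i) {
    read_label_file(f, image_size, coords, frame_index = i, camera_id = camera_id)
  }))
}

#' Write detections as one label file per frame
#'
#' Layout: `dir/frame_{index:06d}.txt`. Frames in `frame_range` with no
#' detections get an empty file so the stream length is explicit.
#'
#' @param detections Tibble with a `frame_index` column plus the columns of
#'   [write_label_file()].
#' @param dir Output directory (created if needed).
#' @param frame_range Integer vector of frame indices to cover; defaults to
#'   `0:max(frame_index)`.
#' @inheritParams write_label_file
#' @return `dir`, invisibly.
#' @export
write_label_dir <- function(detections, dir, image_size,
                            coords = c("pixel", "normalized"),
                            frame_range = NULL) {
  coords <- match.arg(coords)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(frame_range)) {
    frame_range <- 0:max(c(detections$frame_index, 0L))
  }
  by_frame <- split(detections, factor(detections$frame_index, levels = frame_range))
  for (fr in as.character(frame_range)) {
    f <- file.path(dir, sprintf("frame_%06d.txt", as.integer(fr)))
    d <- by_frame[[fr]]
    if (is.null(d)) d <- detections[0, ]
    write_label_file(d, f, image_size, coords)
  }
  invisible(dir)
}

#' Naive blob detector (stand-in for a trained object detector)
#'
#' Detects dark connected components on a light background and returns their
#' tight bounding boxes. This is a deliberately simple detector that lets the
#' full pipeline run on rendered or real frames without trained weights; any
#' detector producing the same label-file records can be swapped in.
#'
#' @param image Numeric matrix or height x width x channels array in `[0, 1]`.
#'   Multichannel images are reduced to luminance by channel averaging.
#' @param threshold Foreground is `luminance < threshold`.
#' @param min_area,max_area Component area bounds in pixels^2; components
#'   outside the range are discarded.
#' @param frame_index,camera_id Optional metadata attached to every row.
#' @return A detection tibble (see [read_label_file()]) with `confidence = 1`.
#' @export
detect_blobs <- function(image, threshold = 0.5, min_area = 4,
                         max_area = Inf,
                         frame_index = NA_integer_, camera_id = NA_integer_) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("detect_blobs() needs the EBImage package for connected components.",
         call. = FALSE)
  }
  d <- dim(image)
  lum <- if (length(d) == 3) apply(image, c(1, 2), mean) else image
  fg <- lum < threshold
  empty <- tibble::tibble(
    camera_id = integer(), frame_index = integer(),
    class_label = integer(), x_center = double(), y_center = double(),
    width = double(), height = double(), confidence = double())
  if (!any(fg)) return(empty)
  # EBImage stores images as (x = column, y = row): transpose in and out
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(fg * 1)))))
  comps <- which(lab > 0, arr.ind = TRUE)
  rows <- list()
  for (id in sort(unique(lab[lab > 0]))) {
    px <- comps[lab[comps] == id, , drop = FALSE]
    area <- nrow(px)
    if (area < min_area || area > max_area) next
    r0 <- min(px[, 1]); r1 <- max(px[, 1])
    c0 <- min(px[, 2]); c1 <- max(px[, 2])
    rows[[length(rows) + 1]] <- tibble::tibble(
      camera_id = as.integer(camera_id), frame_index = as.integer(frame_index),
      class_label = 0L,
      x_center = (c0 + c1) / 2, y_center = (r0 + r1) / 2,
      width = c1 - c0 + 1, height = r1 - r0 + 1, confidence = 1)
  }
  if (length(rows) == 0) empty else dplyr::bind_rows(rows)
}
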