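# Eye-region extraction and iris segmentation.
#
# Image convention used throughout the package: a numeric matrix of 8-bit
# gray levels in [0, 255]; rows are y (top to bottom), columns are x (left
# to right); pixel coordinates are 0-based with the origin at the top-left,
# so pixel (x, y) is img[y + 1, x + 1]. Centroids are real-valued.
#
# Landmark convention: the standard 68-point face annotation, 0-based
# indices. Points 36-41 delimit one eye ("left" in the scheme's own naming,
# which is the image-left eye, i.e. the subject's right — the mirror caveat
# is inherited from the annotation scheme) and 42-47 the other. Within each
# eye's six points, the first and fourth are the corners, the second and
# third the upper eyelid, and the fifth and sixth the lower eyelid.

#' 68-point facial landmarks
#'
#' @param points a 68 x 2 numeric matrix of pixel coordinates (x, y),
#'   0-based, indexed 0-67 row-wise.
#' @return object of class `"face_landmarks"`.
#' @export
face_landmarks <- function(points) {
  points <- as.matrix(points)
  if (!is.numeric(points) || nrow(points) != 68L || ncol(points) != 2L) {
    stop("landmarks must be a 68 x 2 numeric matrix", call. = FALSE)
  }
  for (start in c(37L, 43L)) { # 1-based rows of landmark 36 and 42
    hull <- points[start:(start + 5L), ]
    if (polygon_area(hull) <= 0) {
      stop("invalid landmarks: degenerate eye hull", call. = FALSE)
    }
  }
  structure(list(points = points), class = "face_landmarks")
}

# Shoelace area of a polygon given as a matrix of vertices.
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p)
  abs(sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y)) / 2
}

#' Iris segmentation parameters
#'
#' The segmentation pipeline is bilateral filter, grayscale erosion, then a
#' binary threshold that keeps the dark iris as foreground. No canonical
#' parameter values exist for webcam eye crops; the defaults below
#' (diameter-10 bilateral window with color/space sigmas of 15, three
#' passes of a 3x3 erosion, and an automatic threshold at the midpoint of
#' the 5th and 95th intensity percentiles) work well on crops a few tens of
#' pixels across and are all exposed here.
#'
#' @param bilateral_diameter filter window diameter in pixels.
#' @param bilateral_sigma_color range sigma in gray levels.
#' @param bilateral_sigma_space spatial sigma in pixels.
#' @param erosion_kernel side of the square erosion kernel in pixels.
#' @param erosion_iterations number of erosion passes.
#' @param binary_threshold gray level in \[0,255\], or `"auto"`.
#' @return object of class `"iris_seg_params"`.
#' @export
iris_seg_params <- function(bilateral_diameter = 10,
                            bilateral_sigma_color = 15,
                            bilateral_sigma_space = 15,
                            erosion_kernel = 3,
                            erosion_iterations = 3,
                            binary_threshold = "auto") {
  stopifnot(bilateral_diameter > 0, bilateral_sigma_color > 0,
            bilateral_sigma_space > 0, erosion_kernel > 0,
            erosion_iterations >= 0)
  if (!identical(binary_threshold, "auto")) {
    stopifnot(is.numeric(binary_threshold),
              binary_threshold >= 0, binary_threshold <= 255)
  }
  structure(list(bilateral_diameter = bilateral_diameter,
                 bilateral_sigma_color = bilateral_sigma_color,
                 bilateral_sigma_space = bilateral_sigma_space,
                 erosion_kernel = erosion_kernel,
                 erosion_iterations = erosion_iterations,
                 binary_threshold = binary_threshold),
            class = "iris_seg_params")
}

#' Extract the two eye regions from a face frame
#'
#' Crops each eye's bounding box (landmark points 36-41 and 42-47) expanded
#' by `margin` pixels and clamped to the frame, and records the reference
#' coordinates used by the ratio formulas: the corner x positions, and the
#' eyelid y references taken as the mean y of the two upper-lid points and
#' the mean y of the two lower-lid points.
#'
#' @param image grayscale image matrix.
#' @param landmarks a [face_landmarks()] object.
#' @param margin crop margin in pixels (default 5).
#' @return a list with elements `left` and `right`, each an `eye_region`
#'   with fields `crop`, `origin` (0-based x, y offset of the crop),
#'   `corner_x_min`, `corner_x_max`, `eyelid_y_min`, `eyelid_y_max`.
#' @export
extract_eye_regions <- function(image, landmarks, margin = 5) {
  if (!inherits(landmarks, "face_landmarks")) landmarks <- face_landmarks(landmarks)
  pts <- landmarks$points
  h <- nrow(image); w <- ncol(image)
  if (any(pts[, 1] < 0 | pts[, 1] > w - 1 | pts[, 2] < 0 | pts[, 2] > h - 1)) {
    stop("invalid landmarks: points outside image bounds", call. = FALSE)
  }
  region_for <- function(start) { # 1-based row of the eye's first landmark
    p <- pts[start:(start + 5L), ]
    x0 <- max(0, floor(min(p[, 1])) - margin)
    x1 <- min(w - 1, ceiling(max(p[, 1])) + margin)
    y0 <- max(0, floor(min(p[, 2])) - margin)
    y1 <- min(h - 1, ceiling(max(p[, 2])) + margin)
    structure(list(
      crop = image[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE],
      origin = c(x0, y0),
      corner_x_min = p[1, 1],
      corner_x_max = p[4, 1],
      eyelid_y_min = mean(p[2:3, 2]),
      eyelid_y_max = mean(p[5:6, 2])
    ), class = "eye_region")
  }
  list(left = region_for(37L), right = region_for(43L))
}

# Bilateral filter on a gray matrix: edge-preserving smoothing weighting
# neighbours by both spatial distance and intensity difference. Implemented
# as a vectorized loop over window offsets; crops here are tens of pixels
# across, so the cost is negligible. (No installed package exposes a
# bilateral filter for plain matrices.)
bilateral_filter <- function(img, diameter, sigma_color, sigma_space) {
  r <- max(1L, floor(diameter / 2))
  h <- nrow(img); w <- ncol(img)
  num <- matrix(0, h, w)
  den <- matrix(0, h, w)
  for (dy in -r:r) {
    for (dx in -r:r) {
      if (dy * dy + dx * dx > r * r) next
      ws <- exp(-(dy * dy + dx * dx) / (2 * sigma_space^2))
      # replicate-pad shift
      rows <- clamp(seq_len(h) + dy, 1, h)
      cols <- clamp(seq_len(w) + dx, 1, w)
      shifted <- img[rows, cols, drop = FALSE]
      wr <- exp(-((shifted - img)^2) / (2 * sigma_color^2))
      wgt <- ws * wr
      num <- num + wgt * shifted
      den <- den + wgt
    }
  }
  num / den
}

#' Segment the iris in an eye crop
#'
#' Pipeline: bilateral filter (edge-preserving smoothing of sclera/iris
#' texture), grayscale erosion (a min filter that consolidates and slightly
#' grows the dark iris region), then a binary threshold. The iris is the
#' dark region, so foreground is `filtered < threshold` — foreground always
#' means iris here, regardless of how a mask might be displayed. With
#' `binary_threshold = "auto"` the threshold is the midpoint of the 5th and
#' 95th intensity percentiles of the eroded crop, which makes the
#' segmentation invariant to adding a constant to all gray levels.
#'
#' @param region an `eye_region` from [extract_eye_regions()], or a plain
#'   gray matrix.
#' @param params an [iris_seg_params()] object.
#' @return a logical matrix the size of the crop, `TRUE` on iris pixels.
#'   Signals an error of class `"segmentation_failure"` when the mask comes
#'   out all-foreground or all-background (no separable dark region).
#' @export
segment_iris <- function(region, params = iris_seg_params()) {
  crop <- if (inherits(region, "eye_region")) region$crop else region
  if (length(crop) == 0) stop("empty crop", call. = FALSE)
  sm <- bilateral_filter(crop, params$bilateral_diameter,
                         params$bilateral_sigma_color,
                         params$bilateral_sigma_space)
  if (params$erosion_iterations > 0) {
    k <- EBImage::makeBrush(odd_size(params$erosion_kernel), shape = "box")
    e <- sm / 255
    for (i in seq_len(params$erosion_iterations)) e <- EBImage::erode(e, k)
    sm <- e * 255
  }
  thr <- params$binary_threshold
  if (identical(thr, "auto")) {
    q <- stats::quantile(sm, c(0.05, 0.95), names = FALSE)
    thr <- mean(q)
  }
  mask <- sm < thr
  if (all(mask) || !any(mask)) {
    cond <- structure(
      class = c("segmentation_failure", "error", "condition"),
      list(message = "segmentation failure: mask is uniform", call = NULL))
    stop(cond)
  }
  mask
}

odd_size <- function(k) { k <- as.integer(k); if (k %% 2L == 0L) k + 1L else k }

#' Pupil center from a binary mask by image moments
#'
#' The pupil center is taken as the centroid of the iris mask: the first
#' spatial moments divided by the zeroth moment, translated by the crop
#' origin into full-frame coordinates.
#'
#' @param mask logical (or 0/1) matrix, `TRUE` on iris pixels.
#' @param origin 0-based (x, y) offset of the mask's crop in the full
#'   frame; default `c(0, 0)`.
#' @return numeric `c(x, y)`, real-valued full-frame pixel coordinates.
#' @export
pupil_center <- function(mask, origin = c(0, 0)) {
  m <- (mask != 0) * 1
  m00 <- sum(m)
  if (m00 == 0) {
    cond <- structure(
      class = c("no_pupil_detected", "error", "condition"),
      list(message = "no pupil detected: empty mask", call = NULL))
    stop(cond)
  }
  xs <- 0:(ncol(m) - 1)
  ys <- 0:(nrow(m) - 1)
  m10 <- sum(colSums(m) * xs) # sum of x over foreground
  m01 <- sum(rowSums(m) * ys) # sum of y over foreground
  c(m10 / m00 + origin[1], m01 / m00 + origin[2])
}
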