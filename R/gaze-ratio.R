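# Pupil-position ratios: the shape-based gaze features used in place of a
# point of regard. The horizontal ratio of one eye is the pupil-center x
# position normalized by the eye-corner span; the vertical ratio uses the
# eyelid midlines. Raw ratios never span the full [0,1] because the pupil
# cannot reach the landmark positions, so they are re-normalized against
# pilot-study extremes before use.

#' Pilot re-normalization constants
#'
#' Raw pupil ratios occupy only part of \[0,1\]: the pupil cannot physically
#' reach the eye-corner or eyelid landmarks. The defaults are the mean raw
#' ratios observed in a seven-participant pilot when looking as far as
#' possible in each direction: horizontal 0.28 (rightmost) to 0.87
#' (leftmost), vertical 0.48 (top) to 0.95 (bottom).
#'
#' @param h_min,h_max raw horizontal ratio at the rightmost/leftmost gaze.
#' @param v_min,v_max raw vertical ratio at the top/bottom gaze.
#' @return an object of class `"norm_constants"`.
#' @export
#' @examples
#' norm_constants()
norm_constants <- function(h_min = 0.28, h_max = 0.87,
                           v_min = 0.48, v_max = 0.95) {
  stopifnot(h_min < h_max, v_min < v_max,
            h_min >= 0, h_max <= 1, v_min >= 0, v_max <= 1)
  structure(list(h_min = h_min, h_max = h_max, v_min = v_min, v_max = v_max),
            class = "norm_constants")
}

#' Raw horizontal pupil ratio
#'
#' `(x - x_min) / (x_max - x_min)`, clamped to \[0,1\], where the bounds are
#' the x coordinates of the two eye corners. Because the camera mirrors the
#' scene, a ratio near 1 means the user is looking leftmost and near 0
#' rightmost.
#'
#' @param pupil_x pupil-center x coordinate (pixels, full-frame).
#' @param corner_x_min,corner_x_max eye-corner x coordinates (pixels).
#' @return ratio in \[0,1\].
#' @export
raw_horizontal_ratio <- function(pupil_x, corner_x_min, corner_x_max) {
  if (!(corner_x_min < corner_x_max)) {
    stop("invalid eye geometry: corner_x_min must be < corner_x_max",
         call. = FALSE)
  }
  clamp((pupil_x - corner_x_min) / (corner_x_max - corner_x_min))
}

#' Raw vertical pupil ratio
#'
#' Vertical analogue of [raw_horizontal_ratio()]: the bounds are the mean y
#' of the two upper-eyelid landmarks and the mean y of the two lower-eyelid
#' landmarks. With image y growing downward, a ratio near 1 means gaze at
#' the bottom of the screen.
#'
#' @param pupil_y pupil-center y coordinate (pixels).
#' @param eyelid_y_min,eyelid_y_max upper/lower eyelid reference y (pixels).
#' @return ratio in \[0,1\].
#' @export
raw_vertical_ratio <- function(pupil_y, eyelid_y_min, eyelid_y_max) {
  if (!(eyelid_y_min < eyelid_y_max)) {
    stop("invalid eye geometry: eyelid_y_min must be < eyelid_y_max",
         call. = FALSE)
  }
  clamp((pupil_y - eyelid_y_min) / (eyelid_y_max - eyelid_y_min))
}

#' Re-normalize a raw ratio against pilot extremes
#'
#' Maps the usable raw-ratio band `[lo, hi]` onto \[0,1\]:
#' `(raw - lo) / (hi - lo)`, clamped. With the default horizontal constants
#' (0.28, 0.87) a raw ratio of 0.28 maps to 0 and 0.87 to 1.
#'
#' @param raw raw ratio(s).
#' @param lo,hi raw-ratio bounds, `lo < hi`.
#' @return normalized ratio in \[0,1\].
#' @export
renormalize <- function(raw, lo, hi) {
  if (!(lo < hi)) stop("invalid constants: lo must be < hi", call. = FALSE)
  clamp((raw - lo) / (hi - lo))
}

#' Combine the two eyes' ratios
#'
#' The final per-axis ratio is the arithmetic mean of the left- and
#' right-eye normalized ratios. If one eye is unavailable (blink or
#' segmentation failure, passed as `NA`/`NULL`) the other eye's value is
#' used alone; if both are missing the result is `NA`.
#'
#' @param left,right normalized ratios in \[0,1\], or `NA`/`NULL` if that
#'   eye yielded no pupil.
#' @return combined ratio, or `NA` if both eyes are missing.
#' @export
combine_eyes <- function(left, right) {
  l <- if (is.null(left) || is.na(left)) NA_real_ else left
  r <- if (is.null(right) || is.na(right)) NA_real_ else right
  if (is.na(l) && is.na(r)) return(NA_real_)
  if (is.na(l)) return(r)
  if (is.na(r)) return(l)
  (l + r) / 2
}

#' A horizontal/vertical ratio pair
#'
#' @param h,v ratios in \[0,1\].
#' @return object of class `"ratio_pair"`.
#' @export
ratio_pair <- function(h, v) {
  stopifnot(is.finite(h), is.finite(v))
  structure(list(h = clamp(h), v = clamp(v)), class = "ratio_pair")
}

#' @export
print.ratio_pair <- function(x, ...) {
  cat(sprintf("<ratio_pair> h = %.3f, v = %.3f\n", x$h, x$v))
  invisible(x)
}

#' Gaze-ratio pair from one face frame
#'
#' Full per-frame pipeline: extract both eye regions from the 68-point
#' landmarks, segment each iris, locate the pupil centers by image moments,
#' convert to raw ratios, re-normalize against the pilot constants, and
#' average the two eyes. An eye whose segmentation fails (e.g. during a
#' blink, when no dark iris region is visible) is dropped; if both eyes
#' fail, `NULL` is returned and the frame counts as missing.
#'
#' @param image grayscale image matrix (see [generate_eye_image()] for the
#'   convention) or path to a PNG file.
#' @param landmarks a `face_landmarks` object or path to a landmarks JSON.
#' @param params iris segmentation parameters, see [iris_seg_params()].
#' @param constants pilot constants, see [norm_constants()].
#' @param margin crop margin in pixels passed to [extract_eye_regions()].
#' @return a [ratio_pair()] or `NULL` when neither eye yields a pupil.
#' @export
ratios_from_frame <- function(image, landmarks,
                              params = iris_seg_params(),
                              constants = norm_constants(),
                              margin = 5) {
  if (is.character(image)) image <- read_gray_png(image)
  if (is.character(landmarks)) landmarks <- read_landmarks(landmarks)
  regions <- extract_eye_regions(image, landmarks, margin = margin)
  one_eye <- function(region) {
    mask <- tryCatch(segment_iris(region, params), error = function(e) NULL)
    if (is.null(mask)) return(NULL)
    ctr <- tryCatch(pupil_center(mask, region$origin), error = function(e) NULL)
    if (is.null(ctr)) return(NULL)
    if (!(region$eyelid_y_min < region$eyelid_y_max)) return(NULL)
    list(
      h = renormalize(
        raw_horizontal_ratio(ctr[1], region$corner_x_min, region$corner_x_max),
        constants$h_min, constants$h_max),
      v = renormalize(
        raw_vertical_ratio(ctr[2], region$eyelid_y_min, region$eyelid_y_max),
        constants$v_min, constants$v_max)
    )
  }
  left <- one_eye(regions$left)
  right <- one_eye(regions$right)
  if (is.null(left) && is.null(right)) return(NULL)
  h <- combine_eyes(if (is.null(left)) NA else left$h,
                    if (is.null(right)) NA else right$h)
  v <- combine_eyes(if (is.null(left)) NA else left$v,
                    if (is.null(right)) NA else right$v)
  ratio_pair(h, v)
}
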