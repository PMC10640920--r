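# Readers/writers for the package's on-disk formats: 8-bit grayscale PNG
# images, landmark JSON, gaze-stream CSV, calibration JSON, menu YAML/JSON,
# and event/trial CSVs.

#' Read a PNG as a grayscale matrix
#'
#' Color images are converted to gray with the usual luma weights
#' (0.299 R + 0.587 G + 0.114 B). Values are rescaled to \[0, 255\].
#'
#' @param path PNG file path.
#' @return numeric matrix in the package image convention.
#' @export
read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) {
    if (dim(a)[3] >= 3L) {
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else {
      a <- a[, , 1]
    }
  }
  a * 255
}

#' Write a grayscale matrix as an 8-bit PNG
#'
#' @param image numeric matrix in \[0, 255\].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(image, path) {
  png::writePNG(clamp(image, 0, 255) / 255, path)
  invisible(path)
}

#' Write landmarks (and optional ground truth) as JSON
#'
#' @param landmarks a [face_landmarks()] object.
#' @param path output path.
#' @param iris_left,iris_right optional ground-truth iris centers.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path, iris_left = NULL,
                            iris_right = NULL) {
  obj <- list(points = unname(apply(landmarks$points, 1, identity,
                                    simplify = FALSE)))
  if (!is.null(iris_left)) obj$iris_left <- iris_left
  if (!is.null(iris_right)) obj$iris_right <- iris_right
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read landmarks from JSON
#'
#' @param path JSON path with a `points` field of 68 `[x, y]` pairs.
#' @return a [face_landmarks()] object.
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- obj$points
  if (is.list(pts)) pts <- do.call(rbind, pts)
  face_landmarks(pts)
}

#' Write a gaze-ratio stream as CSV
#'
#' @param stream data.frame with `timestamp`, `h_ratio`, `v_ratio`, `valid`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gaze_stream <- function(stream, path) {
  utils::write.csv(stream, path, row.names = FALSE)
  invisible(path)
}

#' Read a gaze-ratio stream from CSV
#'
#' @param path CSV with header `timestamp,h_ratio,v_ratio,valid`.
#' @return data.frame.
#' @export
read_gaze_stream <- function(path) {
  s <- utils::read.csv(path)
  s$valid <- as.logical(s$valid)
  s
}

#' Persist / load calibration state as JSON
#'
#' @param calib a [calibration_state()].
#' @param path file path.
#' @return `path` (write) or a [calibration_state()] (read).
#' @export
write_calibration <- function(calib, path) {
  jsonlite::write_json(unclass(calib), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_state(o$h_c, o$v_c, o$w, o$l, o$n_samples, o$sample_sd)
}

#' Read a menu model from YAML or JSON
#'
#' The file must map each of `up`, `down`, `left`, `right` to an ordered
#' triple of item identifiers.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return a [menu_model()].
#' @export
read_menu <- function(path) {
  o <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  menu_model(up = o$up, down = o$down, left = o$left, right = o$right)
}
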