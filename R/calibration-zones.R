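# One-point calibration and five-zone gaze classification.
#
# Per-user center ratios vary, so a single short fixation on a screen-center
# point establishes the user's center (h_c, v_c). Ratio space is then
# partitioned into a closed central rectangle of width w and height l (the
# dead zone: looking there triggers nothing, mitigating the Midas-touch
# problem) and four directional zones.

#' Calibration state
#'
#' @param h_c,v_c center ratios in \[0,1\].
#' @param w,l central-rectangle width and height in ratio units, in (0,1).
#'   The defaults 0.4 and 0.2 are the pilot-study values found to suit all
#'   participants.
#' @param n_samples number of samples the center was averaged over.
#' @param sample_sd spread of those samples (mean of the per-axis sds).
#' @return object of class `"calibration_state"`.
#' @export
calibration_state <- function(h_c, v_c, w = 0.4, l = 0.2,
                              n_samples = 1L, sample_sd = 0) {
  stopifnot(h_c >= 0, h_c <= 1, v_c >= 0, v_c <= 1,
            w > 0, w < 1, l > 0, l < 1, n_samples >= 1)
  structure(list(h_c = h_c, v_c = v_c, w = w, l = l,
                 n_samples = as.integer(n_samples), sample_sd = sample_sd),
            class = "calibration_state")
}

#' @export
print.calibration_state <- function(x, ...) {
  cat(sprintf(
    "<calibration_state> center = (%.3f, %.3f), rectangle = %.2f x %.2f (n = %d, sd = %.4f)\n",
    x$h_c, x$v_c, x$w, x$l, x$n_samples, x$sample_sd))
  invisible(x)
}

#' One-point calibration from a gaze stream
#'
#' Averages the valid ratio samples in the first `duration` seconds of the
#' stream while the user fixates a single center point. Two seconds is
#' enough for a stable mean yet short enough that, at a resting blink rate
#' of about 17/min, most windows contain no blink at all. Robustness:
#' invalid (blink) samples are dropped, and samples farther than 2.5
#' median-absolute-deviations from the per-axis median are rejected before
#' averaging, so a stray saccade or half-closed-lid sample cannot shift the
#' center.
#'
#' @param stream data.frame with columns `timestamp`, `h_ratio`, `v_ratio`,
#'   `valid` (as produced by [generate_gaze_stream()]).
#' @param duration calibration window in seconds (default 2).
#' @param w,l central-rectangle size to store in the state.
#' @param min_valid_samples minimum number of usable samples; below this a
#'   `"calibration_failed"` error is signalled so the caller can restart.
#' @return a [calibration_state()].
#' @export
run_one_point_calibration <- function(stream, duration = 2.0,
                                      w = 0.4, l = 0.2,
                                      min_valid_samples = 10L) {
  stopifnot(is.data.frame(stream),
            all(c("timestamp", "h_ratio", "v_ratio", "valid") %in% names(stream)))
  # a stream of n samples at interval dt covers n*dt seconds, so count the
  # trailing sample's interval when checking the window
  dt <- if (nrow(stream) > 1) stats::median(diff(stream$timestamp)) else 0
  if (nrow(stream) == 0 ||
      (max(stream$timestamp) - min(stream$timestamp)) + dt < duration - 1e-9) {
    stop(calibration_failed("stream shorter than the calibration window"))
  }
  t0 <- min(stream$timestamp)
  win <- stream[stream$timestamp <= t0 + duration & stream$valid &
                  !is.na(stream$h_ratio) & !is.na(stream$v_ratio), ]
  keep <- mad_keep(win$h_ratio) & mad_keep(win$v_ratio)
  win <- win[keep, ]
  if (nrow(win) < min_valid_samples) {
    stop(calibration_failed("too few valid samples in the calibration window"))
  }
  sd0 <- function(x) if (length(x) > 1) stats::sd(x) else 0
  calibration_state(h_c = mean(win$h_ratio), v_c = mean(win$v_ratio),
                    w = w, l = l, n_samples = nrow(win),
                    sample_sd = mean(c(sd0(win$h_ratio), sd0(win$v_ratio))))
}

calibration_failed <- function(msg) {
  structure(class = c("calibration_failed", "error", "condition"),
            list(message = paste0("calibration failed: ", msg), call = NULL))
}

# TRUE for samples within 2.5 MAD of the median (all TRUE when MAD is 0,
# i.e. a constant stream keeps every sample).
mad_keep <- function(x, k = 2.5) {
  m <- stats::median(x)
  s <- stats::mad(x)
  abs(x - m) <= k * s + 1e-12
}

#' Classify a ratio pair into one of five gaze zones
#'
#' A point is `"center"` iff it lies in the closed rectangle
#' `|h - h_c| <= w/2` and `|v - v_c| <= l/2` (boundary points are center:
#' conservative against accidental triggers). Outside the rectangle the
#' zone is the axis with the larger normalized excess — the per-axis
#' overshoot beyond the rectangle scaled by the rectangle's half-extent on
#' that axis (`(|h - h_c| - w/2) / (w/2)` vs the vertical analogue), which
#' keeps the rule scale-free for asymmetric rectangles; an exact tie goes
#' to the horizontal axis. Horizontal labels follow the mirror convention
#' (h above center means the user looks left); v above center means down.
#'
#' @param ratio a [ratio_pair()] or numeric `c(h, v)`.
#' @param calib a [calibration_state()].
#' @return one of `"center"`, `"left"`, `"right"`, `"up"`, `"down"`.
#' @export
classify_zone <- function(ratio, calib) {
  if (inherits(ratio, "ratio_pair")) ratio <- c(ratio$h, ratio$v)
  dh <- ratio[1] - calib$h_c
  dv <- ratio[2] - calib$v_c
  eps <- 1e-9 # keep the closed boundary closed under floating-point error
  if (abs(dh) <= calib$w / 2 + eps && abs(dv) <= calib$l / 2 + eps) {
    return("center")
  }
  eh <- (abs(dh) - calib$w / 2) / (calib$w / 2)
  ev <- (abs(dv) - calib$l / 2) / (calib$l / 2)
  if (eh >= ev - eps) { # ties (within float error) go to the horizontal axis
    if (dh > 0) "left" else "right"
  } else {
    if (dv > 0) "down" else "up"
  }
}

#' Classify every sample of a stream into gaze events
#'
#' Vectorized wrapper around [classify_zone()]; invalid samples become
#' `"missing"` events so that downstream consumers handle blink gaps
#' explicitly.
#'
#' @param stream gaze-ratio stream data.frame.
#' @param calib a [calibration_state()].
#' @return data.frame with columns `timestamp`, `label`.
#' @export
classify_events <- function(stream, calib) {
  n <- nrow(stream)
  lab <- character(n)
  ok <- stream$valid & !is.na(stream$h_ratio) & !is.na(stream$v_ratio)
  lab[!ok] <- "missing"
  if (any(ok)) {
    dh <- stream$h_ratio[ok] - calib$h_c
    dv <- stream$v_ratio[ok] - calib$v_c
    inside <- abs(dh) <= calib$w / 2 + 1e-9 & abs(dv) <= calib$l / 2 + 1e-9
    eh <- (abs(dh) - calib$w / 2) / (calib$w / 2)
    ev <- (abs(dv) - calib$l / 2) / (calib$l / 2)
    z <- ifelse(inside, "center",
                ifelse(eh >= ev - 1e-9,
                       ifelse(dh > 0, "left", "right"),
                       ifelse(dv > 0, "down", "up")))
    lab[ok] <- z
  }
  data.frame(timestamp = stream$timestamp, label = lab)
}
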