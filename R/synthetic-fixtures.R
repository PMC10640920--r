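# Synthetic fixtures: eye images with known iris geometry, full-frame face
# fixtures with 68-point landmarks, and simulated gaze-ratio streams. These
# make every downstream module testable with no camera, no landmark-model
# download, and no human data.

#' Specification of a synthetic eye image
#'
#' The eye opening is modeled as two quadratic arcs through the eye corners
#' whose apexes sit `eyelid_apex_offsets` pixels above/below the corner
#' line; the sclera fills the area between the arcs and a dark filled disc
#' is drawn at the iris position. This is deliberately schematic: it
#' exercises the six-landmark geometry and the dark-iris/light-sclera
#' contrast that the segmentation relies on, nothing more.
#'
#' @param image_size `c(width, height)` in pixels.
#' @param eye_corners 2 x 2 matrix, rows are the two corner points (x, y);
#'   the first row must have the smaller x.
#' @param eyelid_apex_offsets `c(upper, lower)` apex offsets in pixels.
#' @param iris_center `c(x, y)` iris-center pixel position (ground truth).
#' @param iris_radius iris radius in pixels (> 0).
#' @param sclera_intensity,iris_intensity,background_intensity 8-bit gray
#'   levels; the iris must be darker than the sclera.
#' @param noise_sd additive Gaussian noise sd in gray levels.
#' @param seed integer RNG seed for the noise.
#' @return object of class `"eye_image_spec"`.
#' @export
eye_image_spec <- function(image_size = c(64, 40),
                           eye_corners = rbind(c(12, 20), c(52, 20)),
                           eyelid_apex_offsets = c(9, 9),
                           iris_center = c(32, 20),
                           iris_radius = 7,
                           sclera_intensity = 230,
                           iris_intensity = 60,
                           background_intensity = 200,
                           noise_sd = 0,
                           seed = 1L) {
  eye_corners <- as.matrix(eye_corners)
  stopifnot(length(image_size) == 2L, all(image_size >= 4),
            nrow(eye_corners) == 2L, ncol(eye_corners) == 2L,
            eye_corners[1, 1] < eye_corners[2, 1],
            length(eyelid_apex_offsets) == 2L, all(eyelid_apex_offsets > 0),
            iris_radius > 0, noise_sd >= 0)
  if (!(iris_intensity < sclera_intensity)) {
    stop("iris must be darker than sclera", call. = FALSE)
  }
  spec <- structure(list(image_size = image_size, eye_corners = eye_corners,
                         eyelid_apex_offsets = eyelid_apex_offsets,
                         iris_center = iris_center, iris_radius = iris_radius,
                         sclera_intensity = sclera_intensity,
                         iris_intensity = iris_intensity,
                         background_intensity = background_intensity,
                         noise_sd = noise_sd, seed = as.integer(seed)),
                    class = "eye_image_spec")
  lids <- eyelid_curves(spec, iris_center[1])
  if (!(iris_center[1] > eye_corners[1, 1] && iris_center[1] < eye_corners[2, 1] &&
        iris_center[2] > lids$upper && iris_center[2] < lids$lower)) {
    stop("iris_center must lie within the eyelid polygon", call. = FALSE)
  }
  spec
}

# Upper/lower eyelid y at horizontal position(s) x: a line between the
# corners bent by a parabola with the given apex offset at the midpoint.
eyelid_curves <- function(spec, x) {
  c0 <- spec$eye_corners[1, ]; c1 <- spec$eye_corners[2, ]
  t <- (x - c0[1]) / (c1[1] - c0[1])
  y_line <- c0[2] + t * (c1[2] - c0[2])
  bend <- 4 * t * (1 - t)
  list(upper = y_line - spec$eyelid_apex_offsets[1] * bend,
       lower = y_line + spec$eyelid_apex_offsets[2] * bend)
}

# The six eye landmarks implied by the geometry, in the standard order:
# corner(min x), upper lid at 1/3 and 2/3 of the span, corner(max x),
# lower lid at 2/3 and 1/3.
eye_landmarks_from_spec <- function(spec) {
  c0 <- spec$eye_corners[1, ]; c1 <- spec$eye_corners[2, ]
  xs <- c0[1] + (c1[1] - c0[1]) * c(1, 2) / 3
  lids <- eyelid_curves(spec, xs)
  rbind(c0,
        c(xs[1], lids$upper[1]), c(xs[2], lids$upper[2]),
        c1,
        c(xs[2], lids$lower[2]), c(xs[1], lids$lower[1]))
}

# Paint one eye (sclera between the eyelid arcs, iris disc clipped to the
# opening) onto a canvas matrix; returns the canvas.
draw_eye <- function(canvas, spec) {
  w <- ncol(canvas); h <- nrow(canvas)
  xs <- matrix(0:(w - 1), h, w, byrow = TRUE)
  ys <- matrix(0:(h - 1), h, w)
  c0 <- spec$eye_corners[1, ]; c1 <- spec$eye_corners[2, ]
  inside_x <- xs >= c0[1] & xs <= c1[1]
  lids <- eyelid_curves(spec, xs)
  open_region <- inside_x & ys >= lids$upper & ys <= lids$lower
  canvas[open_region] <- spec$sclera_intensity
  iris <- (xs - spec$iris_center[1])^2 + (ys - spec$iris_center[2])^2 <=
    spec$iris_radius^2
  canvas[open_region & iris] <- spec$iris_intensity
  canvas
}

#' Generate a synthetic eye image with ground truth
#'
#' @param spec an [eye_image_spec()].
#' @return list with `image` (gray matrix, \[0,255\]), `iris_center`
#'   (ground-truth `c(x, y)`), and `landmarks` (6 x 2 matrix of the eye
#'   landmark positions implied by the geometry, in standard order).
#'   Deterministic for a fixed spec (the noise is seeded by `spec$seed`).
#' @export
#' @examples
#' eye <- generate_eye_image(eye_image_spec())
#' dim(eye$image)
#' eye$iris_center
generate_eye_image <- function(spec) {
  stopifnot(inherits(spec, "eye_image_spec"))
  w <- spec$image_size[1]; h <- spec$image_size[2]
  img <- matrix(spec$background_intensity, h, w)
  img <- draw_eye(img, spec)
  if (spec$noise_sd > 0) {
    img <- with_seed(spec$seed,
                     img + matrix(stats::rnorm(h * w, 0, spec$noise_sd), h, w))
    img <- clamp(img, 0, 255)
  }
  list(image = img, iris_center = spec$iris_center,
       landmarks = eye_landmarks_from_spec(spec))
}

#' Generate a synthetic face frame with 68-point landmarks
#'
#' Composites two synthetic eyes into one frame and assembles a full
#' 68-point landmark set: points 36-41 come from the image-left eye and
#' 42-47 from the image-right eye; the remaining 56 points (jaw, brows,
#' nose, mouth) are filled with a schematic but non-degenerate face layout
#' since only the eye points are consumed by the pipeline.
#'
#' @param left_spec,right_spec [eye_image_spec()]s whose coordinates are
#'   absolute frame coordinates; the left spec must be the image-left eye.
#' @param frame_size `c(width, height)` of the frame in pixels.
#' @param background_intensity frame background gray level.
#' @return list with `image`, `landmarks` (a [face_landmarks()] object) and
#'   `iris_centers` (list with `left` and `right` ground-truth centers).
#' @export
generate_face_frame <- function(left_spec, right_spec,
                                frame_size = c(200, 120),
                                background_intensity = 200) {
  stopifnot(inherits(left_spec, "eye_image_spec"),
            inherits(right_spec, "eye_image_spec"),
            left_spec$eye_corners[2, 1] < right_spec$eye_corners[1, 1])
  w <- frame_size[1]; h <- frame_size[2]
  img <- matrix(background_intensity, h, w)
  img <- draw_eye(img, left_spec)
  img <- draw_eye(img, right_spec)
  noise_sd <- max(left_spec$noise_sd, right_spec$noise_sd)
  if (noise_sd > 0) {
    img <- with_seed(left_spec$seed,
                     img + matrix(stats::rnorm(h * w, 0, noise_sd), h, w))
    img <- clamp(img, 0, 255)
  }
  pts <- filler_landmarks(frame_size, left_spec, right_spec)
  pts[37:42, ] <- eye_landmarks_from_spec(left_spec)
  pts[43:48, ] <- eye_landmarks_from_spec(right_spec)
  list(image = img, landmarks = face_landmarks(pts),
       iris_centers = list(left = left_spec$iris_center,
                           right = right_spec$iris_center))
}

# A plausible, in-frame layout for the 56 landmarks the pipeline ignores.
filler_landmarks <- function(frame_size, left_spec, right_spec) {
  w <- frame_size[1]; h <- frame_size[2]
  cx <- (left_spec$eye_corners[1, 1] + right_spec$eye_corners[2, 1]) / 2
  cy <- mean(c(left_spec$eye_corners[, 2], right_spec$eye_corners[, 2]))
  pts <- matrix(0, 68, 2)
  # jaw 0-16: lower half-ellipse
  th <- seq(pi, 2 * pi, length.out = 17)
  pts[1:17, ] <- cbind(cx + cos(th) * (w * 0.35), cy - sin(th) * (h * 0.45))
  # brows 17-26
  th <- seq(0.2, 0.8, length.out = 5) * pi
  pts[18:22, ] <- cbind(left_spec$eye_corners[1, 1] +
                          (left_spec$eye_corners[2, 1] - left_spec$eye_corners[1, 1]) *
                          seq(0, 1, length.out = 5),
                        cy - h * 0.2)
  pts[23:27, ] <- cbind(right_spec$eye_corners[1, 1] +
                          (right_spec$eye_corners[2, 1] - right_spec$eye_corners[1, 1]) *
                          seq(0, 1, length.out = 5),
                        cy - h * 0.2)
  # nose 27-35
  pts[28:31, ] <- cbind(rep(cx, 4), cy + seq(0.02, 0.2, length.out = 4) * h)
  pts[32:36, ] <- cbind(cx + seq(-0.08, 0.08, length.out = 5) * w, cy + 0.25 * h)
  # mouth 48-67
  th <- seq(0, 2 * pi, length.out = 21)[-21]
  pts[49:68, ] <- cbind(cx + cos(th) * w * 0.12, cy + 0.35 * h + sin(th) * h * 0.08)
  pts[, 1] <- clamp(pts[, 1], 0, w - 1)
  pts[, 2] <- clamp(pts[, 2], 0, h - 1)
  pts
}

#' Simulated gaze scenario
#'
#' Describes a simulated user driving the interface through a sequence of
#' target items. Noise has three components: per-sample Gaussian jitter
#' (`jitter_sd`, measurement noise), a slow AR(1) fixation drift
#' (`drift_sd` stationary sd, `drift_tau` time constant) emulating the
#' autocorrelated wander of fixational eye position as seen through a
#' webcam estimator, and blink dropouts (samples kept but flagged
#' invalid). Blink onsets follow a Poisson process thinned so that blink
#' intervals never overlap; the default rate of 17/min is the resting
#' human blink rate.
#'
#' @param target_sequence character vector of item identifiers.
#' @param reaction_latency mean time (s) the simulated user takes to
#'   re-orient gaze after a stage change; default 0.3 s.
#' @param latency_sd sd of the per-reaction latency (closed-loop trials
#'   draw each latency from a Gamma distribution with mean
#'   `reaction_latency` and this sd; 0 makes reactions deterministic).
#'   The occasional slow reaction is what lets a short dwell threshold
#'   fire on the arrow the user is still looking at.
#' @param jitter_sd per-sample Gaussian noise, ratio units.
#' @param drift_sd stationary sd of the AR(1) drift, ratio units.
#' @param drift_tau drift correlation time constant, seconds.
#' @param blink_rate blinks per minute.
#' @param blink_duration blink length, seconds.
#' @param sample_rate sampling rate, Hz (> 0).
#' @param seed integer master seed; expanded into independent substreams
#'   for jitter, drift, blinks and latencies, so adding one noise source
#'   never perturbs the draws of another.
#' @param true_center `c(h, v)` the user's calibrated center ratio.
#' @param direction_offsets ratio displacement applied when the user looks
#'   at an arrow; default 0.3, safely outside the default central
#'   rectangle (half-width 0.2, half-height 0.1).
#' @param hold_margin extra hold time (s) past the dwell threshold in
#'   open-loop streams, so a confirm sample is guaranteed to fall inside
#'   the hold.
#' @return object of class `"gaze_scenario"`.
#' @export
gaze_scenario <- function(target_sequence,
                          reaction_latency = 0.3,
                          latency_sd = 0.1,
                          jitter_sd = 0.03,
                          drift_sd = 0.08,
                          drift_tau = 0.3,
                          blink_rate = 17,
                          blink_duration = 0.15,
                          sample_rate = 30,
                          seed = 1L,
                          true_center = c(0.56, 0.51),
                          direction_offsets = 0.3,
                          hold_margin = 0.2) {
  stopifnot(sample_rate > 0, jitter_sd >= 0, drift_sd >= 0, drift_tau > 0,
            blink_rate >= 0, blink_duration > 0, reaction_latency >= 0,
            latency_sd >= 0,
            hold_margin >= 0, direction_offsets > 0,
            length(true_center) == 2L)
  structure(list(target_sequence = as.character(target_sequence),
                 reaction_latency = reaction_latency,
                 latency_sd = latency_sd,
                 jitter_sd = jitter_sd, drift_sd = drift_sd,
                 drift_tau = drift_tau, blink_rate = blink_rate,
                 blink_duration = blink_duration, sample_rate = sample_rate,
                 seed = as.integer(seed), true_center = true_center,
                 direction_offsets = direction_offsets,
                 hold_margin = hold_margin),
            class = "gaze_scenario")
}

# Unit ratio-space displacement for gazing at an arrow. Horizontal follows
# the mirror convention (ratio above center = looking left); vertical
# ratio grows toward the bottom of the screen.
direction_vector <- function(direction) {
  switch(direction,
         center = c(0, 0),
         left = c(1, 0),
         right = c(-1, 0),
         down = c(0, 1),
         up = c(0, -1),
         stop("unknown direction: ", direction, call. = FALSE))
}

# Non-overlapping blink intervals over [0, total): Poisson onsets with the
# next onset drawn after the previous blink ends. Returns a 2-column matrix
# (start, end); zero rows when blink_rate is 0.
blink_intervals <- function(total, blink_rate, blink_duration) {
  if (blink_rate <= 0 || total <= 0) return(matrix(numeric(0), ncol = 2))
  rate <- blink_rate / 60
  starts <- numeric(0)
  t <- stats::rexp(1, rate)
  while (t < total) {
    starts <- c(starts, t)
    t <- t + blink_duration + stats::rexp(1, rate)
  }
  cbind(starts, starts + blink_duration)
}

in_any_interval <- function(t, intervals) {
  if (nrow(intervals) == 0) return(rep(FALSE, length(t)))
  out <- rep(FALSE, length(t))
  for (i in seq_len(nrow(intervals))) {
    out <- out | (t >= intervals[i, 1] & t < intervals[i, 2])
  }
  out
}

# AR(1) drift sampled on a regular grid; stationary initialization.
ar1_drift <- function(n, dt, sd, tau) {
  if (sd <= 0 || n == 0) return(numeric(n))
  rho <- exp(-dt / tau)
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  innov_sd <- sd * sqrt(1 - rho^2)
  eps <- stats::rnorm(n - 1, 0, innov_sd)
  for (i in seq_len(n - 1)) x[i + 1] <- rho * x[i] + eps[i]
  x
}

#' Generate an open-loop gaze-ratio stream for a scenario
#'
#' For each target the stream holds the calibrated center for
#' `reaction_latency`, then the direction of the target's cluster for
#' `dwell_threshold + hold_margin`, then the center again, then the
#' item-stage direction likewise (targets in the middle slot map to the
#' "down" arrow; the top slot at the item stage is the back control, which
#' scripted streams never aim at). Drift and jitter are added per sample
#' and blink gaps flagged invalid. Deterministic for a fixed scenario seed.
#'
#' @param scenario a [gaze_scenario()].
#' @param menu a [menu_model()] containing every target.
#' @param dwell_threshold dwell threshold in seconds.
#' @return a data.frame with columns `timestamp`, `h_ratio`, `v_ratio`,
#'   `valid`; timestamps strictly increasing; invalid rows have `NA`
#'   ratios.
#' @export
generate_gaze_stream <- function(scenario, menu, dwell_threshold) {
  stopifnot(inherits(scenario, "gaze_scenario"), dwell_threshold > 0)
  hold <- dwell_threshold + scenario$hold_margin
  segs <- list()
  for (target in scenario$target_sequence) {
    loc <- locate_item(menu, target)
    segs <- c(segs, list(
      c("center", scenario$reaction_latency),
      c(loc$cluster, hold),
      c("center", scenario$reaction_latency),
      c(loc$item_direction, hold)))
  }
  durations <- vapply(segs, function(s) as.numeric(s[2]), numeric(1))
  dirs <- vapply(segs, function(s) s[1], character(1))
  total <- sum(durations)
  dt <- 1 / scenario$sample_rate
  ts <- seq(0, total, by = dt)
  ts <- ts[ts < total]
  n <- length(ts)
  if (n == 0) {
    return(data.frame(timestamp = numeric(0), h_ratio = numeric(0),
                      v_ratio = numeric(0), valid = logical(0)))
  }
  seg_idx <- findInterval(ts, cumsum(c(0, durations)), rightmost.closed = FALSE)
  offsets <- t(vapply(dirs[seg_idx], direction_vector, numeric(2)))
  seeds <- derive_seeds(scenario$seed, c("jitter", "drift", "blinks"))
  jit <- with_seed(seeds[["jitter"]], {
    if (scenario$jitter_sd > 0) {
      matrix(stats::rnorm(2 * n, 0, scenario$jitter_sd), n, 2)
    } else matrix(0, n, 2)
  })
  drift <- with_seed(seeds[["drift"]],
                     cbind(ar1_drift(n, dt, scenario$drift_sd, scenario$drift_tau),
                           ar1_drift(n, dt, scenario$drift_sd, scenario$drift_tau)))
  blinks <- with_seed(seeds[["blinks"]],
                      blink_intervals(total, scenario$blink_rate,
                                      scenario$blink_duration))
  h <- clamp(scenario$true_center[1] + offsets[, 1] * scenario$direction_offsets +
               drift[, 1] + jit[, 1])
  v <- clamp(scenario$true_center[2] + offsets[, 2] * scenario$direction_offsets +
               drift[, 2] + jit[, 2])
  valid <- !in_any_interval(ts, blinks)
  h[!valid] <- NA_real_
  v[!valid] <- NA_real_
  data.frame(timestamp = ts, h_ratio = h, v_ratio = v, valid = valid)
}
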