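# Shared fixtures: a 12-item menu, event-stream builders, and a sweep of
# eye-image specs whose iris disc fits fully inside the eye opening.

test_menu <- function() {
  menu_model(
    up    = c("pizza", "burger", "hotdog"),
    down  = c("drumstick", "chips", "popcorn"),
    left  = c("coffee", "tea", "cocoa"),
    right = c("cola", "water", "juice"))
}

# events data.frame from parallel vectors
events_df <- function(timestamps, labels) {
  data.frame(timestamp = timestamps, label = labels, stringsAsFactors = FALSE)
}

# regular event stream: one label per sample at `rate` Hz over [0, duration)
held_events <- function(label, duration, rate = 30, t0 = 0) {
  ts <- seq(t0, t0 + duration, by = 1 / rate)
  ts <- ts[ts < t0 + duration]
  events_df(ts, rep(label, length(ts)))
}

# Eye specs with the iris disc fully visible (no eyelid clipping), so the
# generator's center is the centroid of the drawn disc.
visible_iris_specs <- function(n, seed = 42, noise_sd = 0) {
  out <- vector("list", n)
  i <- 0L
  withr::with_seed(seed, {
    while (i < n) {
      r <- sample(4:6, 1)
      cx <- runif(1, 20, 44)
      cy <- runif(1, 14, 26)
      sp <- try(eye_image_spec(iris_center = c(cx, cy), iris_radius = r,
                               noise_sd = noise_sd, seed = i + 1L),
                silent = TRUE)
      if (inherits(sp, "try-error")) next
      lid <- gazedwell:::eyelid_curves(sp, cx)
      if (lid$upper > cy - r || lid$lower < cy + r) next
      if (cx - r < sp$eye_corners[1, 1] || cx + r > sp$eye_corners[2, 1]) next
      i <- i + 1L
      out[[i]] <- sp
    }
  })
  out
}

# brute-force centroid oracle: enumerate foreground pixels and average
brute_force_centroid <- function(mask, origin = c(0, 0)) {
  idx <- which(mask != 0, arr.ind = TRUE)
  c(mean(idx[, "col"] - 1) + origin[1], mean(idx[, "row"] - 1) + origin[2])
}

# random logical masks with at least one foreground pixel
random_mask <- function(h, w, p = 0.3) {
  repeat {
    m <- matrix(stats::runif(h * w) < p, h, w)
    if (any(m)) return(m)
  }
}
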